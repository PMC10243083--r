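#' Read a FASTA file
#'
#' Parsing is delegated to [Biostrings::readBStringSet()]; records are
#' returned in file order with multi-line sequences concatenated and
#' whitespace stripped.  A record with an empty sequence is a parse error
#' (the offending header is named).
#'
#' @param source Path to a FASTA file.
#' @return A `data.frame` with columns `header` (without the leading `>`)
#'   and `sequence`; zero rows for an empty file.
#' @seealso [writeFasta()], [parseSwissProtHeader()]
#' @export
readFasta <- function(source) {
    if (file.exists(source) && file.size(source) == 0)
        return(data.frame(header = character(0), sequence = character(0),
                          stringsAsFactors = FALSE))
    set <- Biostrings::readBStringSet(source)
    headers <- names(set)
    seqs <- gsub("\\s", "", as.character(set))
    empty <- !nzchar(seqs)
    if (any(empty))
        stop(sprintf("FASTA record '%s' has an empty sequence",
                     headers[which(empty)[1L]]))
    data.frame(header = headers, sequence = unname(toupper(seqs)),
               stringsAsFactors = FALSE)
}

#' Write records to a FASTA file
#'
#' Sequences are wrapped at 80 characters.  Gapped alignment strings (with
#' `-`) may be written as-is.
#'
#' @param records A `data.frame` with columns `header` and `sequence` (as
#'   returned by [readFasta()]), or a named character vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(records, path) {
    if (is.character(records))
        records <- data.frame(header = names(records),
                              sequence = unname(records),
                              stringsAsFactors = FALSE)
    set <- Biostrings::BStringSet(records$sequence)
    names(set) <- records$header
    Biostrings::writeXStringSet(set, filepath = path, width = 80L)
    invisible(path)
}

#' Parse UniProtKB FASTA headers
#'
#' Understands the UniProtKB convention
#' `db|ACCESSION|ENTRY_NAME Description OS=Organism ... GN=Gene ...`.
#' Headers without two `|` separators fall back to the whole header as the
#' description with an `NA` accession.
#'
#' @param header Character vector of FASTA headers (no leading `>`).
#' @return A `data.frame` with columns `accession`, `entryName`, `geneName`,
#'   `organism`, `description` (`NA` where a field is absent).
#' @examples
#' parseSwissProtHeader(
#'   "sp|P69905|HBA_HUMAN Hemoglobin subunit alpha OS=Homo sapiens GN=HBA1")
#' @export
parseSwissProtHeader <- function(header) {
    parseOne <- function(h) {
        parts <- strsplit(h, "|", fixed = TRUE)[[1L]]
        if (length(parts) < 3L)
            return(c(accession = NA_character_, entryName = NA_character_,
                     geneName = NA_character_, organism = NA_character_,
                     description = h))
        accession <- parts[2L]
        rest <- paste(parts[-(1:2)], collapse = "|")
        entry <- sub("\\s.*$", "", rest)
        tail <- sub("^\\S+\\s*", "", rest)
        # description runs up to the first XX= tag
        desc <- sub("\\s+[A-Z]{2}=.*$", "", tail)
        grab <- function(tag) {
            m <- regmatches(tail, regexpr(paste0(tag, "=.*?(?=\\s+[A-Z]{2}=|$)"),
                                          tail, perl = TRUE))
            if (length(m)) sub(paste0("^", tag, "="), "", m) else NA_character_
        }
        c(accession = accession, entryName = entry, geneName = grab("GN"),
          organism = grab("OS"),
          description = if (nzchar(desc)) desc else NA_character_)
    }
    out <- t(vapply(header, parseOne, character(5L)))
    rownames(out) <- NULL
    as.data.frame(out, stringsAsFactors = FALSE)
}

#' Filter FASTA records by Swiss-Prot annotation
#'
#' Reproduces the record exclusions used when searching a curated protein
#' dataset: records whose description contains "uncharacterized"
#' (case-insensitive) and/or whose organism matches a viral keyword
#' (`virus`, `phage`, `viridae`) are dropped.  Viral origin is detected from
#' the organism string, as FASTA headers carry no taxonomic lineage; this is
#' a keyword approximation.
#'
#' @param records `data.frame` from [readFasta()].
#' @param excludeUncharacterized,excludeViral Logical flags.
#' @param meta Optional pre-parsed metadata from [parseSwissProtHeader()];
#'   parsed from `records$header` when `NULL`.
#' @return The filtered `records` data.frame.
#' @export
filterRecords <- function(records, excludeUncharacterized = TRUE,
                          excludeViral = TRUE, meta = NULL) {
    if (nrow(records) == 0L) return(records)
    if (is.null(meta)) meta <- parseSwissProtHeader(records$header)
    keep <- rep(TRUE, nrow(records))
    if (excludeUncharacterized) {
        desc <- ifelse(is.na(meta$description), "", meta$description)
        keep <- keep & !grepl("uncharacterized", desc, ignore.case = TRUE)
    }
    if (excludeViral) {
        org <- ifelse(is.na(meta$organism), "", meta$organism)
        keep <- keep & !grepl("virus|phage|viridae", org, ignore.case = TRUE)
    }
    records[keep, , drop = FALSE]
}
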