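#' SpacedPattern: informative and don't-care seed positions
#'
#' A spaced k-mer pattern is a boolean mask over a window of `span`
#' positions; `TRUE` marks the `k` informative positions that enter the
#' k-mer code, `FALSE` the "don't care" positions.  The first and last mask
#' entries must be informative.  A contiguous k-mer is the all-`TRUE`
#' pattern.
#'
#' @slot mask Logical vector.
#' @export
setClass("SpacedPattern", representation(mask = "logical"))

setValidity("SpacedPattern", function(object) {
    m <- object@mask
    if (length(m) < 1L || sum(m) < 1L) return("pattern needs >= 1 informative position")
    if (!m[1L] || !m[length(m)])
        return("first and last pattern positions must be informative")
    if (anyNA(m)) return("pattern mask must not contain NA")
    TRUE
})

#' Create a spaced (or contiguous) seed pattern
#'
#' @param x Either a logical vector, or a string of `'1'`/`'0'` characters
#'   (`'1'` = informative).
#' @return A [SpacedPattern-class].
#' @examples
#' spacedPattern("1101")     # k = 3, span = 4
#' contiguousPattern(6)      # plain 6-mer
#' @export
spacedPattern <- function(x) {
    if (is.character(x)) {
        ch <- strsplit(x, "", fixed = TRUE)[[1L]]
        if (!all(ch %in% c("0", "1")))
            stop("pattern string must consist of '0' and '1' only")
        x <- ch == "1"
    }
    new("SpacedPattern", mask = as.logical(x))
}

#' @rdname spacedPattern
#' @param k Number of informative positions.
#' @export
contiguousPattern <- function(k) new("SpacedPattern", mask = rep(TRUE, k))

#' @rdname spacedPattern
#' @param object A `SpacedPattern`.
#' @export
patternK <- function(object) sum(object@mask)

#' @rdname spacedPattern
#' @export
patternSpan <- function(object) length(object@mask)

setMethod("show", "SpacedPattern", function(object) {
    cat(sprintf("SpacedPattern '%s' (k = %d, span = %d)\n",
                paste(as.integer(object@mask), collapse = ""),
                patternK(object), patternSpan(object)))
})

#' k-mer code arithmetic
#'
#' A k-mer with symbol codes `c_0, ..., c_{k-1}` over an alphabet of size
#' `q` is mapped to the unambiguous integer code
#' `d = sum_i q^i * c_i`, with `0 <= d < q^k`.  `kmerDecode()` is the
#' inverse.  Codes are held as doubles; `q^k` must stay below 2^53 so the
#' arithmetic remains exact.
#'
#' @param codes Integer vector of `k` symbol codes (each `< q`).
#' @param q Alphabet size.
#' @return `kmerCode()`: the scalar code `d`; `kmerDecode()`: the integer
#'   code vector.
#' @examples
#' kmerCode(c(0, 1, 2), 4)      # "ACG" over ACGT -> 36
#' kmerDecode(36, 3, 4)
#' @export
kmerCode <- function(codes, q) {
    if (anyNA(codes) || any(codes < 0) || any(codes >= q))
        stop("symbol codes must lie in [0, q)")
    k <- length(codes)
    sum(q^(seq_len(k) - 1) * codes)
}

#' @rdname kmerCode
#' @param d k-mer code in `[0, q^k)`.
#' @param k k-mer length.
#' @export
kmerDecode <- function(d, k, q) {
    if (is.na(d) || d < 0 || d >= q^k)
        stop("k-mer code out of range [0, q^k)")
    out <- integer(k)
    for (i in seq_len(k)) {
        out[i] <- as.integer(d %% q)
        d <- (d - out[i]) / q
    }
    out
}

# All k-mer codes of a sequence under a pattern: data.frame(pos, code) with
# 0-based start positions; masked positions (mask TRUE = masked) drop any
# k-mer whose informative positions touch them.
sequenceKmerCodes <- function(seq, pattern, mask = NULL) {
    cd <- seq@codes
    q <- alphabetSize(seq@alphabet)
    span <- patternSpan(pattern)
    n <- length(cd)
    nk <- n - span + 1L
    if (nk <= 0L)
        return(data.frame(pos = integer(0), code = numeric(0)))
    inf <- which(pattern@mask)                      # 1-based offsets
    weights <- q^(seq_along(inf) - 1)
    m <- vapply(inf, function(o) cd[o:(o + nk - 1L)], integer(nk))
    if (nk == 1L) m <- matrix(m, nrow = 1L)
    code <- as.numeric(m %*% weights)
    keep <- rep(TRUE, nk)
    if (!is.null(mask)) {
        stopifnot(length(mask) == n)
        bad <- vapply(inf, function(o) mask[o:(o + nk - 1L)], logical(nk))
        if (nk == 1L) bad <- matrix(bad, nrow = 1L)
        keep <- rowSums(bad) == 0L
    }
    data.frame(pos = (seq_len(nk) - 1L)[keep], code = code[keep])
}

#' KmerTable: map from k-mer code to occurrence list
#'
#' Maps every k-mer code `d` occurring in a sequence database to the sorted
#' list of `(reference id, position)` pairs where it appears.  Built in two
#' passes in the counting-sort sense: occurrence counts per code are
#' determined first, then fixed-size occurrence lists are filled, stored
#' here as one contiguous occurrence array plus per-code offsets (no list
#' resizing, and a single representation for any `q^k`).
#'
#' @slot alphabet [Alphabet-class] shared by all indexed sequences.
#' @slot k Number of informative positions.
#' @slot mask Logical pattern mask (all `TRUE` = contiguous).
#' @slot codes Sorted unique k-mer codes present (numeric).
#' @slot offsets 0-based offsets into the occurrence arrays,
#'   `length(codes) + 1` entries.
#' @slot refIds,positions Parallel occurrence arrays (refId 1-based,
#'   position 0-based), sorted by (code, refId, position).
#' @slot refNames,refLengths Per-reference metadata.
#' @export
setClass("KmerTable",
         representation(alphabet = "Alphabet", k = "integer",
                        mask = "logical", codes = "numeric",
                        offsets = "integer", refIds = "integer",
                        positions = "integer", refNames = "character",
                        refLengths = "integer"))

setValidity("KmerTable", function(object) {
    if (is.unsorted(object@codes, strictly = TRUE) && length(object@codes) > 1L)
        return("codes must be strictly increasing")
    if (length(object@offsets) != length(object@codes) + 1L)
        return("offsets must have length(codes) + 1 entries")
    if (length(object@refIds) != length(object@positions))
        return("refIds and positions must be parallel")
    span <- length(object@mask)
    if (length(object@positions)) {
        lens <- object@refLengths[object@refIds]
        if (any(object@positions < 0L) ||
            any(object@positions > lens - span))
            return("stored positions must satisfy 0 <= p <= len - span")
    }
    TRUE
})

#' Number of stored k-mer occurrences
#'
#' @param x A [KmerTable-class].
#' @return Integer count.
#' @export
setGeneric("kmerCount", function(x) standardGeneric("kmerCount"))

#' @rdname kmerCount
#' @export
setMethod("kmerCount", "KmerTable", function(x) length(x@positions))

setMethod("show", "KmerTable", function(object) {
    cat(sprintf(
        "KmerTable: k = %d, pattern '%s', %d reference(s), %d occurrence(s)\n",
        object@k, paste(as.integer(object@mask), collapse = ""),
        length(object@refNames), length(object@positions)))
})

#' Build a k-mer table from a sequence database
#'
#' Indexes every (unmasked) k-mer of every sequence.  With a
#' [SpacedPattern-class], only the informative positions enter the code and
#' a k-mer is dropped when *any* of its informative positions is masked.
#'
#' @param sequences List of [Sequence-class] objects over a common alphabet;
#'   names become reference names (default `seq1, seq2, ...`).
#' @param k k-mer length (ignored when `pattern` is given).
#' @param pattern Optional [SpacedPattern-class]; default contiguous `k`.
#' @param masks Optional list of per-sequence logical vectors (`TRUE` =
#'   masked position, e.g. low-complexity regions).
#' @return A [KmerTable-class].
#' @examples
#' tab <- buildKmerTable(list(encodeSequence("ACGT", nucleotideAlphabet())),
#'                       k = 2)
#' kmerCount(tab)   # 3 two-mers: AC, CG, GT
#' @export
buildKmerTable <- function(sequences, k, pattern = NULL, masks = NULL) {
    stopifnot(length(sequences) >= 1L)
    alph <- alphabet(sequences[[1L]])
    for (s in sequences)
        if (!sameAlphabet(alphabet(s), alph))
            stop("all sequences must share one alphabet")
    if (is.null(pattern)) pattern <- contiguousPattern(k)
    k <- patternK(pattern)
    q <- alphabetSize(alph)
    if (q^k >= 2^53)
        stop("q^k exceeds the exactly representable code range (2^53)")
    nm <- names(sequences)
    if (is.null(nm)) nm <- paste0("seq", seq_along(sequences))
    if (anyDuplicated(nm)) stop("reference names must be unique")

    parts <- lapply(seq_along(sequences), function(i) {
        km <- sequenceKmerCodes(sequences[[i]], pattern,
                                if (is.null(masks)) NULL else masks[[i]])
        if (nrow(km) == 0L) return(NULL)
        cbind(code = km$code, ref = i, pos = km$pos)
    })
    occ <- do.call(rbind, parts[!vapply(parts, is.null, TRUE)])
    newKmerTableFromOcc(alph, pattern, occ, nm,
                        vapply(sequences, length, 0L))
}

# Assemble the CSR-style store from an occurrence matrix (code, ref, pos).
newKmerTableFromOcc <- function(alph, pattern, occ, refNames, refLengths) {
    if (is.null(occ) || nrow(occ) == 0L) {
        return(new("KmerTable", alphabet = alph, k = patternK(pattern),
                   mask = pattern@mask, codes = numeric(0),
                   offsets = 0L, refIds = integer(0), positions = integer(0),
                   refNames = refNames, refLengths = as.integer(refLengths)))
    }
    ord <- order(occ[, "code"], occ[, "ref"], occ[, "pos"])
    occ <- occ[ord, , drop = FALSE]
    codes <- occ[, "code"]
    uniq <- !duplicated(codes)
    counts <- tabulate(cumsum(uniq), nbins = sum(uniq))
    new("KmerTable", alphabet = alph, k = patternK(pattern),
        mask = pattern@mask, codes = unname(codes[uniq]),
        offsets = as.integer(c(0L, cumsum(counts))),
        refIds = as.integer(unname(occ[, "ref"])),
        positions = as.integer(unname(occ[, "pos"])),
        refNames = refNames, refLengths = as.integer(refLengths))
}

# Occurrence rows for a vector of k-mer codes; returns matrix(refId, pos,
# slot) where `slot` indexes the query code that matched.
lookupCodes <- function(table, d) {
    if (length(table@codes) == 0L || length(d) == 0L)
        return(cbind(refId = integer(0), pos = integer(0), slot = integer(0)))
    idx <- findInterval(d, table@codes)
    hit <- idx > 0L & table@codes[pmax(idx, 1L)] == d
    if (!any(hit))
        return(cbind(refId = integer(0), pos = integer(0), slot = integer(0)))
    widx <- which(hit)
    from <- table@offsets[idx[widx]] + 1L
    to <- table@offsets[idx[widx] + 1L]
    take <- sequence(to - from + 1L, from = from)
    slot <- rep(widx, to - from + 1L)
    cbind(refId = table@refIds[take], pos = table@positions[take],
          slot = slot)
}

#' Look up one k-mer code
#'
#' @param table A [KmerTable-class].
#' @param d A k-mer code.
#' @return `data.frame(refId, refName, position)` of occurrences.
#' @export
kmerLookup <- function(table, d) {
    occ <- lookupCodes(table, d)
    data.frame(refId = occ[, "refId"],
               refName = table@refNames[occ[, "refId"]],
               position = occ[, "pos"])
}

# Enumerate all k-mer code vectors y with sum_i S[c_i, y_i] >= threshold
# (branch and bound with per-position suffix score bounds); returns the
# numeric codes d of all such k-mers, including the query k-mer itself when
# it qualifies.
similarKmerCodes <- function(codesVec, scores, threshold, q) {
    k <- length(codesVec)
    rows <- scores[codesVec + 1L, , drop = FALSE]
    rowMax <- apply(rows, 1L, max)
    suffMax <- rev(cumsum(rev(rowMax)))          # bound including position i
    acc <- new.env(parent = emptyenv())
    acc$out <- numeric(0)
    weights <- q^(seq_len(k) - 1)
    recurse <- function(i, sc, d) {
        if (sc + suffMax[i] < threshold) return()
        row <- rows[i, ]
        for (y in 0:(q - 1L)) {
            s2 <- sc + row[y + 1L]
            d2 <- d + y * weights[i]
            bound <- if (i < k) suffMax[i + 1L] else 0
            if (s2 + bound < threshold) next
            if (i == k) acc$out <- c(acc$out, d2)
            else recurse(i + 1L, s2, d2)
        }
    }
    if (k >= 1L) recurse(1L, 0, 0)
    acc$out
}

#' Find k-mer matches between a query and a k-mer table
#'
#' Every k-mer of the query is looked up in the table.  Without a threshold,
#' only exact code matches are returned.  With `threshold` (which requires
#' `matrix`), all k-mers whose summed per-position substitution score
#' against the query k-mer is at least `threshold` are enumerated
#' (branch-and-bound) and their occurrences returned, which relaxes matching
#' to similar k-mers.
#'
#' @param table A [KmerTable-class].
#' @param query A [Sequence-class] over the table's alphabet.
#' @param matrix Optional [SubstitutionMatrix-class] (same alphabet both
#'   sides) for relaxed matching.
#' @param threshold Optional minimum summed substitution score.
#' @return `data.frame(queryPos, refId, refPos)` (0-based positions), sorted
#'   by `(queryPos, refId, refPos)`.  The diagonal of a match is
#'   `refPos - queryPos`.
#' @export
matchKmers <- function(table, query, matrix = NULL, threshold = NULL) {
    if (!sameAlphabet(alphabet(query), table@alphabet))
        stop("query alphabet does not match the table alphabet")
    pattern <- new("SpacedPattern", mask = table@mask)
    km <- sequenceKmerCodes(query, pattern)
    empty <- data.frame(queryPos = integer(0), refId = integer(0),
                        refPos = integer(0))
    if (nrow(km) == 0L) return(empty)

    if (is.null(threshold)) {
        occ <- lookupCodes(table, km$code)
        if (nrow(occ) == 0L) return(empty)
        res <- data.frame(queryPos = km$pos[occ[, "slot"]],
                          refId = occ[, "refId"], refPos = occ[, "pos"])
    } else {
        if (is.null(matrix))
            stop("relaxed matching requires a substitution matrix")
        if (!sameAlphabet(matrix@alphabet1, table@alphabet) ||
            !sameAlphabet(matrix@alphabet2, table@alphabet))
            stop("substitution matrix alphabets must match the table alphabet")
        q <- alphabetSize(table@alphabet)
        res <- empty
        # enumerate candidate k-mers once per distinct query k-mer code
        byCode <- split(km$pos, km$code)
        for (codeStr in names(byCode)) {
            d <- as.numeric(codeStr)
            cand <- similarKmerCodes(kmerDecode(d, table@k, q),
                                     matrix@scores, threshold, q)
            occ <- lookupCodes(table, sort(unique(cand)))
            if (nrow(occ) == 0L) next
            qpos <- byCode[[codeStr]]
            res <- rbind(res, data.frame(
                queryPos = rep(qpos, each = nrow(occ)),
                refId = rep(occ[, "refId"], times = length(qpos)),
                refPos = rep(occ[, "pos"], times = length(qpos))))
        }
        if (nrow(res) == 0L) return(empty)
    }
    res <- res[order(res$queryPos, res$refId, res$refPos), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Merge k-mer tables built over disjoint reference sets
#'
#' Enables building a database index in parts.  All inputs must share `k`,
#' the pattern and the alphabet, and their reference names must be disjoint;
#' merged lookups equal the union of the inputs' lookups.
#'
#' @param tables List of [KmerTable-class] objects.
#' @return A single merged [KmerTable-class].
#' @export
mergeKmerTables <- function(tables) {
    stopifnot(length(tables) >= 1L)
    t1 <- tables[[1L]]
    for (t in tables[-1L]) {
        if (t@k != t1@k || !identical(t@mask, t1@mask) ||
            !sameAlphabet(t@alphabet, t1@alphabet))
            stop("tables differ in k, pattern or alphabet")
    }
    allNames <- unlist(lapply(tables, function(t) t@refNames))
    if (anyDuplicated(allNames))
        stop("reference names of merged tables must be disjoint")
    offset <- 0L
    occs <- list()
    lens <- integer(0)
    for (t in tables) {
        nOcc <- length(t@positions)
        codes <- rep(t@codes, diff(t@offsets))
        occs[[length(occs) + 1L]] <-
            cbind(code = codes, ref = t@refIds + offset, pos = t@positions)
        offset <- offset + length(t@refNames)
        lens <- c(lens, t@refLengths)
    }
    pattern <- new("SpacedPattern", mask = t1@mask)
    newKmerTableFromOcc(t1@alphabet, pattern, do.call(rbind, occs),
                        allNames, lens)
}

KMER_TABLE_MAGIC <- "SQSMKT01"

#' Serialize a k-mer table to raw bytes
#'
#' Binary layout: 8 magic bytes with a format version, the alphabet string,
#' the pattern string, reference names and lengths, then the
#' length-prefixed occurrence arrays.  [deserializeKmerTable()] restores a
#' table equal in all lookups and metadata; a wrong magic/version or a
#' truncated payload is a format error.
#'
#' @param table A [KmerTable-class].
#' @return A raw vector.
#' @export
serializeKmerTable <- function(table) {
    con <- rawConnection(raw(0), "wb")
    on.exit(close(con))
    writeBin(charToRaw(KMER_TABLE_MAGIC), con)
    writeString <- function(s) {
        r <- charToRaw(s)
        writeBin(length(r), con)
        writeBin(r, con)
    }
    writeString(paste(alphabetSymbols(table@alphabet), collapse = ""))
    writeString(paste(as.integer(table@mask), collapse = ""))
    writeBin(length(table@refNames), con)
    for (nm in table@refNames) writeString(nm)
    writeBin(table@refLengths, con)
    writeBin(length(table@codes), con)
    writeBin(table@codes, con)
    writeBin(table@offsets, con)
    writeBin(length(table@refIds), con)
    writeBin(table@refIds, con)
    writeBin(table@positions, con)
    rawConnectionValue(con)
}

#' @rdname serializeKmerTable
#' @param bytes Raw vector from `serializeKmerTable()`.
#' @export
deserializeKmerTable <- function(bytes) {
    con <- rawConnection(bytes, "rb")
    on.exit(close(con))
    readChecked <- function(what, n, size = NA_integer_) {
        out <- if (is.na(size)) readBin(con, what, n = n)
               else readBin(con, what, n = n, size = size)
        if (length(out) != n)
            stop("truncated k-mer table payload")
        out
    }
    magic <- as.raw(readChecked(integer(), 8L, size = 1L))
    if (!identical(magic, charToRaw(KMER_TABLE_MAGIC)))
        stop("not a serialized k-mer table (bad magic/version)")
    readString <- function() {
        n <- readChecked(integer(), 1L)
        rawToChar(as.raw(readChecked(integer(), n, size = 1L)))
    }
    alph <- Alphabet(readString())
    mask <- strsplit(readString(), "", fixed = TRUE)[[1L]] == "1"
    nref <- readChecked(integer(), 1L)
    refNames <- vapply(seq_len(nref), function(i) readString(), "")
    refLengths <- readChecked(integer(), nref)
    ncodes <- readChecked(integer(), 1L)
    codes <- readChecked(numeric(), ncodes)
    offsets <- readChecked(integer(), ncodes + 1L)
    nocc <- readChecked(integer(), 1L)
    refIds <- readChecked(integer(), nocc)
    positions <- readChecked(integer(), nocc)
    new("KmerTable", alphabet = alph, k = sum(mask), mask = mask,
        codes = codes, offsets = offsets, refIds = refIds,
        positions = positions, refNames = refNames,
        refLengths = refLengths)
}
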