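#' SearchConfig: parameters of the multi-stage homology search
#'
#' Bundles every stage threshold of the seed-and-extend pipeline:
#' k-mer matching (optionally relaxed by a substitution-score threshold),
#' the two-hit diagonal filter, ungapped X-drop extension, banded gapped
#' alignment, and E-value ranking.
#'
#' @slot k k-mer length (used when `pattern` is `NULL`).
#' @slot pattern Optional [SpacedPattern-class] (`NULL` = contiguous `k`).
#' @slot kmerThreshold Substitution-score threshold for relaxed k-mer
#'   matching (`NA` = exact matching).
#' @slot minHits Minimum number of k-mer matches on one diagonal of one
#'   reference before extension (two-hit strategy; default 2).
#' @slot ungappedThreshold Minimum ungapped-extension score for a seed to
#'   reach the gapped stage (raw score).
#' @slot xDrop X-drop threshold of the ungapped extension.
#' @slot bandWidth Half-width W of the gapped alignment band around the
#'   seed diagonal.
#' @slot gapOpen,gapExtend Non-positive affine gap penalties.
#' @slot maxEvalue Report only hits with E-value at or below this.
#' @slot evalueSamples Number of random score samples for the Gumbel fit.
#' @slot background Background frequencies for score sampling (`NULL` =
#'   uniform over the 20 standard amino acids for protein alphabets, else
#'   uniform).
#' @slot seed RNG seed for the E-value estimator.
#' @seealso [searchConfig()], [runSearch()]
#' @export
setClass("SearchConfig",
         representation(k = "integer", pattern = "ANY",
                        kmerThreshold = "numeric", minHits = "integer",
                        ungappedThreshold = "numeric", xDrop = "numeric",
                        bandWidth = "integer", gapOpen = "numeric",
                        gapExtend = "numeric", maxEvalue = "numeric",
                        evalueSamples = "integer", background = "ANY",
                        seed = "integer"))

#' Create a search configuration
#'
#' Defaults follow common practice for protein search: contiguous 6-mers,
#' exact k-mer matching, two hits per diagonal, ungapped score threshold 20,
#' X-drop 20, band half-width 20, BLOSUM62-style gap penalties open -11 /
#' extend -1, E-value cutoff 10, 1000 Gumbel samples.
#'
#' @param k,pattern,kmerThreshold,minHits,ungappedThreshold,xDrop,bandWidth
#'   See [SearchConfig-class].
#' @param gapOpen,gapExtend,maxEvalue,evalueSamples,background,seed
#'   See [SearchConfig-class].
#' @return A [SearchConfig-class].
#' @export
searchConfig <- function(k = 6L, pattern = NULL, kmerThreshold = NA_real_,
                         minHits = 2L, ungappedThreshold = 20,
                         xDrop = 20, bandWidth = 20L,
                         gapOpen = -11, gapExtend = -1,
                         maxEvalue = 10, evalueSamples = 1000L,
                         background = NULL, seed = 1L) {
    checkGap(gapOpen, gapExtend)
    new("SearchConfig", k = as.integer(k), pattern = pattern,
        kmerThreshold = as.numeric(kmerThreshold),
        minHits = as.integer(minHits),
        ungappedThreshold = as.numeric(ungappedThreshold),
        xDrop = as.numeric(xDrop), bandWidth = as.integer(bandWidth),
        gapOpen = as.numeric(gapOpen), gapExtend = as.numeric(gapExtend),
        maxEvalue = as.numeric(maxEvalue),
        evalueSamples = as.integer(evalueSamples),
        background = background, seed = as.integer(seed))
}

#' Two-hit diagonal filter
#'
#' Groups k-mer matches by `(refId, diagonal)` with
#' `diagonal = refPos - queryPos`, keeps groups with at least `minHits`
#' distinct query positions, and emits one representative seed per
#' surviving group: the match with the lowest query position.  With
#' `minHits = 1` every match passes.
#'
#' @param matches `data.frame(queryPos, refId, refPos)` from
#'   [matchKmers()].
#' @param minHits Minimum distinct query positions per diagonal group.
#' @return `data.frame(refId, diagonal, queryPos, refPos, nHits)`, sorted by
#'   `(refId, diagonal)`.
#' @export
doubleHitFilter <- function(matches, minHits = 2L) {
    out <- data.frame(refId = integer(0), diagonal = integer(0),
                      queryPos = integer(0), refPos = integer(0),
                      nHits = integer(0))
    if (nrow(matches) == 0L) return(out)
    diagonal <- matches$refPos - matches$queryPos
    key <- paste(matches$refId, diagonal, sep = "/")
    groups <- split(seq_len(nrow(matches)), key)
    rows <- lapply(groups, function(idx) {
        n <- length(unique(matches$queryPos[idx]))
        if (n < minHits) return(NULL)
        rep <- idx[which.min(matches$queryPos[idx])]
        data.frame(refId = matches$refId[rep],
                   diagonal = matches$refPos[rep] - matches$queryPos[rep],
                   queryPos = matches$queryPos[rep],
                   refPos = matches$refPos[rep], nHits = n)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows) == 0L) return(out)
    out <- do.call(rbind, rows)
    out <- out[order(out$refId, out$diagonal), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Run the multi-stage homology search
#'
#' Executes the full seed-and-extend pipeline for one query against a
#' sequence database: k-mer matching against the (given or freshly built)
#' k-mer table, the two-hit diagonal filter, ungapped X-drop extension of
#' each surviving seed, banded gapped local alignment (band = seed diagonal
#' +/- `bandWidth`) of seeds whose ungapped score reaches
#' `ungappedThreshold`, and finally E-value ranking with a Gumbel estimator
#' fitted once per query and scoring scheme.  At most one hit (the best
#' E-value) is reported per reference sequence.
#'
#' @param query A [Sequence-class] (non-empty).
#' @param db Named list of [Sequence-class] references.
#' @param matrix A [SubstitutionMatrix-class].
#' @param config A [SearchConfig-class].
#' @param table Optional prebuilt [KmerTable-class] of `db` (built on the
#'   fly when `NULL`).
#' @param estimator Optional prefitted [GumbelParams-class]; fitted from
#'   `config` when `NULL`.
#' @param meta Optional `data.frame` from [parseSwissProtHeader()], one row
#'   per reference in `db` order; adds gene/accession columns to the hits.
#' @return A `data.frame` of hits sorted by ascending E-value (ties broken
#'   by descending score, then refId), with columns `rank`, `refId`,
#'   `refName`, `score`, `evalue`, `identityPct`, `coveragePct` (identity
#'   excludes terminal gap columns; coverage is aligned query positions over
#'   query length, both in percent) and a list column `alignment`.  Zero
#'   rows when nothing survives the stages.
#' @export
runSearch <- function(query, db, matrix, config = searchConfig(),
                      table = NULL, estimator = NULL, meta = NULL) {
    if (length(query) == 0L) stop("query sequence is empty")
    if (length(db) == 0L) stop("database is empty")
    if (is.null(names(db))) names(db) <- paste0("seq", seq_along(db))
    pattern <- if (is.null(config@pattern))
        contiguousPattern(config@k) else config@pattern

    if (is.null(table))
        table <- buildKmerTable(db, k = config@k, pattern = pattern)

    matches <- if (is.na(config@kmerThreshold)) {
        matchKmers(table, query)
    } else {
        matchKmers(table, query, matrix, config@kmerThreshold)
    }
    seeds <- doubleHitFilter(matches, config@minHits)

    emptyHits <- data.frame(rank = integer(0), refId = integer(0),
                            refName = character(0), score = numeric(0),
                            evalue = numeric(0), identityPct = numeric(0),
                            coveragePct = numeric(0))
    if (nrow(seeds) == 0L) return(emptyHits)

    # ungapped X-drop extension per representative seed
    ungapped <- vapply(seq_len(nrow(seeds)), function(r) {
        alignmentScore(alignLocalUngapped(
            query, db[[seeds$refId[r]]], matrix,
            seed = c(seeds$queryPos[r], seeds$refPos[r]),
            xDrop = config@xDrop))
    }, 0)
    seeds <- seeds[ungapped >= config@ungappedThreshold, , drop = FALSE]
    if (nrow(seeds) == 0L) return(emptyHits)

    # banded gapped alignment around each surviving seed diagonal
    n1 <- length(query)
    alns <- vector("list", nrow(seeds))
    for (r in seq_len(nrow(seeds))) {
        ref <- db[[seeds$refId[r]]]
        dlo <- max(seeds$diagonal[r] - config@bandWidth, -n1)
        dhi <- min(seeds$diagonal[r] + config@bandWidth, length(ref))
        alns[[r]] <- alignBanded(query, ref, matrix,
                                 config@gapOpen, config@gapExtend,
                                 band = c(dlo, dhi), mode = "local",
                                 maxNumber = 1L)[[1L]]
    }
    scores <- vapply(alns, alignmentScore, 0)

    # best-scoring alignment per reference
    bestIdx <- vapply(split(seq_len(nrow(seeds)), seeds$refId),
                      function(idx) idx[which.max(scores[idx])], 0L)
    refIds <- seeds$refId[bestIdx]
    alns <- alns[bestIdx]
    scores <- scores[bestIdx]

    if (is.null(estimator)) {
        background <- config@background
        if (is.null(background)) {
            alph <- alphabet(query)
            background <- if (isProteinAlphabet(alph))
                standardProteinBackground(alph) else uniformBackground(alph)
        }
        estimator <- evalueEstimator(
            matrix, config@gapOpen, config@gapExtend, background,
            lenQ = length(query),
            lenDb = round(mean(vapply(db, length, 0L))),
            nSamples = config@evalueSamples, seed = config@seed)
    }
    lenDbTotal <- sum(vapply(db, length, 0L))
    ev <- eValue(estimator, scores, length(query), lenDbTotal)

    keep <- ev <= config@maxEvalue
    if (!any(keep)) return(emptyHits)
    refIds <- refIds[keep]; alns <- alns[keep]
    scores <- scores[keep]; ev <- ev[keep]

    ord <- order(ev, -scores, refIds)
    hits <- data.frame(
        rank = seq_along(ord),
        refId = refIds[ord],
        refName = names(db)[refIds[ord]],
        score = scores[ord],
        evalue = ev[ord],
        identityPct = 100 * vapply(alns[ord], getIdentity, 0,
                                   mode = "not_terminal"),
        coveragePct = 100 * vapply(alns[ord], getCoverage, 0,
                                   queryIndex = 1L,
                                   queryLength = length(query)))
    if (!is.null(meta)) {
        hits$gene <- meta$geneName[hits$refId]
        hits$accession <- meta$accession[hits$refId]
    }
    hits$alignment <- I(alns[ord])
    hits
}

#' Format search hits as a TSV report
#'
#' Columns: rank, gene, accession, E-value (two significant digits,
#' scientific), identity and coverage in percent (one decimal).  Gene falls
#' back to the reference name and accession to `NA` when no header metadata
#' was supplied.
#'
#' @param hits Hit table from [runSearch()].
#' @param file Optional path; when given the report is written there.
#' @return Character vector of report lines (header first), invisibly when
#'   written to a file.
#' @export
reportHits <- function(hits, file = NULL) {
    header <- paste(c("rank", "gene", "accession", "evalue",
                      "identity", "coverage"), collapse = "\t")
    gene <- if ("gene" %in% names(hits) && !all(is.na(hits$gene)))
        ifelse(is.na(hits$gene), hits$refName, hits$gene) else hits$refName
    accession <- if ("accession" %in% names(hits))
        hits$accession else rep(NA_character_, nrow(hits))
    lines <- c(header, if (nrow(hits)) {
        paste(hits$rank, gene, accession,
              sprintf("%.1e", hits$evalue),
              sprintf("%.1f", hits$identityPct),
              sprintf("%.1f", hits$coveragePct), sep = "\t")
    })
    if (!is.null(file)) {
        writeLines(lines, file)
        return(invisible(lines))
    }
    lines
}
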