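#' Alignment: aligned sequences plus a trace matrix
#'
#' An alignment of `n` sequences is stored as the sequences themselves plus
#' an `L x n` integer *trace* matrix: row `l` holds, for each sequence, the
#' 0-based position shown in alignment column `l`, or `-1` for a gap.  Every
#' trace row contains at least one non-gap entry, and within each sequence
#' the non-gap entries increase strictly down the rows.
#'
#' @slot sequences List of [Sequence-class] objects.
#' @slot trace `L x n` integer matrix (`-1` = gap).
#' @slot score Numeric alignment score (`NA` when not applicable).
#'
#' @seealso [renderAlignment()], [alignOptimal()]
#' @export
setClass("Alignment",
         representation(sequences = "list", trace = "matrix",
                        score = "numeric"))

setValidity("Alignment", function(object) {
    tr <- object@trace
    n <- length(object@sequences)
    if (ncol(tr) != n) return("trace must have one column per sequence")
    if (nrow(tr) > 0L && any(apply(tr, 1L, max) < 0L))
        return("every trace row needs at least one non-gap entry")
    for (s in seq_len(n)) {
        if (nrow(tr) && any(tr[, s] < -1L))
            return("trace entries must be >= -1")
        pos <- tr[, s]
        pos <- pos[pos >= 0L]
        if (length(pos) && max(pos) >= length(object@sequences[[s]]))
            return(sprintf("trace refers past the end of sequence %d", s))
        if (length(pos) > 1L && any(diff(pos) <= 0L))
            return(sprintf("positions of sequence %d are not strictly increasing", s))
    }
    TRUE
})

#' Construct an Alignment
#'
#' @param sequences List of [Sequence-class] objects.
#' @param trace `L x n` integer matrix of 0-based positions, `-1` for gaps.
#' @param score Optional numeric score.
#' @return An [Alignment-class].
#' @export
Alignment <- function(sequences, trace, score = NA_real_) {
    storage.mode(trace) <- "integer"
    new("Alignment", sequences = sequences, trace = trace,
        score = as.numeric(score))
}

#' Alignment accessors
#'
#' @param x An [Alignment-class].
#' @return `alignedSequences()`: the list of sequences;
#'   `alignmentTrace()`: the `L x n` trace matrix;
#'   `alignmentScore()`: the numeric score.
#' @export
setGeneric("alignedSequences", function(x) standardGeneric("alignedSequences"))

#' @rdname alignedSequences
#' @export
setMethod("alignedSequences", "Alignment", function(x) x@sequences)

#' @rdname alignedSequences
#' @export
setGeneric("alignmentTrace", function(x) standardGeneric("alignmentTrace"))

#' @rdname alignedSequences
#' @export
setMethod("alignmentTrace", "Alignment", function(x) x@trace)

#' @rdname alignedSequences
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))

#' @rdname alignedSequences
#' @export
setMethod("alignmentScore", "Alignment", function(x) x@score)

#' Render an alignment as gapped symbol strings
#'
#' Column `l` of string `s` shows the symbol at `trace[l, s]`, or `-` for a
#' gap.
#'
#' @param x An [Alignment-class].
#' @return Character vector, one gapped string per sequence.
#' @examples
#' a <- Alignment(list(encodeSequence("ACG", nucleotideAlphabet()),
#'                     encodeSequence("AG", nucleotideAlphabet())),
#'                rbind(c(0, 0), c(1, -1), c(2, 1)))
#' renderAlignment(a)   # "ACG" "A-G"
#' @export
renderAlignment <- function(x) {
    stopifnot(is(x, "Alignment"))
    vapply(seq_along(x@sequences), function(s) {
        sq <- x@sequences[[s]]
        syms <- sq@alphabet@symbols
        pos <- x@trace[, s]
        out <- rep("-", length(pos))
        ok <- pos >= 0L
        out[ok] <- syms[sq@codes[pos[ok] + 1L] + 1L]
        paste(out, collapse = "")
    }, "")
}

setMethod("show", "Alignment", function(object) {
    cat(sprintf("Alignment of %d sequence(s), %d column(s), score %s\n",
                length(object@sequences), nrow(object@trace),
                format(object@score)))
    if (nrow(object@trace) > 0L && nrow(object@trace) <= 200L)
        cat(paste(renderAlignment(object), collapse = "\n"), "\n")
})

# Rows of the trace that lie between the first and last column in which both
# sequences of a pairwise alignment are aligned (i.e. excluding terminal gap
# runs of either sequence).
nonTerminalRows <- function(trace) {
    spans <- apply(trace, 2L, function(p) {
        w <- which(p >= 0L)
        c(min(w), max(w))
    })
    lo <- max(spans[1L, ])
    hi <- min(spans[2L, ])
    if (lo > hi) integer(0) else lo:hi
}

#' Fraction of identical columns in a pairwise alignment
#'
#' A column is identical when both sequences are aligned (no gap) and carry
#' the same symbol code.  The denominator depends on `mode`: `"all"` counts
#' every alignment column, `"not_terminal"` (the default) excludes terminal
#' gap columns, and `"shortest"` divides by the length of the shorter
#' sequence.
#'
#' @param x A 2-sequence [Alignment-class].
#' @param mode Denominator mode.
#' @return A fraction in `[0, 1]`.
#' @export
getIdentity <- function(x, mode = c("not_terminal", "all", "shortest")) {
    stopifnot(is(x, "Alignment"))
    mode <- match.arg(mode)
    if (length(x@sequences) != 2L)
        stop("identity is defined for 2-sequence alignments")
    tr <- x@trace
    if (nrow(tr) == 0L) return(0)
    c1 <- x@sequences[[1L]]@codes
    c2 <- x@sequences[[2L]]@codes
    aligned <- which(tr[, 1L] >= 0L & tr[, 2L] >= 0L)
    nid <- sum(c1[tr[aligned, 1L] + 1L] == c2[tr[aligned, 2L] + 1L])
    denom <- switch(mode,
        all = nrow(tr),
        not_terminal = length(nonTerminalRows(tr)),
        shortest = min(length(c1), length(c2)))
    if (denom == 0L) return(0)
    nid / denom
}

#' Fraction of a query sequence covered by an alignment
#'
#' The number of positions of the query sequence that appear in the trace,
#' divided by the query length.
#'
#' @param x An [Alignment-class].
#' @param queryIndex Which aligned sequence is the query (default 1).
#' @param queryLength Full length of the query (defaults to the length of
#'   that sequence).
#' @return A fraction in `[0, 1]`.
#' @export
getCoverage <- function(x, queryIndex = 1L, queryLength = NULL) {
    stopifnot(is(x, "Alignment"))
    if (queryIndex < 1L || queryIndex > length(x@sequences))
        stop("'queryIndex' out of range")
    if (is.null(queryLength))
        queryLength <- length(x@sequences[[queryIndex]])
    if (queryLength == 0L) return(0)
    sum(x@trace[, queryIndex] >= 0L) / queryLength
}

#' Recompute the score of a pairwise alignment from its trace
#'
#' Sums substitution scores over aligned columns and charges each gap run of
#' length `L` a penalty `open + (L - 1) * extend`.  With
#' `terminalPenalty = FALSE` gap runs touching the first or last alignment
#' column are free.  Used to verify that reported aligner scores agree with
#' their traces.
#'
#' @param x A 2-sequence [Alignment-class].
#' @param matrix A [SubstitutionMatrix-class].
#' @param gapOpen,gapExtend Non-positive affine gap penalties.
#' @param terminalPenalty Charge terminal gap runs?
#' @return Numeric score.
#' @export
scoreFromTrace <- function(x, matrix, gapOpen, gapExtend,
                           terminalPenalty = TRUE) {
    stopifnot(is(x, "Alignment"), length(x@sequences) == 2L)
    gp <- checkGap(gapOpen, gapExtend)
    tr <- x@trace
    if (nrow(tr) == 0L) return(0)
    c1 <- x@sequences[[1L]]@codes
    c2 <- x@sequences[[2L]]@codes
    aligned <- tr[, 1L] >= 0L & tr[, 2L] >= 0L
    sub <- sum(matrix@scores[cbind(c1[tr[aligned, 1L] + 1L] + 1L,
                                   c2[tr[aligned, 2L] + 1L] + 1L)])
    gapcost <- 0
    for (s in 1:2) {
        r <- rle(tr[, s] < 0L)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (k in seq_along(r$values)) {
            if (!r$values[k]) next
            if (!terminalPenalty &&
                (starts[k] == 1L || ends[k] == nrow(tr))) next
            gapcost <- gapcost + gp["open"] + (r$lengths[k] - 1L) * gp["extend"]
        }
    }
    unname(sub + gapcost)
}

# Project a multi-sequence alignment onto sequences i and j, dropping
# columns where both are gaps.
projectPair <- function(x, i, j) {
    tr <- x@trace[, c(i, j), drop = FALSE]
    keep <- tr[, 1L] >= 0L | tr[, 2L] >= 0L
    Alignment(x@sequences[c(i, j)], tr[keep, , drop = FALSE])
}

#' Sum-of-pairs score of a multiple alignment
#'
#' Sum over all sequence pairs of the pairwise score induced by the MSA
#' (columns where both sequences are gaps are dropped for that pair).
#' Terminal gaps are free by default, matching the merge scoring of
#' [alignMultiple()].
#'
#' @inheritParams scoreFromTrace
#' @return Numeric score.
#' @export
sumOfPairsScore <- function(x, matrix, gapOpen, gapExtend,
                            terminalPenalty = FALSE) {
    n <- length(x@sequences)
    total <- 0
    for (i in seq_len(n - 1L))
        for (j in (i + 1L):n)
            total <- total + scoreFromTrace(projectPair(x, i, j), matrix,
                                            gapOpen, gapExtend,
                                            terminalPenalty)
    total
}
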