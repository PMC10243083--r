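#' MsaResult: a progressive multiple sequence alignment
#'
#' @slot alignment The final [Alignment-class] (every input sequence exactly
#'   once; every input residue appears in the trace exactly once).
#' @slot guideTree The `phylo` guide tree that ordered the merges.
#' @slot order Integer vector mapping guide-tree leaf order to input
#'   indices.
#' @seealso [alignMultiple()]
#' @export
setClass("MsaResult",
         representation(alignment = "Alignment", guideTree = "ANY",
                        order = "integer"))

#' MsaResult accessors
#'
#' @param x An [MsaResult-class].
#' @return The final alignment, the guide tree, or the leaf order.
#' @export
msaAlignment <- function(x) x@alignment

#' @rdname msaAlignment
#' @export
msaGuideTree <- function(x) x@guideTree

#' @rdname msaAlignment
#' @export
msaOrder <- function(x) x@order

setMethod("show", "MsaResult", function(object) {
    cat(sprintf("MsaResult: %d sequences, %d columns\n",
                length(object@alignment@sequences),
                nrow(object@alignment@trace)))
})

# Per-column symbol count matrix of a subalignment (gaps excluded).
columnCounts <- function(sequences, trace, q) {
    n <- nrow(trace)
    counts <- base::matrix(0, n, q)
    for (s in seq_along(sequences)) {
        pos <- trace[, s]
        ok <- pos >= 0L
        if (any(ok)) {
            idx <- cbind(which(ok), sequences[[s]]@codes[pos[ok] + 1L] + 1L)
            counts[idx] <- counts[idx] + 1
        }
    }
    counts
}

#' Progressive multiple sequence alignment
#'
#' Implements the classical progressive alignment scheme: sequences are
#' aligned in the order given by a guide tree (by default a UPGMA tree over
#' `1 - identity` pairwise distances).  At each internal node the two child
#' alignments are merged by an affine-gap global alignment of their columns,
#' where a column pair scores the mean of all pairwise substitution scores
#' between non-gap symbols (gap-symbol pairs contribute 0) and terminal
#' gaps are unpenalized.  Gaps inserted at earlier merges are never removed
#' ("once a gap, always a gap").
#'
#' @param sequences List (optionally named) of >= 2 [Sequence-class]
#'   objects over a common alphabet.
#' @param matrix A [SubstitutionMatrix-class].
#' @param gapOpen,gapExtend Non-positive affine gap penalties used both for
#'   guide-tree distances and the merges.
#' @param guideTree Optional `phylo` tree with exactly one tip per sequence
#'   (tip labels = sequence names); computed by [upgma()] when `NULL`.
#' @return An [MsaResult-class].  The alignment score is the column-merge
#'   score of the root join.
#' @export
alignMultiple <- function(sequences, matrix, gapOpen = -10, gapExtend = -1,
                          guideTree = NULL) {
    m <- length(sequences)
    if (m < 2L) stop("at least two sequences are required")
    alph <- alphabet(sequences[[1L]])
    for (s in sequences)
        if (!sameAlphabet(alphabet(s), alph))
            stop("all sequences must share one alphabet")
    gp <- checkGap(gapOpen, gapExtend)
    labels <- names(sequences)
    if (is.null(labels)) labels <- paste0("seq", seq_len(m))

    if (is.null(guideTree)) {
        guideTree <- upgma(distanceMatrixFromSequences(
            setNames(sequences, labels), matrix, gapOpen, gapExtend))
    }
    if (!inherits(guideTree, "phylo"))
        stop("guideTree must be a 'phylo' object")
    if (length(guideTree$tip.label) != m ||
        !setequal(guideTree$tip.label, labels))
        stop("guide tree tips must match the sequence names exactly")

    q <- alphabetSize(alph)
    S <- matrix@scores

    mergeTwo <- function(a, b) {
        # a, b: list(idx = input indices, trace = L x |idx| matrix)
        ca <- columnCounts(sequences[a$idx], a$trace, q)
        cb <- columnCounts(sequences[b$idx], b$trace, q)
        colScore <- (ca %*% S %*% t(cb)) /
            (length(a$idx) * length(b$idx))
        res <- gotoh_align_cpp(colScore, gp["open"], gp["extend"],
                               local = FALSE, termpen = FALSE,
                               banded = FALSE, dlo = 0L, dhi = 0L,
                               maxPaths = 1L)
        map <- res$traces[[1L]]             # rows: (colA or -1, colB or -1)
        L <- nrow(map)
        trace <- base::matrix(-1L, L, length(a$idx) + length(b$idx))
        selA <- map[, 1L] >= 0L
        selB <- map[, 2L] >= 0L
        trace[selA, seq_along(a$idx)] <- a$trace[map[selA, 1L] + 1L, ,
                                                 drop = FALSE]
        trace[selB, length(a$idx) + seq_along(b$idx)] <-
            b$trace[map[selB, 2L] + 1L, , drop = FALSE]
        list(idx = c(a$idx, b$idx), trace = trace, score = res$score)
    }

    edge <- guideTree$edge
    nTips <- length(guideTree$tip.label)
    buildNode <- function(node) {
        if (node <= nTips) {
            i <- match(guideTree$tip.label[node], labels)
            len <- length(sequences[[i]])
            return(list(idx = i,
                        trace = base::matrix(seq_len(len) - 1L, ncol = 1L),
                        score = NA_real_))
        }
        children <- edge[edge[, 1L] == node, 2L]
        sub <- buildNode(children[1L])
        for (ch in children[-1L]) sub <- mergeTwo(sub, buildNode(ch))
        sub
    }
    root <- nTips + 1L
    res <- buildNode(root)

    aln <- Alignment(sequences[res$idx], res$trace, score = res$score)
    new("MsaResult", alignment = aln, guideTree = guideTree,
        order = as.integer(res$idx))
}
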