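# Pairwise aligners: rigorous Gotoh (global/local), banded, gapped X-drop
# and ungapped X-drop seed extension.  All return Alignment objects whose
# traces satisfy the package-wide trace invariants; scores are exactly
# reproducible from the traces via scoreFromTrace().

# Turn kernel traces (L x 2, 0-based, -1 = gap) into Alignment objects,
# dropping duplicates and capping at maxNumber.
tracesToAlignments <- function(s1, s2, res, maxNumber) {
    traces <- res$traces
    keys <- vapply(traces, function(m) paste(m, collapse = ","), "")
    traces <- traces[!duplicated(keys)]
    if (length(traces) > maxNumber) traces <- traces[seq_len(maxNumber)]
    lapply(traces, function(m) {
        storage.mode(m) <- "integer"
        Alignment(list(s1, s2), m, score = res$score)
    })
}

#' Rigorous optimal pairwise alignment (Gotoh)
#'
#' Explores the complete dynamic-programming table: global mode is
#' Needleman-Wunsch-Gotoh, local mode Smith-Waterman-Gotoh, both with
#' affine gaps (a gap of length L costs `gapOpen + (L-1) * gapExtend`).
#' All co-optimal alignments are enumerated up to `maxNumber`, in a
#' deterministic order (diagonal moves preferred over a gap in the second
#' sequence, over a gap in the first).
#'
#' @param s1,s2 [Sequence-class] objects over the matrix alphabets.
#' @param matrix A [SubstitutionMatrix-class].
#' @param gapOpen,gapExtend Non-positive affine gap penalties.
#' @param mode `"global"` or `"local"`.
#' @param terminalPenalty In global mode, charge terminal gaps?  With
#'   `FALSE`, end gaps are free (semi-global alignment).
#' @param maxNumber Cap on the number of co-optimal alignments returned.
#' @return List of [Alignment-class] objects sharing the optimal score.  A
#'   local alignment with no positive-scoring pair is the empty alignment
#'   with score 0; a global alignment of an empty sequence is an all-gap
#'   alignment.
#' @examples
#' alph <- nucleotideAlphabet()
#' m <- uniformSubstitutionMatrix(alph, 1, -1)
#' a <- alignOptimal(encodeSequence("ACGT", alph),
#'                   encodeSequence("AGT", alph), m,
#'                   gapOpen = -2, gapExtend = -1)[[1]]
#' renderAlignment(a)
#' @export
alignOptimal <- function(s1, s2, matrix, gapOpen = -10, gapExtend = -1,
                         mode = c("global", "local"),
                         terminalPenalty = TRUE, maxNumber = 1000L) {
    mode <- match.arg(mode)
    checkAlphabets(s1, s2, matrix)
    gp <- checkGap(gapOpen, gapExtend)
    res <- gotoh_align_cpp(simMatrix(s1, s2, matrix),
                           gp["open"], gp["extend"],
                           local = mode == "local",
                           termpen = terminalPenalty,
                           banded = FALSE, dlo = 0L, dhi = 0L,
                           maxPaths = as.integer(maxNumber))
    tracesToAlignments(s1, s2, res, maxNumber)
}

#' Banded pairwise alignment
#'
#' Restricts the dynamic programming to the diagonal band
#' `band[1] <= j - i <= band[2]` (diagonals are reference position minus
#' query position), which bounds the number of gaps allowed in either
#' sequence.  With a band covering all diagonals the result equals
#' [alignOptimal()].
#'
#' @inheritParams alignOptimal
#' @param band Integer pair `c(d_low, d_high)`, `d_low <= d_high`.
#' @return List of co-optimal [Alignment-class] objects within the band.
#' @export
alignBanded <- function(s1, s2, matrix, gapOpen = -10, gapExtend = -1,
                        band, mode = c("global", "local"),
                        maxNumber = 1000L) {
    mode <- match.arg(mode)
    checkAlphabets(s1, s2, matrix)
    gp <- checkGap(gapOpen, gapExtend)
    dlo <- as.integer(band[1L]); dhi <- as.integer(band[2L])
    if (dlo > dhi) stop("band must satisfy d_low <= d_high")
    n1 <- length(s1); n2 <- length(s2)
    if (dhi < -n1 || dlo > n2)
        stop("band does not intersect the alignment table")
    if (mode == "global") {
        d0 <- 0L; dend <- n2 - n1
        if (dlo > min(d0, dend) || dhi < max(d0, dend))
            stop("global banded alignment requires the band to contain ",
                 "diagonals 0 and len(s2) - len(s1)")
    }
    res <- gotoh_align_cpp(simMatrix(s1, s2, matrix),
                           gp["open"], gp["extend"],
                           local = mode == "local", termpen = TRUE,
                           banded = TRUE, dlo = dlo, dhi = dhi,
                           maxPaths = as.integer(maxNumber))
    tracesToAlignments(s1, s2, res, maxNumber)
}

#' Ungapped seed extension with X-drop
#'
#' Extends the diagonal through the seed pair left and right independently.
#' Each direction accumulates substitution scores and stops as soon as the
#' running score drops more than `xDrop` below its running maximum; the
#' maximal-scoring ungapped segment containing the seed is returned.  With
#' `xDrop = Inf` this is the best diagonal segment through the seed.
#'
#' @inheritParams alignOptimal
#' @param seed Integer pair `c(queryPos, refPos)` (0-based) inside both
#'   sequences.
#' @param xDrop Positive drop-off threshold (may be `Inf`).
#' @return A single gap-free [Alignment-class] through the seed.
#' @export
alignLocalUngapped <- function(s1, s2, matrix, seed, xDrop = Inf) {
    checkAlphabets(s1, s2, matrix)
    if (!is.numeric(xDrop) || length(xDrop) != 1L || xDrop <= 0)
        stop("'xDrop' must be a positive number (possibly Inf)")
    n1 <- length(s1); n2 <- length(s2)
    qp <- as.integer(seed[1L]); rp <- as.integer(seed[2L])
    if (qp < 0L || qp >= n1 || rp < 0L || rp >= n2)
        stop("seed position out of range")
    S <- matrix@scores
    c1 <- s1@codes; c2 <- s2@codes
    s0 <- S[c1[qp + 1L] + 1L, c2[rp + 1L] + 1L]

    extend <- function(sc) {
        # best X-drop prefix of the score vector sc (scanned left to right)
        if (length(sc) == 0L) return(c(len = 0L, score = 0))
        run <- cumsum(sc)
        runmax <- pmax(cummax(run), 0)
        dropped <- which(runmax - run > xDrop)
        lim <- if (length(dropped)) dropped[1L] - 1L else length(run)
        if (lim == 0L) return(c(len = 0L, score = 0))
        best <- max(run[seq_len(lim)])
        if (best <= 0) return(c(len = 0L, score = 0))
        c(len = which.max(run[seq_len(lim)]), score = best)
    }

    tR <- min(n1 - 1L - qp, n2 - 1L - rp)
    scR <- if (tR >= 1L)
        S[cbind(c1[(qp + 2L):(qp + 1L + tR)] + 1L,
                c2[(rp + 2L):(rp + 1L + tR)] + 1L)] else numeric(0)
    tL <- min(qp, rp)
    scL <- if (tL >= 1L)
        S[cbind(c1[qp:(qp - tL + 1L)] + 1L,
                c2[rp:(rp - tL + 1L)] + 1L)] else numeric(0)
    right <- extend(scR)
    left <- extend(scL)
    qStart <- qp - left["len"]
    len <- left["len"] + 1L + right["len"]
    trace <- cbind(qStart + seq_len(len) - 1L,
                   (rp - left["len"]) + seq_len(len) - 1L)
    Alignment(list(s1, s2), trace,
              score = s0 + left["score"] + right["score"])
}

#' Gapped seed extension with X-drop
#'
#' Grows a gapped alignment outward from the seed in both directions with
#' the Gotoh recursion; cells whose best score falls more than `xDrop`
#' below the best score seen so far are pruned and never extended.  With
#' `xDrop = Inf`, the score equals the rigorous local alignment score
#' whenever the optimal local alignment passes through the seed pair.
#'
#' @inheritParams alignLocalUngapped
#' @param gapOpen,gapExtend Non-positive affine gap penalties.
#' @return A single [Alignment-class] through the seed.
#' @export
alignLocalGapped <- function(s1, s2, matrix, gapOpen = -10, gapExtend = -1,
                             seed, xDrop = Inf) {
    checkAlphabets(s1, s2, matrix)
    gp <- checkGap(gapOpen, gapExtend)
    if (!is.numeric(xDrop) || length(xDrop) != 1L || xDrop <= 0)
        stop("'xDrop' must be a positive number (possibly Inf)")
    n1 <- length(s1); n2 <- length(s2)
    qp <- as.integer(seed[1L]); rp <- as.integer(seed[2L])
    if (qp < 0L || qp >= n1 || rp < 0L || rp >= n2)
        stop("seed position out of range")
    S <- simMatrix(s1, s2, matrix)
    s0 <- S[qp + 1L, rp + 1L]

    fwd <- xdrop_extend_cpp(S[(qp + 1L):n1, (rp + 1L):n2, drop = FALSE],
                            gp["open"], gp["extend"], xDrop)
    bwd <- xdrop_extend_cpp(S[(qp + 1L):1L, (rp + 1L):1L, drop = FALSE],
                            gp["open"], gp["extend"], xDrop)

    fwdTr <- fwd$trace
    fwdTr[, 1L] <- ifelse(fwdTr[, 1L] >= 0L, fwdTr[, 1L] + qp, -1L)
    fwdTr[, 2L] <- ifelse(fwdTr[, 2L] >= 0L, fwdTr[, 2L] + rp, -1L)
    bwdTr <- bwd$trace
    bwdTr[, 1L] <- ifelse(bwdTr[, 1L] >= 0L, qp - bwdTr[, 1L], -1L)
    bwdTr[, 2L] <- ifelse(bwdTr[, 2L] >= 0L, rp - bwdTr[, 2L], -1L)
    # backward trace runs seed -> start; flip and drop its seed column
    bwdTr <- bwdTr[rev(seq_len(nrow(bwdTr))), , drop = FALSE]
    trace <- rbind(bwdTr[-nrow(bwdTr), , drop = FALSE], fwdTr)
    Alignment(list(s1, s2), trace,
              score = fwd$score + bwd$score - s0)
}
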