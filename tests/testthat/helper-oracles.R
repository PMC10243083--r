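# Independent oracles and fixture builders used across the test files.
# Oracles deliberately avoid the package's DP kernels: they enumerate
# alignments exhaustively or scan quadratically.

randomSeq <- function(alphabet, n, seed) {
    q <- alphabetSize(alphabet)
    Sequence(withSeed20(seed, sample.int(q, n, replace = TRUE)) - 1L,
             alphabet)
}

# local seeded sampling without touching the caller's RNG
withSeed20 <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

# 20-standard-residue protein sequence (no ambiguity codes / stop)
randomProteinSeq <- function(n, seed) {
    p <- proteinAlphabet()
    codes <- withSeed20(seed, sample.int(20L, n, replace = TRUE)) - 1L
    Sequence(codes, p)
}

# Exhaustive global alignment score: enumerate every monotone trace and
# score it with the run-based affine rule (gap run of length L costs
# open + (L-1) * extend; terminal runs free when termpen = FALSE).
bruteGlobalScore <- function(c1, c2, S, open, ext, termpen = TRUE) {
    n1 <- length(c1); n2 <- length(c2)
    best <- -Inf
    moves <- character(n1 + n2)
    rec <- function(i, j, depth) {
        if (i == n1 && j == n2) {
            mv <- moves[seq_len(depth)]
            sc <- 0
            r <- rle(mv)
            ends <- cumsum(r$lengths)
            for (k in seq_along(r$values)) {
                v <- r$values[k]
                if (v == "D") next
                terminal <- (ends[k] - r$lengths[k] == 0L) ||
                    (ends[k] == depth)
                if (!(terminal && !termpen))
                    sc <- sc + open + (r$lengths[k] - 1L) * ext
            }
            ii <- 0L; jj <- 0L
            for (m in mv) {
                if (m == "D") {
                    ii <- ii + 1L; jj <- jj + 1L
                    sc <- sc + S[c1[ii] + 1L, c2[jj] + 1L]
                } else if (m == "U") ii <- ii + 1L
                else jj <- jj + 1L
            }
            best <<- max(best, sc)
            return(invisible())
        }
        if (i < n1 && j < n2) {
            moves[depth + 1L] <<- "D"; rec(i + 1L, j + 1L, depth + 1L)
        }
        if (i < n1) { moves[depth + 1L] <<- "U"; rec(i + 1L, j, depth + 1L) }
        if (j < n2) { moves[depth + 1L] <<- "L"; rec(i, j + 1L, depth + 1L) }
    }
    rec(0L, 0L, 0L)
    best
}

# Exhaustive local score: best global score over all substring pairs, or 0.
bruteLocalScore <- function(c1, c2, S, open, ext) {
    best <- 0
    n1 <- length(c1); n2 <- length(c2)
    for (i1 in seq_len(n1)) for (i2 in i1:n1)
        for (j1 in seq_len(n2)) for (j2 in j1:n2)
            best <- max(best, bruteGlobalScore(c1[i1:i2], c2[j1:j2], S,
                                               open, ext))
    best
}

# Biostrings rigorous aligner as an independent cross-check; gap
# conventions converted (Biostrings charges opening + L * extension).
biostringsScore <- function(s1, s2, submat, open, ext, local = FALSE) {
    m <- scoreMatrix(submat)
    Biostrings::pairwiseAlignment(
        Biostrings::AAString(decodeSequence(s1)),
        Biostrings::AAString(decodeSequence(s2)),
        substitutionMatrix = m,
        gapOpening = -(open - ext), gapExtension = -ext,
        type = if (local) "local" else "global", scoreOnly = TRUE)
}

# Quadratic all-pairs k-mer match scan (exact or score-thresholded),
# honoring a spaced pattern.  Compares every query window with every
# database window directly; vectorized over database positions.
bruteKmerMatches <- function(dbseqs, query, pattern, S = NULL,
                             threshold = NULL) {
    span <- patternSpan(pattern)
    inf <- which(pattern@mask)
    k <- length(inf)
    qc <- symbolCodes(query)
    nq <- length(qc) - span + 1L
    res <- NULL
    for (r in seq_along(dbseqs)) {
        rc <- symbolCodes(dbseqs[[r]])
        nr <- length(rc) - span + 1L
        if (nq < 1L || nr < 1L) next
        dbm <- vapply(inf, function(o) rc[o:(o + nr - 1L)], integer(nr))
        if (nr == 1L) dbm <- matrix(dbm, nrow = 1L)
        for (qp in seq_len(nq) - 1L) {
            a <- qc[qp + inf]
            ok <- if (is.null(threshold)) {
                colSums(t(dbm) == a) == k
            } else {
                sc <- vapply(seq_len(k),
                             function(t) S[a[t] + 1L, dbm[, t] + 1L],
                             numeric(nr))
                if (nr == 1L) sc <- matrix(sc, nrow = 1L)
                rowSums(sc) >= threshold
            }
            w <- which(ok)
            if (length(w))
                res <- rbind(res, cbind(qp, r, w - 1L))
        }
    }
    if (is.null(res))
        return(data.frame(queryPos = integer(0), refId = integer(0),
                          refPos = integer(0)))
    res <- res[order(res[, 1L], res[, 2L], res[, 3L]), , drop = FALSE]
    data.frame(queryPos = as.integer(res[, 1L]),
               refId = as.integer(res[, 2L]),
               refPos = as.integer(res[, 3L]))
}

# Best ungapped diagonal segment through a seed: quadratic scan over all
# (start, end) pairs containing the seed.
bruteDiagonalSegment <- function(s1, s2, submat, seed) {
    S <- scoreMatrix(submat)
    c1 <- symbolCodes(s1); c2 <- symbolCodes(s2)
    qp <- seed[1L]; rp <- seed[2L]
    back <- min(qp, rp)
    fwd <- min(length(c1) - 1L - qp, length(c2) - 1L - rp)
    best <- -Inf
    for (a in 0:back) for (b in 0:fwd) {
        idx <- (-a):b
        best <- max(best, sum(S[cbind(c1[qp + idx + 1L] + 1L,
                                      c2[rp + idx + 1L] + 1L)]))
    }
    best
}

# every Alignment produced anywhere must satisfy these structural rules
expectValidTrace <- function(a) {
    tr <- alignmentTrace(a)
    expect_true(ncol(tr) == length(alignedSequences(a)))
    if (nrow(tr) == 0L) return(invisible())
    expect_true(all(apply(tr, 1L, max) >= 0L))
    for (s in seq_len(ncol(tr))) {
        pos <- tr[, s][tr[, s] >= 0L]
        expect_true(all(pos < length(alignedSequences(a)[[s]])))
        if (length(pos) > 1L) expect_true(all(diff(pos) > 0L))
    }
    invisible()
}
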