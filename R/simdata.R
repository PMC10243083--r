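# Seeded generators for synthetic sequences, mutated homologs and additive
# distance matrices.  All generators are pure functions of (parameters,
# seed); no global RNG state leaks in or out.

#' Random sequence from a background distribution
#'
#' @param alphabet Target [Alphabet-class].
#' @param length Sequence length (>= 0).
#' @param background Named probability vector over the alphabet (default
#'   uniform).
#' @param seed RNG seed.
#' @return A [Sequence-class].
#' @export
randomSequence <- function(alphabet, length, background = NULL, seed = 1L) {
    if (is.null(background)) background <- uniformBackground(alphabet)
    checkBackground(background, alphabet)
    q <- alphabetSize(alphabet)
    codes <- withSeed(seed,
        sample.int(q, length, replace = TRUE, prob = background) - 1L)
    Sequence(codes, alphabet)
}

#' Mutate a sequence under a simple substitution/indel model
#'
#' Each position independently suffers an indel event with probability
#' `indelRate` (insertion or deletion with equal probability, length
#' `1 + Geometric(indelGeomProb)`), and a substitution with probability
#' `substitutionRate` (replacement drawn from `background`, renormalized
#' without the original symbol).  The true alignment of the original and the
#' mutant is returned alongside, so simulation-based tests have a ground
#' truth to compare recovered alignments against.
#'
#' @param x The original [Sequence-class].
#' @param substitutionRate,indelRate Per-site event probabilities in
#'   `[0, 1]`.
#' @param indelGeomProb Success probability of the geometric indel length
#'   distribution.
#' @param background Distribution of substituted/inserted symbols (default
#'   uniform over the alphabet).
#' @param seed RNG seed.
#' @return `list(sequence = mutant, alignment = true Alignment of
#'   (original, mutant))`.
#' @export
mutateSequence <- function(x, substitutionRate = 0, indelRate = 0,
                           indelGeomProb = 0.5, background = NULL,
                           seed = 1L) {
    stopifnot(is(x, "Sequence"),
              substitutionRate >= 0, substitutionRate <= 1,
              indelRate >= 0, indelRate <= 1)
    alph <- alphabet(x)
    q <- alphabetSize(alph)
    if (is.null(background)) background <- uniformBackground(alph)
    checkBackground(background, alph)
    orig <- x@codes
    n <- length(orig)

    res <- withSeed(seed, {
        out <- integer(0)
        tr1 <- integer(0)   # original positions (or -1)
        tr2 <- integer(0)   # mutant positions (or -1)
        i <- 0L
        while (i < n) {
            if (indelRate > 0 && runif(1) < indelRate) {
                len <- 1L + rgeom(1L, indelGeomProb)
                if (runif(1) < 0.5) {          # deletion of len sites
                    len <- min(len, n - i)
                    tr1 <- c(tr1, i:(i + len - 1L))
                    tr2 <- c(tr2, rep(-1L, len))
                    i <- i + len
                    next
                } else {                        # insertion before site i
                    ins <- sample.int(q, len, replace = TRUE,
                                      prob = background) - 1L
                    tr1 <- c(tr1, rep(-1L, len))
                    tr2 <- c(tr2, length(out) + seq_len(len) - 1L)
                    out <- c(out, ins)
                }
            }
            code <- orig[i + 1L]
            if (substitutionRate > 0 && runif(1) < substitutionRate) {
                p <- background
                p[code + 1L] <- 0
                if (sum(p) == 0) p <- rep(1, q) * (seq_len(q) != code + 1L)
                code <- sample.int(q, 1L, prob = p) - 1L
            }
            tr1 <- c(tr1, i)
            tr2 <- c(tr2, length(out))
            out <- c(out, code)
            i <- i + 1L
        }
        list(out = out, tr1 = tr1, tr2 = tr2)
    })
    mutant <- Sequence(res$out, alph)
    aln <- Alignment(list(x, mutant), cbind(res$tr1, res$tr2))
    list(sequence = mutant, alignment = aln)
}

#' Random additive distance matrix from a random tree
#'
#' Generates a random binary tree with positive branch lengths over `m`
#' leaves (uniform random joins, branch lengths `Uniform(0.5, 2)`) and
#' returns the matrix of leaf-to-leaf path lengths, which is additive by
#' construction and satisfies the four-point condition.  The generating
#' tree is returned in Newick form for topology checks.
#'
#' @param m Number of leaves (>= 3), or a `phylo` tree whose path lengths
#'   should be used directly.
#' @param seed RNG seed.
#' @return `list(d = labeled distance matrix, newick = generating tree)`.
#' @export
makeAdditiveMatrix <- function(m, seed = 1L) {
    if (inherits(m, "phylo")) {
        d <- cophenetic(m)
        return(list(d = d[m$tip.label, m$tip.label],
                    newick = toNewick(m)))
    }
    m <- as.integer(m)
    if (m < 3L) stop("at least three leaves are required")
    withSeed(seed, {
        labels <- paste0("t", seq_len(m))
        # per active cluster: distances from its root to each of its leaves
        depth <- lapply(labels, function(l) setNames(0, l))
        nwk <- labels
        d <- base::matrix(0, m, m, dimnames = list(labels, labels))
        while (length(depth) > 1L) {
            pick <- sort(sample.int(length(depth), 2L))
            i <- pick[1L]; j <- pick[2L]
            li <- runif(1, 0.5, 2)
            lj <- runif(1, 0.5, 2)
            di <- depth[[i]] + li
            dj <- depth[[j]] + lj
            for (a in names(di))
                for (b in names(dj))
                    d[a, b] <- d[b, a] <- di[[a]] + dj[[b]]
            merged <- sprintf("(%s:%s,%s:%s)", nwk[i], fmtLen(li),
                              nwk[j], fmtLen(lj))
            keep <- setdiff(seq_along(depth), c(i, j))
            depth <- c(depth[keep], list(c(di, dj)))
            nwk <- c(nwk[keep], merged)
        }
        list(d = d, newick = paste0(nwk, ";"))
    })
}
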