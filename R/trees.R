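# Distance-based guide trees.  Trees are represented as ape "phylo"
# objects; UPGMA and neighbor-joining are implemented here, Newick
# serialization is delegated to ape behind a validating wrapper.

checkDistanceMatrix <- function(d, minSize = 2L) {
    if (inherits(d, "dist")) d <- as.matrix(d)
    if (!is.matrix(d) || nrow(d) != ncol(d))
        stop("distance matrix must be square")
    if (nrow(d) < minSize)
        stop(sprintf("at least %d taxa are required", minSize))
    if (any(d < 0)) stop("distances must be non-negative")
    if (max(abs(d - t(d))) > 1e-9)
        stop("distance matrix must be symmetric")
    if (any(abs(diag(d)) > 1e-9))
        stop("distance matrix must have a zero diagonal")
    if (is.null(rownames(d))) rownames(d) <- paste0("t", seq_len(nrow(d)))
    dimnames(d) <- list(rownames(d), rownames(d))
    d
}

# lexicographically smallest (i, j), i < j, attaining the minimum of the
# upper triangle of m (deterministic agglomeration tie-break)
argminPair <- function(m) {
    n <- nrow(m)
    best <- Inf; bi <- bj <- 0L
    for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
            if (m[i, j] < best - 1e-12) {
                best <- m[i, j]; bi <- i; bj <- j
            }
        }
    }
    c(bi, bj)
}

#' UPGMA hierarchical clustering
#'
#' Average-linkage agglomeration of a distance matrix into a rooted,
#' ultrametric binary tree: every leaf is at the same distance from the
#' root, and cluster merge heights are non-decreasing.  Ties are broken
#' towards the lowest index pair, making the tree deterministic.
#'
#' @param d Symmetric non-negative distance matrix (or `dist`) with a zero
#'   diagonal; row names are used as leaf labels.
#' @return An [ape::read.tree()]-style `phylo` tree with branch lengths.
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' toNewick(upgma(d))   # "((A:1,B:1):1,C:2);"
#' @export
upgma <- function(d) {
    d <- checkDistanceMatrix(d, minSize = 2L)
    labels <- rownames(d)
    nwk <- labels
    height <- numeric(length(labels))
    size <- rep(1L, length(labels))
    D <- d
    while (length(nwk) > 1L) {
        ij <- argminPair(D)
        i <- ij[1L]; j <- ij[2L]
        h <- D[i, j] / 2
        merged <- sprintf("(%s:%s,%s:%s)", nwk[i], fmtLen(h - height[i]),
                          nwk[j], fmtLen(h - height[j]))
        newRow <- (size[i] * D[i, ] + size[j] * D[j, ]) / (size[i] + size[j])
        # the merged cluster takes slot i; slot j disappears
        D[i, ] <- newRow; D[, i] <- newRow; D[i, i] <- 0
        D <- D[-j, -j, drop = FALSE]
        nwk[i] <- merged; nwk <- nwk[-j]
        height[i] <- h; height <- height[-j]
        size[i] <- size[i] + size[j]; size <- size[-j]
    }
    fromNewick(paste0(nwk, ";"))
}

#' Neighbor-joining tree reconstruction
#'
#' Saitou-Nei agglomeration by the Q criterion.  For an additive distance
#' matrix the leaf-to-leaf path lengths of the result reproduce the input
#' exactly.  The returned tree is rooted arbitrarily at the final three-way
#' join (so the root has three children); negative branch lengths are kept
#' as computed.
#'
#' @inheritParams upgma
#' @return A `phylo` tree.
#' @export
neighborJoining <- function(d) {
    d <- checkDistanceMatrix(d, minSize = 3L)
    nwk <- rownames(d)
    D <- d
    while (length(nwk) > 3L) {
        r <- nrow(D)
        rs <- rowSums(D)
        Q <- (r - 2) * D - outer(rs, rs, "+")
        diag(Q) <- Inf
        ij <- argminPair(Q)
        i <- ij[1L]; j <- ij[2L]
        li <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
        lj <- D[i, j] - li
        merged <- sprintf("(%s:%s,%s:%s)", nwk[i], fmtLen(li),
                          nwk[j], fmtLen(lj))
        newRow <- (D[i, ] + D[j, ] - D[i, j]) / 2
        D[i, ] <- newRow; D[, i] <- newRow; D[i, i] <- 0
        D <- D[-j, -j, drop = FALSE]
        nwk[i] <- merged; nwk <- nwk[-j]
    }
    la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    fromNewick(sprintf("(%s:%s,%s:%s,%s:%s);",
                       nwk[1L], fmtLen(la), nwk[2L], fmtLen(lb),
                       nwk[3L], fmtLen(lc)))
}

#' Newick serialization
#'
#' `toNewick()` renders a `phylo` tree as a Newick string (nested
#' parentheses, `:`-prefixed branch lengths, `;` terminator);
#' `fromNewick()` parses one, rejecting unbalanced parentheses, a missing
#' terminator or a dangling `:` with an error that names the position.
#' Round-tripping preserves topology, labels and branch lengths.
#'
#' @param tree A `phylo` tree.
#' @return `toNewick()`: a single string; `fromNewick()`: a `phylo` tree.
#' @export
toNewick <- function(tree) {
    stopifnot(inherits(tree, "phylo"))
    ape::write.tree(tree)
}

#' @rdname toNewick
#' @param text A Newick string.
#' @export
fromNewick <- function(text) {
    stopifnot(is.character(text), length(text) == 1L)
    chars <- strsplit(text, "", fixed = TRUE)[[1L]]
    depth <- 0L
    for (p in seq_along(chars)) {
        if (chars[p] == "(") depth <- depth + 1L
        if (chars[p] == ")") {
            depth <- depth - 1L
            if (depth < 0L)
                stop(sprintf("unbalanced ')' at position %d", p))
        }
        if (chars[p] == ":" &&
            (p == length(chars) ||
             !grepl("^[-+0-9.eE]", chars[p + 1L])))
            stop(sprintf("dangling ':' at position %d", p))
    }
    if (depth != 0L)
        stop(sprintf("unbalanced '(' (%d unclosed) in Newick string", depth))
    if (!grepl(";\\s*$", text))
        stop("Newick string must end with ';'")
    tree <- ape::read.tree(text = text)
    if (is.null(tree)) stop("failed to parse Newick string")
    tree
}

#' Pairwise distance matrix from sequences
#'
#' Guide-tree distances: `d[i, j] = 1 - identity` of the rigorous global
#' alignment of sequences i and j (identity mode `"all"`), a bounded
#' dissimilarity that is 0 for identical and 1 for completely dissimilar
#' sequences.
#'
#' @param sequences List (optionally named) of [Sequence-class] objects.
#' @param matrix A [SubstitutionMatrix-class].
#' @param gapOpen,gapExtend Non-positive affine gap penalties.
#' @return Labeled symmetric distance matrix.
#' @export
distanceMatrixFromSequences <- function(sequences, matrix,
                                        gapOpen = -10, gapExtend = -1) {
    m <- length(sequences)
    if (m < 2L) stop("at least two sequences are required")
    labels <- names(sequences)
    if (is.null(labels)) labels <- paste0("seq", seq_len(m))
    d <- base::matrix(0, m, m, dimnames = list(labels, labels))
    for (i in seq_len(m - 1L)) {
        for (j in (i + 1L):m) {
            a <- alignOptimal(sequences[[i]], sequences[[j]], matrix,
                              gapOpen, gapExtend, mode = "global",
                              maxNumber = 1L)[[1L]]
            d[i, j] <- d[j, i] <- 1 - getIdentity(a, mode = "all")
        }
    }
    d
}
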