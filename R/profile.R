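#' SequenceProfile: per-position symbol counts of an alignment
#'
#' Stores the position frequency matrix (PFM): an `n x k` matrix of symbol
#' occurrence counts `C_S` per alignment column (`n` = alignment length,
#' `k` = alphabet size), together with the number of gaps per column.  At
#' every position the symbol counts plus the gap count equal the number of
#' aligned sequences.  Probability (PPM) and log-odds (PWM) matrices, the
#' consensus, and sequence probabilities/scores are derived from it.
#'
#' @slot counts `n x k` integer PFM.
#' @slot gaps Integer vector of per-position gap counts.
#' @slot alphabet The [Alphabet-class].
#' @seealso [sequenceProfile()], [probabilityMatrix()], [logOddsMatrix()],
#'   [toConsensus()]
#' @export
setClass("SequenceProfile",
         representation(counts = "matrix", gaps = "integer",
                        alphabet = "Alphabet"))

setValidity("SequenceProfile", function(object) {
    if (ncol(object@counts) != alphabetSize(object@alphabet))
        return("PFM must have one column per alphabet symbol")
    if (length(object@gaps) != nrow(object@counts))
        return("gap vector length must equal the number of positions")
    if (any(object@counts < 0) || any(object@gaps < 0))
        return("counts must be non-negative")
    TRUE
})

#' @rdname alphabetSymbols
#' @export
setMethod("alphabet", "SequenceProfile", function(x) x@alphabet)

#' Profile accessors
#'
#' @param x A [SequenceProfile-class].
#' @return `positionCounts()`: the `n x k` PFM; `gapCounts()`: per-position
#'   gap counts.
#' @export
positionCounts <- function(x) x@counts

#' @rdname positionCounts
#' @export
gapCounts <- function(x) x@gaps

setMethod("show", "SequenceProfile", function(object) {
    cat(sprintf("SequenceProfile: %d position(s) over %d symbols\n",
                nrow(object@counts), ncol(object@counts)))
})

#' Build a sequence profile from an alignment
#'
#' `counts[i, S]` is the number of sequences showing symbol `S` in
#' alignment column `i`; `gaps[i]` the number of gap entries there.
#'
#' @param x An [Alignment-class] (>= 1 sequence, common alphabet).
#' @return A [SequenceProfile-class].
#' @examples
#' alph <- nucleotideAlphabet()
#' a <- Alignment(list(encodeSequence("ACG", alph),
#'                     encodeSequence("AG", alph)),
#'                rbind(c(0, 0), c(1, -1), c(2, 1)))
#' positionCounts(sequenceProfile(a))
#' @export
sequenceProfile <- function(x) {
    stopifnot(is(x, "Alignment"), length(x@sequences) >= 1L)
    alph <- alphabet(x@sequences[[1L]])
    for (s in x@sequences)
        if (!sameAlphabet(alphabet(s), alph))
            stop("all aligned sequences must share one alphabet")
    q <- alphabetSize(alph)
    n <- nrow(x@trace)
    counts <- matrix(0L, n, q,
                     dimnames = list(NULL, alphabetSymbols(alph)))
    gaps <- integer(n)
    for (s in seq_along(x@sequences)) {
        pos <- x@trace[, s]
        gap <- pos < 0L
        gaps <- gaps + as.integer(gap)
        if (any(!gap)) {
            sym <- x@sequences[[s]]@codes[pos[!gap] + 1L] + 1L
            idx <- cbind(which(!gap), sym)
            counts[idx] <- counts[idx] + 1L
        }
    }
    new("SequenceProfile", counts = counts, gaps = gaps, alphabet = alph)
}

#' Position probability matrix (PPM) with pseudocounts
#'
#' Each entry is `P(S) = (C_S + c_p / k) / (sum_i C_i + c_p)` where `c_p` is
#' the pseudocount and `k` the alphabet size; every row sums to 1.  Gap
#' counts never enter the probabilities.
#'
#' @param x A [SequenceProfile-class].
#' @param pseudocount Non-negative pseudocount `c_p`.
#' @return `n x k` probability matrix.
#' @export
probabilityMatrix <- function(x, pseudocount = 0) {
    stopifnot(is(x, "SequenceProfile"), pseudocount >= 0)
    k <- ncol(x@counts)
    denom <- rowSums(x@counts) + pseudocount
    if (any(denom == 0))
        stop("position with no symbol counts and zero pseudocount")
    (x@counts + pseudocount / k) / denom
}

#' Position weight matrix (PWM): log-odds scores
#'
#' `W(S) = log2(P(S) / B_S)` with background frequencies `B`.  Entries with
#' `P(S) = 0` are `-Inf` (an impossible symbol), not an error.
#'
#' @inheritParams probabilityMatrix
#' @param background Named probability vector over the alphabet; all entries
#'   must be positive.  Default uniform.
#' @return `n x k` weight matrix.
#' @export
logOddsMatrix <- function(x, pseudocount = 0, background = NULL) {
    stopifnot(is(x, "SequenceProfile"))
    if (is.null(background)) background <- uniformBackground(x@alphabet)
    if (length(background) != ncol(x@counts) || any(background <= 0))
        stop("background must be positive for every alphabet symbol")
    P <- probabilityMatrix(x, pseudocount)
    log2(sweep(P, 2L, background, "/"))
}

IUPAC_MAP <- c(A = "A", C = "C", G = "G", T = "T",
               AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
               ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

#' Consensus sequence of a profile
#'
#' Per position, the symbol with maximum count.  For nucleotide profiles a
#' tie is resolved to the IUPAC ambiguity code of the tied symbol set (so
#' the consensus lives in the 15-symbol IUPAC alphabet); for any other
#' alphabet the first tied symbol in alphabet order is chosen.
#'
#' @param x A [SequenceProfile-class] with at least one position.
#' @return A [Sequence-class] (over [iupacNucleotideAlphabet()] for
#'   nucleotide profiles).
#' @export
toConsensus <- function(x) {
    stopifnot(is(x, "SequenceProfile"), nrow(x@counts) >= 1L)
    if (isNucleotideAlphabet(x@alphabet)) {
        out <- iupacNucleotideAlphabet()
        syms <- vapply(seq_len(nrow(x@counts)), function(i) {
            cnt <- x@counts[i, ]
            tied <- alphabetSymbols(x@alphabet)[cnt == max(cnt)]
            IUPAC_MAP[[paste(sort(tied), collapse = "")]]
        }, "")
        encodeSequence(paste(syms, collapse = ""), out)
    } else {
        codes <- apply(x@counts, 1L, which.max) - 1L
        Sequence(codes, x@alphabet)
    }
}

#' Probability and score of a sequence under a profile
#'
#' `sequenceProbability()` is the product over positions of the PPM entry of
#' the observed symbol; `sequenceScore()` the sum of the corresponding PWM
#' log-odds weights.  The sequence must have exactly one symbol per profile
#' position.
#'
#' @inheritParams logOddsMatrix
#' @param sequence A [Sequence-class] of length `n` over the profile
#'   alphabet.
#' @return A probability in `[0, 1]`, or a log2 score (possibly `-Inf`).
#' @export
sequenceProbability <- function(x, sequence, pseudocount = 0) {
    stopifnot(is(x, "SequenceProfile"), is(sequence, "Sequence"))
    if (length(sequence) != nrow(x@counts))
        stop("sequence length must equal the number of profile positions")
    P <- probabilityMatrix(x, pseudocount)
    prod(P[cbind(seq_len(nrow(P)), sequence@codes + 1L)])
}

#' @rdname sequenceProbability
#' @export
sequenceScore <- function(x, sequence, pseudocount = 0, background = NULL) {
    stopifnot(is(x, "SequenceProfile"), is(sequence, "Sequence"))
    if (length(sequence) != nrow(x@counts))
        stop("sequence length must equal the number of profile positions")
    W <- logOddsMatrix(x, pseudocount, background)
    sum(W[cbind(seq_len(nrow(W)), sequence@codes + 1L)])
}
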