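#' Background symbol frequencies
#'
#' `uniformBackground()` assigns equal probability to every alphabet symbol.
#' `standardProteinBackground()` is uniform over the 20 standard amino
#' acids (zero on the ambiguity codes B, Z, X and the stop symbol), which is
#' the natural null model for sampling random protein sequences.
#' `blosum62Frequencies()` returns the marginal amino-acid frequencies
#' underlying the BLOSUM62 matrix (Robinson-Robinson style values, zero on
#' the ambiguity codes), normalized to sum to 1.
#'
#' @param alphabet Target [Alphabet-class].
#' @return Named numeric probability vector over the alphabet symbols.
#' @export
uniformBackground <- function(alphabet) {
    q <- alphabetSize(alphabet)
    setNames(rep(1 / q, q), alphabetSymbols(alphabet))
}

#' @rdname uniformBackground
#' @export
standardProteinBackground <- function(alphabet = proteinAlphabet()) {
    std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
    p <- setNames(numeric(alphabetSize(alphabet)),
                  alphabetSymbols(alphabet))
    if (!all(std %in% names(p)))
        stop("alphabet lacks the 20 standard amino acids")
    p[std] <- 1 / length(std)
    p
}

#' @rdname uniformBackground
#' @export
blosum62Frequencies <- function(alphabet = proteinAlphabet()) {
    f <- c(A = 0.07422, R = 0.05161, N = 0.04465, D = 0.05363, C = 0.02469,
           Q = 0.03426, E = 0.05431, G = 0.07415, H = 0.02621, I = 0.06792,
           L = 0.09891, K = 0.05816, M = 0.02499, F = 0.04742, P = 0.03854,
           S = 0.05723, T = 0.05089, W = 0.01303, Y = 0.03228, V = 0.07292)
    p <- setNames(numeric(alphabetSize(alphabet)),
                  alphabetSymbols(alphabet))
    if (!all(names(f) %in% names(p)))
        stop("alphabet lacks the 20 standard amino acids")
    p[names(f)] <- f / sum(f)
    p
}

checkBackground <- function(background, alphabet) {
    q <- alphabetSize(alphabet)
    if (length(background) != q)
        stop("background must have one probability per alphabet symbol")
    if (any(background < 0) || abs(sum(background) - 1) > 1e-9)
        stop("background frequencies must be non-negative and sum to 1")
    invisible(TRUE)
}

#' GumbelParams: fitted extreme-value score distribution
#'
#' Parameters of the Gumbel distribution fitted to sampled local alignment
#' scores, plus the sequence lengths used during sampling (needed to rescale
#' E-values to other search space sizes).
#'
#' @slot lam Scale parameter lambda (> 0).
#' @slot u Location parameter.
#' @slot sampleLenQ,sampleLenDb Sequence lengths used when sampling.
#' @slot nSamples Number of sampled scores.
#' @seealso [fitGumbel()], [eValue()]
#' @export
setClass("GumbelParams",
         representation(lam = "numeric", u = "numeric",
                        sampleLenQ = "numeric", sampleLenDb = "numeric",
                        nSamples = "integer"))

setValidity("GumbelParams", function(object) {
    if (length(object@lam) != 1L || is.na(object@lam) || object@lam <= 0)
        return("lambda must be a single positive number")
    if (object@nSamples < 2L) return("at least two samples are required")
    TRUE
})

setMethod("show", "GumbelParams", function(object) {
    cat(sprintf(
        "GumbelParams: lambda = %.4g, u = %.4g (n = %d, sample lengths %g x %g)\n",
        object@lam, object@u, object@nSamples, object@sampleLenQ,
        object@sampleLenDb))
})

#' Sample local alignment scores from randomized sequences
#'
#' Draws `nSamples` i.i.d. sequence pairs of lengths `lenQ` and `lenDb` from
#' the background distribution and computes the rigorous Smith-Waterman
#' (Gotoh) local alignment score of each pair.  Deterministic given `seed`.
#'
#' @param matrix A [SubstitutionMatrix-class] (square, one alphabet).
#' @param gapOpen,gapExtend Non-positive affine gap penalties.
#' @param background Named probability vector over the alphabet (default
#'   uniform).
#' @param lenQ,lenDb Lengths of the sampled query/database sequences.
#' @param nSamples Number of score samples (>= 2).
#' @param seed RNG seed.
#' @return Numeric vector of `nSamples` non-negative local alignment scores.
#' @export
sampleScores <- function(matrix, gapOpen = -10, gapExtend = -1,
                         background = NULL, lenQ, lenDb,
                         nSamples = 1000L, seed = 1L) {
    gp <- checkGap(gapOpen, gapExtend)
    alph <- matrix@alphabet1
    if (is.null(background)) background <- uniformBackground(alph)
    checkBackground(background, alph)
    if (nSamples < 2L) stop("nSamples must be >= 2")
    q <- alphabetSize(alph)
    S <- matrix@scores
    scores <- withSeed(seed, {
        vapply(seq_len(nSamples), function(i) {
            cq <- sample.int(q, lenQ, replace = TRUE, prob = background) - 1L
            cd <- sample.int(q, lenDb, replace = TRUE, prob = background) - 1L
            gotoh_score_cpp(S[cq + 1L, cd + 1L, drop = FALSE],
                            gp["open"], gp["extend"],
                            local = TRUE, termpen = TRUE)
        }, 0)
    })
    if (all(scores == 0))
        warning("all sampled scores are zero (degenerate background/matrix)")
    scores
}

#' Fit a Gumbel distribution by the method of moments
#'
#' Moment estimators from the sample mean and standard deviation:
#' `lambda = pi / (sd * sqrt(6))` and `u = mean - gamma / lambda`, with
#' Euler-Mascheroni constant `gamma ~= 0.5772157`.
#'
#' @param scores Numeric score sample (standard deviation must be positive).
#' @param sampleLenQ,sampleLenDb Sequence lengths the scores were sampled at
#'   (stored for E-value length rescaling).
#' @return A [GumbelParams-class].
#' @export
fitGumbel <- function(scores, sampleLenQ = NA_real_, sampleLenDb = NA_real_) {
    if (length(scores) < 2L) stop("need at least two scores")
    s <- sd(scores)
    if (!is.finite(s) || s <= 0)
        stop("score sample has zero variance; cannot fit")
    lam <- pi / (s * sqrt(6))
    u <- mean(scores) - EULER_GAMMA / lam
    new("GumbelParams", lam = lam, u = u,
        sampleLenQ = as.numeric(sampleLenQ),
        sampleLenDb = as.numeric(sampleLenDb),
        nSamples = length(scores))
}

EULER_GAMMA <- 0.57721566490153286

#' Convenience: sample scores and fit in one step
#'
#' @inheritParams sampleScores
#' @return A [GumbelParams-class] carrying the sampling lengths.
#' @export
evalueEstimator <- function(matrix, gapOpen = -10, gapExtend = -1,
                            background = NULL, lenQ, lenDb,
                            nSamples = 1000L, seed = 1L) {
    fitGumbel(sampleScores(matrix, gapOpen, gapExtend, background,
                           lenQ, lenDb, nSamples, seed),
              sampleLenQ = lenQ, sampleLenDb = lenDb)
}

#' E-value of an alignment score
#'
#' Expected number of chance hits with at least the given score:
#' `E = (lenQ * lenDbTotal) / (sampleLenQ * sampleLenDb) *
#' exp(-lambda * (score - u))`.  The leading ratio rescales the fitted
#' search space (one sampled pair) to the actual query length times total
#' database length, the usual m-by-n dependence of local alignment
#' statistics.  E is monotonically non-increasing in the score.
#'
#' @param params A [GumbelParams-class].
#' @param score Alignment score(s).
#' @param lenQ Query length.
#' @param lenDbTotal Total database length (sum of reference lengths).
#' @return Numeric E-value(s).
#' @export
eValue <- function(params, score, lenQ, lenDbTotal) {
    stopifnot(is(params, "GumbelParams"))
    if (lenQ < 0 || lenDbTotal < 0) stop("lengths must be non-negative")
    (lenQ * lenDbTotal) / (params@sampleLenQ * params@sampleLenDb) *
        exp(-params@lam * (score - params@u))
}
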