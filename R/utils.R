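# Internal helpers.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package thread an explicit seed through
# this helper; nothing relies on ambient global RNG state.
withSeed <- function(seed, code) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE)) {
            get(".Random.seed", envir = globalenv())
        } else {
            NULL
        }
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv(),
                           inherits = FALSE))
                    rm(".Random.seed", envir = globalenv())
            } else {
                assign(".Random.seed", old, envir = globalenv())
            }
        })
        set.seed(seed)
    }
    force(code)
}

# Validate an affine gap penalty pair: both components non-positive.
checkGap <- function(gapOpen, gapExtend) {
    if (!is.numeric(gapOpen) || length(gapOpen) != 1L || is.na(gapOpen) ||
        gapOpen > 0)
        stop("'gapOpen' must be a single non-positive number")
    if (is.null(gapExtend)) gapExtend <- gapOpen   # linear gap penalty
    if (!is.numeric(gapExtend) || length(gapExtend) != 1L ||
        is.na(gapExtend) || gapExtend > 0)
        stop("'gapExtend' must be a single non-positive number")
    c(open = gapOpen, extend = gapExtend)
}

fmtLen <- function(x) sprintf("%.17g", x)
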