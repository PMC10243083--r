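#' Sequence: an alphabet plus a symbol-code vector
#'
#' The universal sequence representation of the package: an [Alphabet-class]
#' together with an integer vector of symbol codes (each code `c` satisfies
#' `0 <= c < q`).  Positions are 0-based and intervals half-open throughout
#' the package.
#'
#' @slot alphabet The [Alphabet-class].
#' @slot codes Integer vector of symbol codes.
#'
#' @seealso [encodeSequence()], [decodeSequence()]
#' @export
setClass("Sequence",
         representation(alphabet = "Alphabet", codes = "integer"))

setValidity("Sequence", function(object) {
    q <- alphabetSize(object@alphabet)
    cd <- object@codes
    if (length(cd) && (anyNA(cd) || min(cd) < 0L || max(cd) >= q))
        return(sprintf("symbol codes must lie in [0, %d)", q))
    TRUE
})

#' Construct a Sequence from raw codes
#'
#' @param codes Integer vector of symbol codes in `[0, q)`.
#' @param alphabet The [Alphabet-class].
#' @return A [Sequence-class].
#' @export
Sequence <- function(codes, alphabet) {
    new("Sequence", alphabet = alphabet, codes = as.integer(codes))
}

#' Encode a symbol string into a Sequence
#'
#' Translates each character into its symbol code (its 0-based position in
#' the alphabet).  Matching is case-insensitive.  For the built-in protein
#' alphabet the rare residues U (selenocysteine) and O (pyrrolysine) are
#' remapped to X with a warning, so that Swiss-Prot sequences encode without
#' preprocessing.
#'
#' @param text A single string of symbols.
#' @param alphabet Target [Alphabet-class].
#' @return A [Sequence-class].
#' @examples
#' encodeSequence("ACGT", nucleotideAlphabet())
#' @export
encodeSequence <- function(text, alphabet) {
    stopifnot(is.character(text), length(text) == 1L)
    chars <- strsplit(toupper(text), "", fixed = TRUE)[[1L]]
    if (isProteinAlphabet(alphabet)) {
        odd <- chars %in% c("U", "O")
        if (any(odd)) {
            warning(sprintf("remapped %d U/O symbol(s) to X", sum(odd)))
            chars[odd] <- "X"
        }
    }
    codes <- match(chars, alphabet@symbols) - 1L
    if (anyNA(codes)) {
        bad <- which(is.na(codes))[1L]
        stop(sprintf(
            "symbol '%s' at position %d (0-based) is not in the alphabet",
            chars[bad], bad - 1L))
    }
    new("Sequence", alphabet = alphabet, codes = codes)
}

#' Decode a Sequence back into its symbol string
#'
#' Inverse of [encodeSequence()]: `decodeSequence(encodeSequence(s, a))`
#' reproduces `s` (uppercased) for every symbol of the alphabet.
#'
#' @param x A [Sequence-class].
#' @return A single string.
#' @export
decodeSequence <- function(x) {
    stopifnot(is(x, "Sequence"))
    paste(x@alphabet@symbols[x@codes + 1L], collapse = "")
}

#' @describeIn Sequence-class number of positions
#' @param x A `Sequence`.
#' @export
setMethod("length", "Sequence", function(x) length(x@codes))

#' @rdname alphabetSymbols
#' @export
setMethod("alphabet", "Sequence", function(x) x@alphabet)

#' Symbol codes of a sequence
#'
#' @param x A [Sequence-class].
#' @return Integer vector of 0-based symbol codes.
#' @export
setGeneric("symbolCodes", function(x) standardGeneric("symbolCodes"))

#' @rdname symbolCodes
#' @export
setMethod("symbolCodes", "Sequence", function(x) x@codes)

setMethod("as.character", "Sequence", function(x) decodeSequence(x))

setMethod("show", "Sequence", function(object) {
    n <- length(object)
    txt <- decodeSequence(object)
    if (n > 60L) txt <- paste0(substr(txt, 1L, 57L), "...")
    cat(sprintf("Sequence of length %d: %s\n", n, txt))
})
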