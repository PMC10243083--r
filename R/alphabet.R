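#' Alphabet: an ordered set of sequence symbols
#'
#' An `Alphabet` defines the bijection between symbols and their integer
#' *symbol codes*: the symbol at position `i` of the alphabet has code
#' `i - 1`, so codes run from 0 to `q - 1` where `q` is the alphabet length.
#' All sequences in this package store symbol codes, not characters; the
#' code representation makes substitution-matrix lookup and k-mer encoding
#' direct array indexing.
#'
#' @slot symbols Character vector of distinct single-character symbols, in
#'   code order.
#'
#' @seealso [nucleotideAlphabet()], [proteinAlphabet()], [encodeSequence()]
#' @export
setClass("Alphabet", representation(symbols = "character"))

setValidity("Alphabet", function(object) {
    s <- object@symbols
    if (length(s) < 1L) return("alphabet must contain at least one symbol")
    if (anyDuplicated(s)) return("alphabet symbols must be unique")
    if (any(nchar(s) != 1L)) return("alphabet symbols must be single characters")
    TRUE
})

#' Create an alphabet
#'
#' @param symbols Character vector of distinct single-character symbols; a
#'   single multi-character string is split into its characters.
#' @return An [Alphabet-class] object.
#' @examples
#' Alphabet("ACGT")
#' @export
Alphabet <- function(symbols) {
    if (length(symbols) == 1L && nchar(symbols) > 1L)
        symbols <- strsplit(symbols, "", fixed = TRUE)[[1L]]
    new("Alphabet", symbols = as.character(symbols))
}

#' Built-in alphabets
#'
#' `nucleotideAlphabet()` is the unambiguous DNA alphabet `A,C,G,T` (codes
#' 0..3 in that order).  `proteinAlphabet()` is the 24-symbol amino-acid
#' alphabet `ACDEFGHIKLMNPQRSTVWYBZX*` (20 standard residues plus the
#' ambiguity codes B, Z, X and the stop symbol `*`), chosen so that BLOSUM
#' matrices apply without remapping.  `iupacNucleotideAlphabet()` is the
#' 15-symbol IUPAC nucleotide alphabet used for consensus sequences of
#' nucleotide profiles.
#'
#' @return An [Alphabet-class].
#' @examples
#' symbolCodes(encodeSequence("ACGT", nucleotideAlphabet()))
#' @export
nucleotideAlphabet <- function() Alphabet(c("A", "C", "G", "T"))

#' @rdname nucleotideAlphabet
#' @export
proteinAlphabet <- function() Alphabet("ACDEFGHIKLMNPQRSTVWYBZX*")

#' @rdname nucleotideAlphabet
#' @export
iupacNucleotideAlphabet <- function() Alphabet("ACGTRYSWKMBDHVN")

#' @describeIn Alphabet-class number of symbols (`q`)
#' @param x An `Alphabet`.
#' @export
setMethod("length", "Alphabet", function(x) length(x@symbols))

#' Accessors for alphabets
#'
#' `alphabetSymbols()` returns the ordered symbol vector,
#' `alphabetSize()` the number of symbols `q`.
#'
#' @param x An [Alphabet-class] or an object carrying one.
#' @return Character vector, or integer.
#' @export
setGeneric("alphabetSymbols", function(x) standardGeneric("alphabetSymbols"))

#' @rdname alphabetSymbols
#' @export
setMethod("alphabetSymbols", "Alphabet", function(x) x@symbols)

#' @rdname alphabetSymbols
#' @export
setGeneric("alphabetSize", function(x) standardGeneric("alphabetSize"))

#' @rdname alphabetSymbols
#' @export
setGeneric("alphabet", function(x) standardGeneric("alphabet"))

#' @rdname alphabetSymbols
#' @export
setMethod("alphabetSize", "Alphabet", function(x) length(x@symbols))

setMethod("show", "Alphabet", function(object) {
    cat(sprintf("Alphabet of %d symbols: %s\n", length(object@symbols),
                paste(object@symbols, collapse = "")))
})

# TRUE when two alphabets define the same symbol-code bijection.
sameAlphabet <- function(a, b) identical(a@symbols, b@symbols)

isNucleotideAlphabet <- function(a) identical(a@symbols, c("A", "C", "G", "T"))
isProteinAlphabet <- function(a) {
    identical(a@symbols, strsplit("ACDEFGHIKLMNPQRSTVWYBZX*", "")[[1L]])
}
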