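#' SubstitutionMatrix: pairwise symbol scores
#'
#' A `q1 x q2` integer score matrix between two alphabets, indexed by symbol
#' code.  The canonical BLOSUM62 matrix (NCBI flat format) is bundled with
#' the package and is the default scoring scheme for protein sequences.
#'
#' @slot alphabet1,alphabet2 Row/column [Alphabet-class]s.
#' @slot scores Integer matrix with `dim = c(q1, q2)`.
#'
#' @seealso [loadSubstitutionMatrix()], [substitutionMatrix()]
#' @export
setClass("SubstitutionMatrix",
         representation(alphabet1 = "Alphabet", alphabet2 = "Alphabet",
                        scores = "matrix"))

setValidity("SubstitutionMatrix", function(object) {
    if (nrow(object@scores) != alphabetSize(object@alphabet1) ||
        ncol(object@scores) != alphabetSize(object@alphabet2))
        return("score matrix dimensions must match the alphabet sizes")
    if (!is.numeric(object@scores)) return("scores must be numeric")
    TRUE
})

#' Construct a substitution matrix from explicit scores
#'
#' @param alphabet1,alphabet2 Row and column alphabets.
#' @param scores `q1 x q2` numeric matrix.
#' @return A [SubstitutionMatrix-class].
#' @export
substitutionMatrix <- function(alphabet1, alphabet2 = alphabet1, scores) {
    dimnames(scores) <- list(alphabetSymbols(alphabet1),
                             alphabetSymbols(alphabet2))
    new("SubstitutionMatrix", alphabet1 = alphabet1, alphabet2 = alphabet2,
        scores = scores)
}

#' Simple match/mismatch matrix
#'
#' @param alphabet The [Alphabet-class].
#' @param match,mismatch Scores on and off the diagonal.
#' @return A [SubstitutionMatrix-class].
#' @export
uniformSubstitutionMatrix <- function(alphabet, match = 1, mismatch = -1) {
    q <- alphabetSize(alphabet)
    s <- matrix(mismatch, q, q)
    diag(s) <- match
    substitutionMatrix(alphabet, alphabet, s)
}

#' Load a substitution matrix in NCBI flat format
#'
#' Reads a matrix file in the NCBI convention: `#` comment lines, a header
#' row of symbols, then one row per symbol of integer scores.  The matrix is
#' re-indexed to the requested alphabet; every symbol of the target alphabet
#' must be present in the file.
#'
#' @param name Either the name of a bundled matrix (currently `"BLOSUM62"`)
#'   or a path to an NCBI-format flat file.
#' @param alphabet Target alphabet (default: the built-in protein alphabet).
#' @return A [SubstitutionMatrix-class] with `alphabet1 == alphabet2 ==
#'   alphabet`.
#' @examples
#' b62 <- loadSubstitutionMatrix("BLOSUM62")
#' scoreMatrix(b62)["W", "W"]   # 11
#' @export
loadSubstitutionMatrix <- function(name = "BLOSUM62",
                                   alphabet = proteinAlphabet()) {
    path <- if (file.exists(name)) {
        name
    } else {
        p <- system.file("extdata", name, package = "seqsmith")
        if (!nzchar(p))
            stop(sprintf("'%s' is neither a bundled matrix nor a file", name))
        p
    }
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*#", lines)]
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2L)
        stop("malformed substitution matrix file: no header/data rows")
    header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
    if (any(nchar(header) != 1L))
        stop("malformed substitution matrix file: bad header row")
    nsym <- length(header)
    rows <- strsplit(trimws(lines[-1L]), "\\s+")
    if (length(rows) != nsym)
        stop("malformed substitution matrix file: row count does not match header")
    rowsyms <- vapply(rows, `[[`, "", 1L)
    vals <- lapply(rows, function(r) suppressWarnings(as.numeric(r[-1L])))
    if (any(vapply(vals, length, 0L) != nsym) || anyNA(unlist(vals)))
        stop("malformed substitution matrix file: non-numeric or ragged rows")
    m <- do.call(rbind, vals)
    dimnames(m) <- list(rowsyms, header)

    want <- alphabetSymbols(alphabet)
    missing <- setdiff(want, intersect(rowsyms, header))
    if (length(missing))
        stop(sprintf("matrix file lacks symbols required by the alphabet: %s",
                     paste(missing, collapse = ", ")))
    substitutionMatrix(alphabet, alphabet, m[want, want, drop = FALSE])
}

#' Score matrix accessor
#'
#' @param x A [SubstitutionMatrix-class].
#' @return The numeric score matrix with symbol dimnames.
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname scoreMatrix
#' @export
setMethod("scoreMatrix", "SubstitutionMatrix", function(x) x@scores)

setMethod("show", "SubstitutionMatrix", function(object) {
    cat(sprintf("SubstitutionMatrix %d x %d over '%s' / '%s'\n",
                nrow(object@scores), ncol(object@scores),
                paste(alphabetSymbols(object@alphabet1), collapse = ""),
                paste(alphabetSymbols(object@alphabet2), collapse = "")))
})

# Position-pair similarity matrix for two code-encoded sequences.
simMatrix <- function(s1, s2, submat) {
    n1 <- length(s1)
    n2 <- length(s2)
    if (n1 == 0L || n2 == 0L) return(matrix(0, n1, n2))
    matrix(submat@scores[s1@codes + 1L, s2@codes + 1L, drop = FALSE], n1, n2)
}

checkAlphabets <- function(s1, s2, submat) {
    if (!sameAlphabet(alphabet(s1), submat@alphabet1) ||
        !sameAlphabet(alphabet(s2), submat@alphabet2))
        stop("sequence alphabets do not match the substitution matrix")
    invisible(TRUE)
}
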