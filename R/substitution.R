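#' Substitution matrices over the 21-letter alphabet
#'
#' `blosum62()` returns the BLOSUM62 substitution matrix restricted to the 20
#' standard amino acids and extended with an `"X"` row/column whose entries
#' are the matrix minimum (-4), so unknown residues can only penalize an
#' alignment. `substitution_matrix()` validates an arbitrary square scoring
#' table against the alphabet and wraps it in the class the aligners expect.
#'
#' @param scores A symmetric numeric matrix with identical row and column
#'   names drawn from [aa_alphabet()].
#' @return A `substitution_matrix`: a numeric matrix with an `alphabet`
#'   attribute.
#' @examples
#' m <- blosum62()
#' m["G", "G"] # 6
#' @export
blosum62 <- function() {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  b62 <- data_env$BLOSUM62
  aa20 <- AA_ALPHABET21[1:20]
  m <- matrix(min(b62), nrow = 21, ncol = 21,
              dimnames = list(AA_ALPHABET21, AA_ALPHABET21))
  m[aa20, aa20] <- b62[aa20, aa20]
  substitution_matrix(m)
}

#' @rdname blosum62
#' @export
substitution_matrix <- function(scores) {
  if (!is.matrix(scores) || nrow(scores) != ncol(scores)) {
    abort("`scores` must be a square matrix")
  }
  ab <- rownames(scores)
  if (is.null(ab) || !identical(ab, colnames(scores))) {
    abort("`scores` must have identical row and column names (the alphabet)")
  }
  if (!all(ab %in% AA_ALPHABET21)) {
    abort("alphabet symbols must be drawn from aa_alphabet()")
  }
  if (!isTRUE(all.equal(scores, t(scores)))) {
    abort("substitution matrix must be symmetric")
  }
  structure(scores, class = c("substitution_matrix", "matrix", "array"),
            alphabet = ab)
}

# Expand a substitution matrix to the full fixed-order 21-letter table used
# by the C++ kernels; symbols missing from the matrix score as its minimum.
full_matrix <- function(m) {
  ab <- attr(m, "alphabet")
  if (identical(ab, AA_ALPHABET21)) return(unclass(m))
  out <- matrix(min(m), 21, 21, dimnames = list(AA_ALPHABET21, AA_ALPHABET21))
  out[ab, ab] <- unclass(m)[ab, ab]
  out
}
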