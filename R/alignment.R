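#' Affine-gap pairwise alignment
#'
#' `smith_waterman()` computes the optimal local alignment and
#' `needleman_wunsch()` the optimal global alignment (end gaps penalized) of
#' two residue strings under a substitution matrix and affine gap costs: a
#' gap of length L costs `gap_open + L * gap_extend`. The traceback is
#' deterministic (state preference diagonal > up > left; the first maximal
#' cell in row-major order ends a local alignment), so repeated runs are
#' bit-identical.
#'
#' @param a,b Residue strings over [aa_alphabet()] (upper case).
#' @param matrix A [substitution_matrix()]; default [blosum62()].
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @return An `alignment_result`: a list with elements `mode` ("local" or
#'   "global"), `score`, `a_interval` and `b_interval` (0-based half-open),
#'   `pairs` (a tibble with 0-based `a_idx`, `b_idx`, `NA` marking a gap),
#'   `identity` (matches / aligned non-gap columns), and `length` (number of
#'   alignment columns).
#' @examples
#' smith_waterman("GKT", "GKT")$score # 16
#' needleman_wunsch("FGLSGTGKTTL", "VGPNGSGKSTV")$identity
#' @export
smith_waterman <- function(a, b, matrix = blosum62(), gap_open = 11,
                           gap_extend = 1) {
  align_pair(a, b, matrix, gap_open, gap_extend, local = TRUE)
}

#' @rdname smith_waterman
#' @export
needleman_wunsch <- function(a, b, matrix = blosum62(), gap_open = 11,
                             gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) {
    abort("global alignment requires two non-empty sequences")
  }
  align_pair(a, b, matrix, gap_open, gap_extend, local = FALSE)
}

align_pair <- function(a, b, matrix, gap_open, gap_extend, local) {
  check_gaps(gap_open, gap_extend)
  if (local && (!nzchar(a) || !nzchar(b))) {
    return(new_alignment_result("local", 0, integer(0), integer(0), 0L, 0L))
  }
  ab <- attr(matrix, "alphabet")
  ca <- encode_checked(a, ab, "a")
  cb <- encode_checked(b, ab, "b")
  S <- cpp_pair_scores(ca, cb, full_matrix(matrix))
  res <- cpp_align(S, gap_open, gap_extend, local)
  out <- new_alignment_result(if (local) "local" else "global",
                              res$score, res$a_idx, res$b_idx,
                              length(ca), length(cb))
  finish_identity(out, a, b)
}

encode_checked <- function(x, alphabet, what) {
  codes <- encode_seq(x, what)
  extra <- setdiff(unique(strsplit(x, "")[[1]]), c(alphabet, "X"))
  if (length(extra) > 0) {
    abort(sprintf("%s contains symbols outside the matrix alphabet: %s",
                  what, paste(extra, collapse = ", ")))
  }
  codes
}

check_gaps <- function(gap_open, gap_extend) {
  if (gap_open < 0 || gap_extend < 0) abort("gap penalties must be non-negative")
}

new_alignment_result <- function(mode, score, a_idx, b_idx, na, nb) {
  a_ng <- a_idx[!is.na(a_idx)]
  b_ng <- b_idx[!is.na(b_idx)]
  a_int <- if (length(a_ng)) c(min(a_ng), max(a_ng) + 1L) else c(0L, 0L)
  b_int <- if (length(b_ng)) c(min(b_ng), max(b_ng) + 1L) else c(0L, 0L)
  aligned <- !is.na(a_idx) & !is.na(b_idx)
  structure(
    list(
      mode = mode,
      score = score,
      a_interval = as.integer(a_int),
      b_interval = as.integer(b_int),
      pairs = tibble::tibble(a_idx = as.integer(a_idx),
                             b_idx = as.integer(b_idx)),
      n_aligned = sum(aligned),
      length = length(a_idx),
      a_length = as.integer(na),
      b_length = as.integer(nb),
      identity = NA_real_
    ),
    class = "alignment_result"
  )
}

# identity needs the residue content; computed where sequences are known
finish_identity <- function(res, a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  ok <- !is.na(res$pairs$a_idx) & !is.na(res$pairs$b_idx)
  if (!any(ok)) {
    res$identity <- NA_real_
    return(res)
  }
  matches <- sum(ca[res$pairs$a_idx[ok] + 1L] == cb[res$pairs$b_idx[ok] + 1L])
  res$identity <- matches / sum(ok)
  res
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result> %s score %.6g, a [%d,%d), b [%d,%d), %d columns, identity %s\n",
    x$mode, x$score, x$a_interval[1], x$a_interval[2],
    x$b_interval[1], x$b_interval[2], x$length,
    ifelse(is.na(x$identity), "NA", sprintf("%.3f", x$identity))
  ))
  invisible(x)
}

#' Local alignment of a position-score profile against a sequence
#'
#' Column `i` of the profile scores residue `b[j]` by table lookup; gaps are
#' affine exactly as in [smith_waterman()]. This is the scan primitive behind
#' the theme search.
#'
#' @param profile A [theme_profile] or a plain numeric matrix (width x
#'   alphabet, columns named by [aa_alphabet()] symbols).
#' @inheritParams smith_waterman
#' @return An `alignment_result` with `a_*` referring to profile columns.
#' @export
profile_align_local <- function(profile, b, gap_open = 11, gap_extend = 1) {
  check_gaps(gap_open, gap_extend)
  scores <- profile_score_table(profile)
  if (nrow(scores) == 0) abort("profile has zero columns")
  if (!nzchar(b)) {
    return(new_alignment_result("local", 0, integer(0), integer(0),
                                nrow(scores), 0L))
  }
  cb <- encode_seq(b, "b")
  S <- scores[, cb + 1L, drop = FALSE]
  res <- cpp_align(S, gap_open, gap_extend, TRUE)
  new_alignment_result("local", res$score, res$a_idx, res$b_idx,
                       nrow(scores), length(cb))
}

profile_score_table <- function(profile) {
  m <- if (inherits(profile, "theme_profile")) profile$column_scores else profile
  if (!is.matrix(m)) abort("`profile` must be a theme_profile or numeric matrix")
  if (nrow(m) == 0) abort("profile has zero columns")
  if (is.null(colnames(m))) abort("profile score table must have residue column names")
  full <- matrix(min(m), nrow = nrow(m), ncol = 21,
                 dimnames = list(NULL, AA_ALPHABET21))
  full[, colnames(m)] <- m
  full
}

# Alignment identities wrapped for external callers
#' @rdname smith_waterman
#' @param result An `alignment_result`.
#' @param a_seq,b_seq The sequences the result was computed from.
#' @export
alignment_identity <- function(result, a_seq, b_seq) {
  finish_identity(result, a_seq, b_seq)$identity
}
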