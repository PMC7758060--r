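#' Greedy identity clustering of sequences
#'
#' CD-HIT-style redundancy reduction: sequences are sorted by length
#' (descending, ties by input order); each joins the first existing cluster
#' whose centroid it matches at `identity_threshold` or better under a
#' global alignment (identity = matches / length of the shorter sequence,
#' the CD-HIT convention), otherwise it founds a new cluster with itself as
#' centroid.
#'
#' @param domains A tibble with at least `id` and `sequence`.
#' @param identity_threshold Identity threshold in (0, 1]; default 0.70.
#' @param matrix,gap_open,gap_extend Alignment parameters for the global
#'   identity computation.
#' @return A tibble with one row per sequence: `id`, `centroid_id`,
#'   `identity_to_centroid`, `is_centroid`.
#' @export
cluster_sequences <- function(domains, identity_threshold = 0.70,
                              matrix = blosum62(), gap_open = 11,
                              gap_extend = 1) {
  if (identity_threshold <= 0 || identity_threshold > 1) {
    abort("`identity_threshold` must be in (0, 1]")
  }
  n <- nrow(domains)
  if (n == 0) {
    return(tibble::tibble(id = character(), centroid_id = character(),
                          identity_to_centroid = double(),
                          is_centroid = logical()))
  }
  ord <- order(-nchar(domains$sequence), seq_len(n))
  centroids <- integer(0) # indices into domains (in cluster-founding order)
  assign_to <- integer(n)
  ident <- numeric(n)
  for (i in ord) {
    placed <- FALSE
    for (ci in centroids) {
      idv <- global_identity(domains$sequence[i], domains$sequence[ci],
                             matrix, gap_open, gap_extend)
      if (idv >= identity_threshold) {
        assign_to[i] <- ci
        ident[i] <- idv
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, i)
      assign_to[i] <- i
      ident[i] <- 1
    }
  }
  tibble::tibble(
    id = domains$id,
    centroid_id = domains$id[assign_to],
    identity_to_centroid = ident,
    is_centroid = assign_to == seq_len(n)
  )
}

# global-alignment identity over the shorter sequence (CD-HIT convention)
global_identity <- function(a, b, matrix = blosum62(), gap_open = 11,
                            gap_extend = 1) {
  aln <- needleman_wunsch(a, b, matrix, gap_open, gap_extend)
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  ok <- !is.na(aln$pairs$a_idx) & !is.na(aln$pairs$b_idx)
  matches <- sum(ca[aln$pairs$a_idx[ok] + 1L] == cb[aln$pairs$b_idx[ok] + 1L])
  matches / min(nchar(a), nchar(b))
}

#' Per-column consensus and conservation of an alignment
#'
#' For each column, the consensus residue is the most frequent non-gap
#' residue (ties broken alphabetically) and the conservation score is that
#' residue's frequency among the column's non-gap rows, in `[0, 1]`.
#'
#' @param msa A [theme_alignment()].
#' @return A `conservation_profile`: a tibble with `column` (1-based),
#'   `consensus_residue`, `score`, `n_nongap`, `composition` (named count
#'   list-column), plus a `consensus` attribute holding the consensus
#'   string.
#' @export
consensus_profile <- function(msa) {
  stopifnot(inherits(msa, "theme_alignment"))
  mat <- do.call(rbind, strsplit(msa$rows, ""))
  cols <- purrr::map(seq_len(ncol(mat)), function(c_) {
    col <- mat[, c_]
    col <- col[col != "-"]
    counts <- table(col) # names come out alphabetically sorted
    best <- names(counts)[counts == max(counts)][1] # tie -> alphabetical
    tibble::tibble(
      column = c_,
      consensus_residue = best,
      score = max(counts) / length(col),
      n_nongap = length(col),
      composition = list(as.list(counts))
    )
  })
  out <- dplyr::bind_rows(cols)
  attr(out, "consensus") <- paste(out$consensus_residue, collapse = "")
  class(out) <- c("conservation_profile", class(out))
  out
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("<conservation_profile> %d columns, consensus %s\n",
              nrow(x), attr(x, "consensus")))
  NextMethod()
}

#' Write a consensus/conservation table
#'
#' TSV columns: `column_index` (1-based), `consensus_residue`, `score`,
#' `column_composition` (residue:count pairs, comma-separated).
#'
#' @param profile A [consensus_profile()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation_table <- function(profile, path) {
  comp <- vapply(profile$composition, function(x) {
    paste(sprintf("%s:%d", names(x), unlist(x)), collapse = ",")
  }, character(1))
  readr::write_tsv(
    tibble::tibble(
      column_index = profile$column,
      consensus_residue = profile$consensus_residue,
      score = profile$score,
      column_composition = comp
    ),
    path, progress = FALSE
  )
  invisible(path)
}

#' Stack retained theme hits into a theme-region alignment
#'
#' Re-aligns each retained hit's domain against the profile and extracts,
#' for every profile column, the matched residue (or a gap), producing an
#' ungapped-core alignment of the theme region across domains. This is the
#' input for [consensus_profile()] when summarizing a bridging theme.
#'
#' @param profile A [build_profile()] result.
#' @param hits A hits tibble (only rows with `retained == TRUE` are used).
#' @param domains The domain tibble.
#' @param gap_open,gap_extend Alignment parameters (match the scan's).
#' @return A [theme_alignment()] of width `profile$width`.
#' @export
theme_region_alignment <- function(profile, hits, domains, gap_open = 11,
                                   gap_extend = 1) {
  kept <- dplyr::filter(hits, .data$retained)
  if (nrow(kept) == 0) abort("no retained hits to stack")
  by_id <- split(domains, domains$id)
  rows <- vapply(seq_len(nrow(kept)), function(i) {
    dom <- by_id[[kept$domain_id[i]]]
    aln <- profile_align_local(profile, dom$sequence, gap_open, gap_extend)
    chars <- rep("-", profile$width)
    ok <- !is.na(aln$pairs$a_idx) & !is.na(aln$pairs$b_idx)
    seq_chars <- strsplit(dom$sequence, "")[[1]]
    chars[aln$pairs$a_idx[ok] + 1L] <- seq_chars[aln$pairs$b_idx[ok] + 1L]
    paste(chars, collapse = "")
  }, character(1))
  theme_alignment(profile$theme_id, rows, source_ids = kept$domain_id)
}
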