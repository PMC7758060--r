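#' Split a domain sequence at a theme hit
#'
#' @param domain One row of a domain tibble (or a list with `id`,
#'   `sequence`).
#' @param start,end 0-based half-open hit interval on the domain.
#' @return A `segmented_domain`: list with `domain_id`, `left_flank`,
#'   `match_segment`, `right_flank`; the three concatenate back to the
#'   original sequence.
#' @export
segment_domain <- function(domain, start, end) {
  seq <- domain$sequence
  n <- nchar(seq)
  if (start < 0 || end > n || start > end) {
    abort(sprintf("hit interval [%d,%d) out of bounds for '%s' (length %d)",
                  start, end, domain$id, n))
  }
  structure(
    list(
      domain_id = domain$id,
      left_flank = substr(seq, 1, start),
      match_segment = substr(seq, start + 1, end),
      right_flank = substr(seq, end + 1, n)
    ),
    class = "segmented_domain"
  )
}

#' Re-align two theme-matching segments (local with global fallback)
#'
#' Smith-Waterman is attempted first; if the local alignment covers less
#' than `min_coverage` (default 50%) of either segment, the pair is
#' re-aligned globally with Needleman-Wunsch and the mode records the
#' fallback.
#'
#' @param a,b The two match segments (non-empty residue strings).
#' @param matrix,gap_open,gap_extend Alignment parameters.
#' @param min_coverage Minimum local-alignment coverage of both segments
#'   before falling back to a global alignment.
#' @return A list with `alignment` (an `alignment_result`) and `mode`
#'   ("SW" or "NW").
#' @export
align_match_segments <- function(a, b, matrix = blosum62(), gap_open = 11,
                                 gap_extend = 1, min_coverage = 0.5) {
  if (!nzchar(a) || !nzchar(b)) abort("match segments must be non-empty")
  sw <- smith_waterman(a, b, matrix, gap_open, gap_extend)
  cov_a <- (sw$a_interval[2] - sw$a_interval[1]) / nchar(a)
  cov_b <- (sw$b_interval[2] - sw$b_interval[1]) / nchar(b)
  if (cov_a < min_coverage || cov_b < min_coverage) {
    list(alignment = needleman_wunsch(a, b, matrix, gap_open, gap_extend),
         mode = "NW")
  } else {
    list(alignment = sw, mode = "SW")
  }
}

#' Random segments from a template's residue composition
#'
#' Draws `n` residue strings of the template's length, residues i.i.d. from
#' the template's empirical amino-acid frequencies (a multinomial model of
#' the segment).
#'
#' @param template Residue string whose composition defines the model.
#' @param n Number of segments.
#' @param seed Integer seed.
#' @return Character vector of `n` strings, each `nchar(template)` long.
#' @export
sample_random_segments <- function(template, n, seed) {
  L <- nchar(template)
  if (L < 1) abort("`template` must be non-empty")
  if (n < 1) abort("`n` must be positive")
  chars <- strsplit(template, "")[[1]]
  withr::with_seed(seed, {
    draws <- sample(chars, n * L, replace = TRUE)
    vapply(seq_len(n),
           function(i) paste(draws[((i - 1) * L + 1):(i * L)], collapse = ""),
           character(1))
  })
}

#' Empirical extreme-value p-value for a segment alignment score
#'
#' Draws `n` random segments from `seg_b`'s multinomial composition model,
#' aligns each to `seg_a` with the same mode and penalties as the observed
#' pair, fits a Gumbel law to the null scores, and evaluates the Gumbel
#' survival probability of the observed score:
#' `p = 1 - exp(-exp(-(s_obs - mu) / beta))`.
#'
#' @param seg_a,seg_b The two matching segments.
#' @param n Number of random segments (default 1000).
#' @param seed Integer seed.
#' @param matrix,gap_open,gap_extend,min_coverage Passed to
#'   [align_match_segments()].
#' @param mode Force "SW" or "NW"; default `NULL` lets the fallback rule of
#'   [align_match_segments()] decide.
#' @return A list with `pvalue`, `score`, `mode`, `fit` (the `gumbel_fit`),
#'   and `alignment`.
#' @export
empirical_pvalue <- function(seg_a, seg_b, n = 1000, seed,
                             matrix = blosum62(), gap_open = 11,
                             gap_extend = 1, min_coverage = 0.5,
                             mode = NULL) {
  if (!nzchar(seg_a) || !nzchar(seg_b)) abort("segments must be non-empty")
  if (is.null(mode)) {
    obs <- align_match_segments(seg_a, seg_b, matrix, gap_open, gap_extend,
                                min_coverage)
  } else {
    aln <- if (mode == "SW") smith_waterman(seg_a, seg_b, matrix, gap_open, gap_extend)
           else needleman_wunsch(seg_a, seg_b, matrix, gap_open, gap_extend)
    obs <- list(alignment = aln, mode = mode)
  }
  rand <- sample_random_segments(seg_b, n, seed)
  codes <- lapply(rand, encode_seq)
  null_scores <- cpp_seq_best_scores(encode_seq(seg_a), codes,
                                     full_matrix(matrix), gap_open, gap_extend,
                                     local = obs$mode == "SW")
  fit <- fit_gumbel(null_scores)
  p <- pgumbel(obs$alignment$score, fit$mu, fit$beta, lower.tail = FALSE)
  list(pvalue = p, score = obs$alignment$score, mode = obs$mode, fit = fit,
       alignment = obs$alignment)
}

#' Flank similarity of two segmented domains
#'
#' Smith-Waterman aligns left flank to left flank and right flank to right
#' flank; the similarity is the sum of the two local scores (an empty flank
#' contributes 0). High values flag pairs whose resemblance extends beyond
#' the shared theme.
#'
#' @param sd_a,sd_b [segment_domain()] results.
#' @inheritParams align_match_segments
#' @return A single numeric score.
#' @export
flank_similarity <- function(sd_a, sd_b, matrix = blosum62(), gap_open = 11,
                             gap_extend = 1) {
  one <- function(x, y) {
    if (!nzchar(x) || !nzchar(y)) return(0)
    smith_waterman(x, y, matrix, gap_open, gap_extend)$score
  }
  one(sd_a$left_flank, sd_b$left_flank) +
    one(sd_a$right_flank, sd_b$right_flank)
}

#' Score all cross-lineage pairs of a bridging theme
#'
#' For every (lineage-A hit, lineage-B hit) pair of each bridging theme, the
#' theme-matching segments are re-aligned (SW with NW fallback), an
#' extreme-value p-value is computed from `n_random` multinomial segments
#' drawn from the B-side segment's composition and aligned to the A-side
#' segment, and the flanks are compared by local alignment. Pairs are
#' retained when `pvalue < p_max` (default 0.05, strict).
#'
#' @param bridging Output of [find_bridging_themes()].
#' @param domains The domain tibble the hits refer to.
#' @param n_random Random segments per pair (default 1000).
#' @param seed Integer seed; pair-level seeds are derived deterministically.
#' @param p_max Retention threshold on the match p-value.
#' @param matrix,gap_open,gap_extend,min_coverage Alignment parameters.
#' @return A candidate tibble: `theme_id`, `domain_a`, `domain_b`, `mode`,
#'   `match_score`, `match_identity`, `match_pvalue`, `flank_similarity`,
#'   `retained`.
#' @export
score_bridge_candidates <- function(bridging, domains, n_random = 1000, seed,
                                    p_max = 0.05, matrix = blosum62(),
                                    gap_open = 11, gap_extend = 1,
                                    min_coverage = 0.5) {
  if (nrow(bridging) == 0) return(empty_candidates())
  by_id <- split(domains, domains$id)
  rows <- list()
  pair_idx <- 0L
  for (t_ in seq_len(nrow(bridging))) {
    hits_a <- bridging$hits_a[[t_]]
    hits_b <- bridging$hits_b[[t_]]
    for (ia in seq_len(nrow(hits_a))) {
      for (ib in seq_len(nrow(hits_b))) {
        pair_idx <- pair_idx + 1L
        ha <- hits_a[ia, ]
        hb <- hits_b[ib, ]
        sd_a <- segment_domain(by_id[[ha$domain_id]], ha$start, ha$end)
        sd_b <- segment_domain(by_id[[hb$domain_id]], hb$start, hb$end)
        ep <- empirical_pvalue(sd_a$match_segment, sd_b$match_segment,
                               n = n_random, seed = seed + pair_idx,
                               matrix = matrix, gap_open = gap_open,
                               gap_extend = gap_extend,
                               min_coverage = min_coverage)
        rows[[pair_idx]] <- tibble::tibble(
          theme_id = bridging$theme_id[t_],
          domain_a = ha$domain_id,
          domain_b = hb$domain_id,
          mode = ep$mode,
          match_score = ep$score,
          match_identity = ep$alignment$identity,
          match_pvalue = ep$pvalue,
          flank_similarity = flank_similarity(sd_a, sd_b, matrix,
                                              gap_open, gap_extend)
        )
      }
    }
  }
  cands <- dplyr::bind_rows(rows)
  dplyr::mutate(cands, retained = .data$match_pvalue < p_max)
}

empty_candidates <- function() {
  tibble::tibble(theme_id = character(), domain_a = character(),
                 domain_b = character(), mode = character(),
                 match_score = double(), match_identity = double(),
                 match_pvalue = double(), flank_similarity = double(),
                 retained = logical())
}

#' Pick representative partners per theme
#'
#' Among retained candidates of each theme, keeps the `k` (default 2) that
#' best combine a similar matching part with dissimilar flanks: candidates
#' are ordered lexicographically by ascending match p-value, then ascending
#' flank similarity, then domain ids, and the first `k` are kept. The result
#' is a deterministic, permutation-invariant function of the candidate set.
#'
#' @param candidates A candidate tibble ([score_bridge_candidates()]); rows
#'   with `retained == FALSE` are dropped first.
#' @param k Representatives per theme (default 2).
#' @return The selected subset, ordered by theme then rank.
#' @export
select_representatives <- function(candidates, k = 2) {
  if (k < 1) abort("`k` must be at least 1")
  candidates |>
    dplyr::filter(.data$retained) |>
    dplyr::arrange(.data$theme_id, .data$match_pvalue, .data$flank_similarity,
                   .data$domain_a, .data$domain_b) |>
    dplyr::group_by(.data$theme_id) |>
    dplyr::slice_head(n = k) |>
    dplyr::ungroup()
}
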