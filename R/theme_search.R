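#' Build a position-specific scoring profile from a theme alignment
#'
#' Column scores are log-odds of observing residue `r` in column `c` against
#' a background frequency table, with a background-proportional pseudocount:
#' `score(c, r) = log2((count(c, r) + pseudocount * background(r)) /
#' ((n_c + pseudocount) * background(r)))`, where `n_c` is the number of
#' non-gap rows in column `c`. Gap characters never contribute to counts.
#'
#' @param theme A [theme_alignment()].
#' @param pseudocount Non-negative pseudocount mass (default 1). A strictly
#'   positive value keeps unobserved residues at finite scores.
#' @param background Named residue-frequency vector summing to 1 over the 20
#'   amino acids (plus optionally `X`); default uniform over the 20.
#' @return A `theme_profile`: list with `theme_id`, `width`, `column_scores`
#'   (width x alphabet matrix), `background`, `consensus`.
#' @export
build_profile <- function(theme, pseudocount = 1, background = NULL) {
  stopifnot(inherits(theme, "theme_alignment"))
  if (pseudocount < 0) abort("`pseudocount` must be non-negative")
  background <- normalize_background(background)
  aa <- names(background)
  mat <- do.call(rbind, strsplit(theme$rows, ""))
  scores <- matrix(NA_real_, nrow = theme$width, ncol = length(aa),
                   dimnames = list(NULL, aa))
  for (c_ in seq_len(theme$width)) {
    col <- mat[, c_]
    col <- col[col != "-"]
    n_c <- length(col)
    counts <- table(factor(col, levels = aa))
    scores[c_, ] <- log2((as.numeric(counts) + pseudocount * background) /
                           ((n_c + pseudocount) * background))
  }
  structure(
    list(theme_id = theme$theme_id, width = theme$width,
         column_scores = scores, background = background,
         consensus = attr(consensus_profile(theme), "consensus")),
    class = "theme_profile"
  )
}

normalize_background <- function(background) {
  aa20 <- AA_ALPHABET21[1:20]
  if (is.null(background)) {
    background <- setNames(rep(1 / 20, 20), aa20)
  }
  if (is.null(names(background)) || !all(names(background) %in% AA_ALPHABET21)) {
    abort("`background` must be named by residue symbols")
  }
  if (any(background <= 0)) abort("background frequencies must be positive")
  background / sum(background)
}

#' Residue background frequencies of a domain database
#'
#' @param domains A domain tibble ([read_domain_fasta()]).
#' @param pseudo Small count added to every residue so no frequency is zero.
#' @return Named frequency vector over the 20 amino acids, summing to 1.
#' @export
database_background <- function(domains, pseudo = 1) {
  aa20 <- AA_ALPHABET21[1:20]
  chars <- unlist(strsplit(domains$sequence, ""), use.names = FALSE)
  counts <- table(factor(chars[chars != "X"], levels = aa20))
  freq <- as.numeric(counts) + pseudo
  setNames(freq / sum(freq), aa20)
}

#' @export
print.theme_profile <- function(x, ...) {
  cat(sprintf("<theme_profile> '%s': width %d, consensus %s\n",
              x$theme_id, x$width, x$consensus))
  invisible(x)
}

#' Calibrate an empirical E-value null for a profile
#'
#' Each of `n_shuffles` draws permutes the residues of one randomly chosen
#' database sequence and records the best local profile alignment score; a
#' Gumbel law is fitted to the scores (method of moments, then maximum
#' likelihood). The E-value of an observed score `s` is then
#' `E(s) = n_database * (1 - GumbelCDF(s))`: the expected number of database
#' sequences reaching `s` by chance.
#'
#' @param profile A [build_profile()] result.
#' @param domains Domain tibble (the database being scanned).
#' @param n_shuffles Number of shuffled sequences (>= 100; default 1000).
#' @param seed Integer seed; the calibration is reproducible under it.
#' @param gap_open,gap_extend Affine gap penalties used for the scan.
#' @return A `gumbel_fit` with an `n_database` attribute used by [evalue()].
#' @export
calibrate_evalue <- function(profile, domains, n_shuffles = 1000, seed,
                             gap_open = 11, gap_extend = 1) {
  if (n_shuffles < 100) abort("`n_shuffles` must be at least 100")
  if (nrow(domains) == 0) abort("cannot calibrate against an empty database")
  codes <- lapply(domains$sequence, encode_seq)
  scores <- withr::with_seed(seed, {
    picks <- sample.int(nrow(domains), n_shuffles, replace = TRUE)
    shuffled <- lapply(picks, function(i) sample(codes[[i]]))
    cpp_profile_best_scores(profile_score_table(profile), shuffled,
                            gap_open, gap_extend)
  })
  fit <- fit_gumbel(scores)
  attr(fit, "n_database") <- nrow(domains)
  fit
}

#' @rdname calibrate_evalue
#' @param s Observed alignment score(s).
#' @param fit A calibrated `gumbel_fit`.
#' @export
evalue <- function(s, fit) {
  n_db <- attr(fit, "n_database")
  if (is.null(n_db)) abort("`fit` has no database size; use calibrate_evalue()")
  n_db * pgumbel(s, fit$mu, fit$beta, lower.tail = FALSE)
}

#' Scan a domain database with a theme profile
#'
#' Aligns the profile locally against every domain, converts scores to
#' E-values under the calibrated null, and applies the hit filters:
#' `evalue < evalue_max` AND `coverage >= coverage_min` AND
#' `aln_length >= min_aln_length` (defaults 1e-3, 0.85, 20). Coverage is the
#' fraction of profile columns consumed by the local alignment; `aln_length`
#' the number of alignment columns.
#'
#' @inheritParams calibrate_evalue
#' @param fit The calibrated null from [calibrate_evalue()].
#' @param evalue_max,coverage_min,min_aln_length Hit filters.
#' @return A tibble of hits sorted by ascending E-value: `theme_id`,
#'   `domain_id`, `lineage`, `fgroup`, `start`, `end` (0-based half-open on
#'   the domain), `score`, `evalue`, `coverage`, `aln_length`, `retained`.
#' @export
scan_database <- function(profile, domains, fit, gap_open = 11, gap_extend = 1,
                          evalue_max = 1e-3, coverage_min = 0.85,
                          min_aln_length = 20) {
  if (nrow(domains) == 0) {
    return(empty_hits())
  }
  res <- purrr::map(domains$sequence, function(s) {
    profile_align_local(profile, s, gap_open, gap_extend)
  })
  hits <- tibble::tibble(
    theme_id = profile$theme_id,
    domain_id = domains$id,
    lineage = domains$lineage,
    fgroup = domains$fgroup,
    start = purrr::map_int(res, ~ .x$b_interval[1]),
    end = purrr::map_int(res, ~ .x$b_interval[2]),
    score = purrr::map_dbl(res, "score"),
    coverage = purrr::map_dbl(res, ~ (.x$a_interval[2] - .x$a_interval[1]) / profile$width),
    aln_length = purrr::map_int(res, ~ as.integer(.x$length))
  )
  hits$evalue <- evalue(hits$score, fit)
  hits <- apply_hit_filters(hits, evalue_max, coverage_min, min_aln_length)
  dplyr::arrange(hits, .data$evalue, .data$domain_id)
}

empty_hits <- function() {
  tibble::tibble(
    theme_id = character(), domain_id = character(), lineage = character(),
    fgroup = character(), start = integer(), end = integer(),
    score = double(), coverage = double(), aln_length = integer(),
    evalue = double(), retained = logical()
  )
}

#' @rdname scan_database
#' @param hits A hits tibble.
#' @export
apply_hit_filters <- function(hits, evalue_max = 1e-3, coverage_min = 0.85,
                              min_aln_length = 20) {
  dplyr::mutate(
    hits,
    retained = .data$evalue < evalue_max &
      .data$coverage >= coverage_min &
      .data$aln_length >= min_aln_length
  )
}

#' Intersect retained hits across two lineages
#'
#' A theme "bridges" two lineages when it has at least one retained hit in
#' each. Returns one row per (theme, lineage-A hit, lineage-B hit) pair, in
#' deterministic theme/domain order, ready for pairwise re-alignment.
#'
#' @param hits A hits tibble (typically several themes' scans bound together).
#' @param lineage_a,lineage_b The two lineage labels (e.g. "2004", "2003").
#' @param known_lineages Optional character vector of valid labels; labels
#'   outside it are an error.
#' @return A tibble with `theme_id`, `n_hits_a`, `n_hits_b` and list-columns
#'   `hits_a`, `hits_b` of the retained hits, one row per bridging theme.
#' @export
find_bridging_themes <- function(hits, lineage_a, lineage_b,
                                 known_lineages = NULL) {
  if (!is.null(known_lineages)) {
    unknown <- setdiff(c(lineage_a, lineage_b), known_lineages)
    if (length(unknown) > 0) {
      abort(sprintf("unknown lineage label(s): %s", paste(unknown, collapse = ", ")))
    }
  }
  kept <- dplyr::filter(hits, .data$retained)
  if (nrow(kept) == 0) return(empty_bridging())
  kept |>
    dplyr::group_by(.data$theme_id) |>
    dplyr::group_modify(function(g, key) {
      a <- dplyr::filter(g, .data$lineage == lineage_a) |>
        dplyr::arrange(.data$evalue, .data$domain_id)
      b <- dplyr::filter(g, .data$lineage == lineage_b) |>
        dplyr::arrange(.data$evalue, .data$domain_id)
      if (nrow(a) == 0 || nrow(b) == 0) return(tibble::tibble())
      tibble::tibble(n_hits_a = nrow(a), n_hits_b = nrow(b),
                     hits_a = list(a), hits_b = list(b))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$theme_id)
}

empty_bridging <- function() {
  tibble::tibble(theme_id = character(), n_hits_a = integer(),
                 n_hits_b = integer(), hits_a = list(), hits_b = list())
}
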