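#' Specifications for synthetic lineages and the planted theme
#'
#' `lineage_spec()` describes one simulated fold lineage: a set of families,
#' each derived from its own random consensus, with sequences mutated away
#' from that consensus at stated per-position substitution rates (theme
#' region vs flanks). `planted_theme()` describes the conserved element
#' shared across lineages: a 25-residue core imitating a beta-strand,
#' Gly-rich phosphate-binding loop (with the Walker-A-like glycines and
#' lysine), a helix, and a downstream Asp anchor; anchor positions are never
#' mutated.
#'
#' @param lineage_label Lineage label (plays the role of an ECOD X-group,
#'   e.g. "2004").
#' @param n_families,seqs_per_family Family structure of the lineage.
#' @param flank_length_range Inclusive range the two flank lengths are drawn
#'   from, per family.
#' @param substitution_rate_theme,substitution_rate_flank Per-position
#'   probability in `[0, 1]` that a residue is replaced (by one of the other
#'   19) relative to the family consensus.
#' @param seed Integer seed for everything stochastic in the lineage.
#' @return A `lineage_spec` / `planted_theme` list.
#' @export
lineage_spec <- function(lineage_label, n_families = 4, seqs_per_family = 2,
                         flank_length_range = c(60, 120),
                         substitution_rate_theme = 0.3,
                         substitution_rate_flank = 1.0, seed = 1) {
  stopifnot(substitution_rate_theme >= 0, substitution_rate_theme <= 1,
            substitution_rate_flank >= 0, substitution_rate_flank <= 1,
            n_families >= 1, seqs_per_family >= 1,
            all(flank_length_range >= 1))
  structure(
    list(lineage_label = lineage_label, n_families = n_families,
         seqs_per_family = seqs_per_family,
         flank_length_range = as.integer(flank_length_range),
         substitution_rate_theme = substitution_rate_theme,
         substitution_rate_flank = substitution_rate_flank,
         seed = as.integer(seed)),
    class = "lineage_spec"
  )
}

# Default 25-residue core: beta1 (ILVA), Gly-rich P-loop GGSGSGKST with the
# Walker-A-like glycines and lysine, a short helix, and the beta2 Asp anchor.
DEFAULT_THEME_CORE <- "ILVAGGSGSGKSTLARELAKRLDAD"
DEFAULT_THEME_ANCHORS <- c(5L, 6L, 8L, 10L, 11L, 25L) # G,G,G,G,K and the final D

#' @rdname lineage_spec
#' @param core Residue string of length >= 20 (so planted hits can pass the
#'   length filter).
#' @param anchor_positions 1-based positions in `core` that are never
#'   mutated.
#' @export
planted_theme <- function(core = DEFAULT_THEME_CORE,
                          anchor_positions = DEFAULT_THEME_ANCHORS) {
  if (nchar(core) < 20) abort("theme core must be at least 20 residues")
  encode_seq(core, "core")
  if (any(anchor_positions < 1 | anchor_positions > nchar(core))) {
    abort("anchor positions must fall inside the core")
  }
  structure(list(core = core, anchor_positions = as.integer(anchor_positions)),
            class = "planted_theme")
}

random_seq <- function(n) {
  paste(sample(AA_ALPHABET21[1:20], n, replace = TRUE), collapse = "")
}

# per-position substitution: with prob `rate`, replace by one of the other 19
mutate_seq <- function(seq, rate, protect = integer(0)) {
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) < rate
  hit[protect] <- FALSE
  if (any(hit)) {
    aa20 <- AA_ALPHABET21[1:20]
    chars[hit] <- vapply(chars[hit],
                         function(c_) sample(setdiff(aa20, c_), 1),
                         character(1))
  }
  paste(chars, collapse = "")
}

#' Generate two synthetic lineages sharing a planted theme
#'
#' Each family derives from a random consensus (uniform over the 20 amino
#' acids). In a `fraction_planted` share of each lineage's families, the
#' theme core is embedded between the family's random flanks; family members
#' mutate the theme at `substitution_rate_theme` (anchors exempt) and the
#' flanks at `substitution_rate_flank`. Unplanted families are pure flank
#' material of matching total length. The truth table records where the
#' theme really sits.
#'
#' @param spec_a,spec_b [lineage_spec()]s for the two lineages.
#' @param theme A [planted_theme()].
#' @param fraction_planted Fraction of families per lineage carrying the
#'   theme (default 0.5).
#' @return A list with `domains` (domain tibble: `id`, `lineage`, `fgroup`,
#'   `sequence`) and `truth` (tibble: `domain_id`, `planted`, `start`, `end`
#'   0-based half-open).
#' @export
generate_lineages <- function(spec_a, spec_b, theme = planted_theme(),
                              fraction_planted = 0.5) {
  if (fraction_planted < 0 || fraction_planted > 1) {
    abort("`fraction_planted` must be in [0, 1]")
  }
  parts <- lapply(list(spec_a, spec_b), generate_one_lineage,
                  theme = theme, fraction_planted = fraction_planted)
  list(
    domains = dplyr::bind_rows(purrr::map(parts, "domains")),
    truth = dplyr::bind_rows(purrr::map(parts, "truth"))
  )
}

generate_one_lineage <- function(spec, theme, fraction_planted) {
  core_len <- nchar(theme$core)
  n_planted <- round(fraction_planted * spec$n_families)
  withr::with_seed(spec$seed, {
    dom_rows <- list()
    truth_rows <- list()
    planted_families <- if (n_planted > 0) {
      sort(sample.int(spec$n_families, n_planted))
    } else integer(0)
    for (f in seq_len(spec$n_families)) {
      lo <- spec$flank_length_range[1]
      hi <- spec$flank_length_range[2]
      l_left <- sample(lo:hi, 1)
      l_right <- sample(lo:hi, 1)
      left_cons <- random_seq(l_left)
      right_cons <- random_seq(l_right)
      planted <- f %in% planted_families
      mid_cons <- if (planted) theme$core else random_seq(core_len)
      fgroup <- sprintf("%s.1.1.%d", spec$lineage_label, f)
      for (s in seq_len(spec$seqs_per_family)) {
        left <- mutate_seq(left_cons, spec$substitution_rate_flank)
        right <- mutate_seq(right_cons, spec$substitution_rate_flank)
        mid <- if (planted) {
          mutate_seq(mid_cons, spec$substitution_rate_theme,
                     protect = theme$anchor_positions)
        } else {
          mutate_seq(mid_cons, spec$substitution_rate_flank)
        }
        id <- sprintf("%s_f%02d_s%02d", spec$lineage_label, f, s)
        dom_rows[[length(dom_rows) + 1L]] <- tibble::tibble(
          id = id, lineage = spec$lineage_label, fgroup = fgroup,
          sequence = paste0(left, mid, right)
        )
        if (planted) {
          truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
            domain_id = id, planted = TRUE,
            start = l_left, end = l_left + core_len
          )
        }
      }
    }
    list(domains = dplyr::bind_rows(dom_rows),
         truth = dplyr::bind_rows(truth_rows))
  })
}

#' Generate a theme alignment by mutating the core
#'
#' `n_rows` independently mutated, ungapped copies of the core (anchors
#' preserved): the stand-in for a curated theme's seed alignment.
#'
#' @param theme A [planted_theme()].
#' @param n_rows Number of rows.
#' @param rate Per-position substitution rate.
#' @param seed Integer seed.
#' @return A [theme_alignment()] with `theme_id = "planted"`.
#' @export
generate_theme_msa <- function(theme, n_rows = 20, rate = 0.2, seed = 1) {
  if (n_rows < 1) abort("`n_rows` must be positive")
  rows <- withr::with_seed(seed, {
    vapply(seq_len(n_rows),
           function(i) mutate_seq(theme$core, rate, theme$anchor_positions),
           character(1))
  })
  theme_alignment("planted", rows,
                  source_ids = sprintf("synthetic%02d", seq_len(n_rows)))
}

#' Synthetic loop coordinate pairs for superposition tests
#'
#' Returns a base helix-like Cα trace (2.3 Å radius, 1.5 Å rise, 100° turn
#' per residue) and a copy moved by a known rigid motion, optionally
#' perturbed by isotropic Gaussian noise. The true transform is attached so
#' recovery can be checked.
#'
#' @param n_atoms Number of trace points (>= 3; default 11, the length of a
#'   phosphate-binding loop selection).
#' @param noise_sigma Per-axis Gaussian noise (Angstrom) added to the moved
#'   copy.
#' @param rotation 3 x 3 proper rotation of the true motion (default: a
#'   fixed non-trivial rotation).
#' @param translation Length-3 translation of the true motion.
#' @param seed Integer seed (used only when `noise_sigma > 0`).
#' @return A list with `base`, `moved` (n x 3 matrices), `rotation`,
#'   `translation`.
#' @export
generate_loop_coords <- function(n_atoms = 11, noise_sigma = 0,
                                 rotation = NULL, translation = c(5, -3, 2),
                                 seed = 1) {
  if (n_atoms < 3) abort("`n_atoms` must be at least 3")
  if (is.null(rotation)) rotation <- rotation_matrix(0.7, c(1, 2, 2))
  i <- seq_len(n_atoms) - 1
  ang <- i * 100 * pi / 180
  base <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
  moved <- base %*% t(rotation) +
    matrix(translation, n_atoms, 3, byrow = TRUE)
  if (noise_sigma > 0) {
    moved <- moved + withr::with_seed(seed, {
      matrix(stats::rnorm(3 * n_atoms, sd = noise_sigma), n_atoms, 3)
    })
  }
  list(base = base, moved = moved, rotation = rotation,
       translation = translation)
}

#' @rdname generate_loop_coords
#' @param angle Rotation angle (radians).
#' @param axis Rotation axis (length-3, need not be unit).
#' @export
rotation_matrix <- function(angle, axis) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
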