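#' Pipeline configuration
#'
#' A single flat configuration drives every stage. Defaults hold the
#' method's thresholds: E-value < 1e-3, theme coverage >= 85%, alignment
#' length >= 20 for the scan; p < 0.05 against 1000 multinomial random
#' segments for pair retention; 2 representatives per theme; clustering at
#' 70% identity. The seed is mandatory for every stochastic stage.
#'
#' @param seed Integer seed (required).
#' @param ... Overrides for any default listed below.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(seed, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # scan filters
    evalue_max = 1e-3,
    coverage_min = 0.85,
    min_aln_length = 20,
    # alignment
    gap_open = 11,
    gap_extend = 1,
    # profile / calibration
    pseudocount = 1,
    n_shuffles = 1000,
    # bridge statistics
    p_max = 0.05,
    n_random = 1000,
    k_representatives = 2,
    sw_min_coverage = 0.5,
    # conservation
    identity_threshold = 0.70,
    # lineage labels
    lineage_a = "2004",
    lineage_b = "2003",
    # synthetic generation (used when no input FASTA is given)
    n_families = 4,
    seqs_per_family = 2,
    flank_length_range = c(60, 120),
    substitution_rate_theme = 0.3,
    substitution_rate_flank = 1.0,
    fraction_planted = 0.5,
    theme_msa_rows = 20,
    theme_msa_rate = 0.2
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  # small provenance stamp: deterministic digest of the deparsed config
  flat <- paste(names(cfg), vapply(cfg, function(x) paste(format(x), collapse = ","),
                                   character(1)),
                sep = "=", collapse = ";")
  sprintf("%08x", sum(utf8ToInt(flat) * (seq_along(utf8ToInt(flat)) %% 97 + 1)) %% .Machine$integer.max)
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full bridging-theme pipeline
#'
#' generate (or load) -> profile -> calibrate -> scan -> filter -> bridge ->
#' p-values -> representatives -> consensus. Deterministic given the config:
#' the same config (including seed) reproduces every report byte for byte.
#'
#' @param config A [default_config()] result.
#' @param domains Optional domain tibble; if `NULL`, a synthetic two-lineage
#'   database with a planted theme is generated from the config.
#' @param theme Optional [theme_alignment()] query; if `NULL`, a synthetic
#'   theme alignment is generated from the same planted core.
#' @param out_dir Optional directory; when given, the hits table, bridge
#'   report and consensus table are written there.
#' @param verbose Log stage counts via `message()` (default TRUE).
#' @return A list with `domains`, `truth` (synthetic runs only), `profile`,
#'   `calibration`, `hits`, `bridging`, `candidates`, `representatives`,
#'   `consensus` (a [consensus_profile()] or `NULL`), and `config`.
#' @export
run_bridge_pipeline <- function(config, domains = NULL, theme = NULL,
                                out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL
  planted <- planted_theme()
  if (is.null(domains)) {
    spec_a <- lineage_spec(config$lineage_a, config$n_families,
                           config$seqs_per_family, config$flank_length_range,
                           config$substitution_rate_theme,
                           config$substitution_rate_flank,
                           seed = config$seed)
    spec_b <- lineage_spec(config$lineage_b, config$n_families,
                           config$seqs_per_family, config$flank_length_range,
                           config$substitution_rate_theme,
                           config$substitution_rate_flank,
                           seed = config$seed + 1000L)
    gen <- generate_lineages(spec_a, spec_b, planted, config$fraction_planted)
    domains <- gen$domains
    truth <- gen$truth
    pipeline_log(verbose, "generated %d domains (%d carrying the theme)",
                 nrow(domains), nrow(truth))
  }
  if (is.null(theme)) {
    theme <- generate_theme_msa(planted, config$theme_msa_rows,
                                config$theme_msa_rate,
                                seed = config$seed + 2000L)
  }
  background <- database_background(domains)
  profile <- build_profile(theme, config$pseudocount, background)
  fit <- calibrate_evalue(profile, domains, config$n_shuffles,
                          seed = config$seed + 3000L,
                          gap_open = config$gap_open,
                          gap_extend = config$gap_extend)
  pipeline_log(verbose, "calibrated null: mu=%.2f beta=%.2f (n=%d shuffles)",
               fit$mu, fit$beta, fit$n_samples)
  hits <- scan_database(profile, domains, fit, config$gap_open,
                        config$gap_extend, config$evalue_max,
                        config$coverage_min, config$min_aln_length)
  pipeline_log(verbose, "scan: %d/%d hits pass E<%g, coverage>=%g, length>=%d",
               sum(hits$retained), nrow(hits), config$evalue_max,
               config$coverage_min, config$min_aln_length)
  bridging <- find_bridging_themes(hits, config$lineage_a, config$lineage_b,
                                   known_lineages = unique(domains$lineage))
  pipeline_log(verbose, "bridging themes: %d", nrow(bridging))
  candidates <- score_bridge_candidates(bridging, domains, config$n_random,
                                        seed = config$seed + 4000L,
                                        p_max = config$p_max,
                                        gap_open = config$gap_open,
                                        gap_extend = config$gap_extend,
                                        min_coverage = config$sw_min_coverage)
  pipeline_log(verbose, "cross-lineage pairs: %d scored, %d retained at p<%g",
               nrow(candidates), sum(candidates$retained), config$p_max)
  representatives <- select_representatives(candidates,
                                            config$k_representatives)
  consensus <- NULL
  if (sum(hits$retained) > 0) {
    region_hits <- dplyr::semi_join(
      hits,
      cluster_centroids(hits, domains, config),
      by = "domain_id"
    )
    consensus <- consensus_profile(
      theme_region_alignment(profile, region_hits, domains,
                             config$gap_open, config$gap_extend)
    )
  }
  result <- list(domains = domains, truth = truth, profile = profile,
                 calibration = fit, hits = hits, bridging = bridging,
                 candidates = candidates, representatives = representatives,
                 consensus = consensus, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_hits_table(hits, file.path(out_dir, "hits.tsv"))
    write_bridge_report(candidates, config, file.path(out_dir, "bridge.tsv"))
    if (!is.null(consensus)) {
      write_conservation_table(consensus, file.path(out_dir, "consensus.tsv"))
    }
  }
  result
}

# cluster retained-hit domains at the config identity threshold and keep
# centroids, mirroring redundancy reduction before consensus calculation
cluster_centroids <- function(hits, domains, config) {
  kept_ids <- unique(hits$domain_id[hits$retained])
  doms <- domains[domains$id %in% kept_ids, , drop = FALSE]
  cl <- cluster_sequences(doms, config$identity_threshold,
                          gap_open = config$gap_open,
                          gap_extend = config$gap_extend)
  tibble::tibble(domain_id = cl$id[cl$is_centroid])
}

#' Write the bridge-candidate report
#'
#' TSV columns: `theme_id`, `domain_a`, `domain_b`, `mode`, `match_score`,
#' `match_pvalue`, `flank_similarity`, `retained`; a comment line carries
#' the config hash for provenance.
#'
#' @param candidates Candidate tibble.
#' @param config The run config (hashed into the header).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bridge_report <- function(candidates, config, path) {
  body <- readr::format_tsv(
    candidates[, c("theme_id", "domain_a", "domain_b", "mode", "match_score",
                   "match_pvalue", "flank_similarity", "retained")]
  )
  writeLines(c(
    sprintf("# themebridge bridge report; config %s", config_hash(config)),
    strsplit(body, "\n", fixed = TRUE)[[1]]
  ), path)
  invisible(path)
}

#' Run the loop-superposition / ligand-transplant stage
#'
#' Reads donor and acceptor structures, superposes the donor loop onto the
#' acceptor loop on the selected atoms, reports the Cα RMSD, and (when a
#' ligand name is given) writes the acceptor plus the transplanted ligand.
#' The defaults of `donor_sel`/`acceptor_sel` are the phosphate-binding
#' loops used for the Hpr-kinase modeling: donor residues 247-257 onto
#' acceptor chain A residues 150-160.
#'
#' @param donor_path,acceptor_path PDB file paths.
#' @param donor_sel,acceptor_sel [loop_selection()]s.
#' @param ligand_resname HETATM residue name to transplant (`NULL` to only
#'   superpose).
#' @param out_path Optional output PDB path for the merged model.
#' @param verbose Log the RMSD.
#' @return A list with `superposition`, `model` (merged model or `NULL`),
#'   `out_path`.
#' @export
run_overlay <- function(donor_path, acceptor_path,
                        donor_sel = loop_selection("A", 247, 257),
                        acceptor_sel = loop_selection("A", 150, 160),
                        ligand_resname = NULL, out_path = NULL,
                        verbose = TRUE) {
  donor <- read_structure(donor_path)
  acceptor <- read_structure(acceptor_path)
  if (!is.null(ligand_resname)) {
    model <- transplant_ligand(donor, acceptor, donor_sel, acceptor_sel,
                               ligand_resname)
    sup <- attr(model, "superposition")
  } else {
    sup <- kabsch_superpose(extract_loop(donor, donor_sel),
                            extract_loop(acceptor, acceptor_sel))
    model <- NULL
  }
  pipeline_log(verbose, "loop superposition: RMSD %.4f A over %d atoms",
               sup$rmsd, sup$n_atoms)
  if (!is.null(out_path) && !is.null(model)) {
    write_transplant(model, out_path)
  }
  list(superposition = sup, model = model, out_path = out_path)
}
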