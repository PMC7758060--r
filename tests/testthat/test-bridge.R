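test_that("segmenting splits a domain exactly at the hit interval", {
  dom <- list(id = "d1", sequence = "AAAGGGKKK")
  sd <- segment_domain(dom, 3L, 6L)
  expect_equal(sd$left_flank, "AAA")
  expect_equal(sd$match_segment, "GGG")
  expect_equal(sd$right_flank, "KKK")
  expect_equal(paste0(sd$left_flank, sd$match_segment, sd$right_flank),
               dom$sequence)
  # hit spanning the whole sequence
  full <- segment_domain(dom, 0L, 9L)
  expect_equal(full$left_flank, "")
  expect_equal(full$right_flank, "")
  # prefix hit
  pre <- segment_domain(dom, 0L, 3L)
  expect_equal(pre$left_flank, "")
  expect_equal(pre$match_segment, "AAA")
  expect_error(segment_domain(dom, 3L, 10L), "out of bounds")
})

test_that("match re-alignment falls back to global when local coverage is low", {
  seg <- withr::with_seed(21, random_aa_string(25))
  same <- align_match_segments(seg, seg)
  expect_equal(same$mode, "SW")
  expect_equal(same$alignment$identity, 1.0)
  # two segments sharing only a 5-mer core: the local alignment covers
  # ~20% of each segment, far below the 50% floor, so the rule fires
  shared <- "WWWWW"
  a <- withr::with_seed(22, paste0(random_aa_string(10), shared, random_aa_string(10)))
  b <- withr::with_seed(23, paste0(random_aa_string(10), shared, random_aa_string(10)))
  sw <- smith_waterman(a, b)
  cov <- max((sw$a_interval[2] - sw$a_interval[1]) / nchar(a),
             (sw$b_interval[2] - sw$b_interval[1]) / nchar(b))
  expect_lt(cov, 0.5)
  res <- align_match_segments(a, b)
  expect_equal(res$mode, "NW")
  expect_equal(res$alignment$mode, "global")
  expect_error(align_match_segments("", "GKT"), "non-empty")
})

test_that("the printed P-loop segment aligns to itself perfectly", {
  pbl <- "VGPNGSGKSTV"
  res <- align_match_segments(pbl, pbl)
  expect_equal(res$mode, "SW")
  expect_equal(res$alignment$identity, 1.0)
})

test_that("multinomial segment sampling honors length, composition, and seed", {
  expect_equal(sample_random_segments("AAAA", 5, seed = 1),
               rep("AAAA", 5)) # degenerate composition
  segs <- withr::with_seed(20, sample_random_segments(random_aa_string(30), 50, seed = 2))
  expect_true(all(nchar(segs) == 30))
  # frequency concentration: A appears with frequency 1/2 +- 0.01 when
  # sampling many segments from the template "AC"
  big <- sample_random_segments("AC", 1e5, seed = 3)
  freq_a <- mean(strsplit(paste(big, collapse = ""), "")[[1]] == "A")
  expect_lt(abs(freq_a - 0.5), 0.01)
  # only template residues ever appear
  expect_true(all(strsplit(paste(big[1:100], collapse = ""), "")[[1]] %in% c("A", "C")))
})

test_that("segment sampling is reproducible under its seed", {
  tpl <- withr::with_seed(24, random_aa_string(20))
  expect_identical(sample_random_segments(tpl, 10, seed = 5),
                   sample_random_segments(tpl, 10, seed = 5))
})

test_that("empirical p-values behave like p-values", {
  # a segment aligned against itself: overwhelming significance
  res <- withr::with_seed(25, {
    a <- random_aa_string(25)
    empirical_pvalue(a, a, n = 400, seed = 31)
  })
  expect_lt(res$pvalue, 0.05)
  expect_true(res$pvalue >= 0 && res$pvalue <= 1)
  # monotone decreasing in the observed score for a fixed fit
  fit <- res$fit
  s <- seq(fit$mu - 5, fit$mu + 20, by = 1)
  p <- pgumbel(s, fit$mu, fit$beta, lower.tail = FALSE)
  expect_true(all(diff(p) < 0))
  # survival at the fitted location is 1 - exp(-1)
  expect_equal(pgumbel(fit$mu, fit$mu, fit$beta, lower.tail = FALSE),
               1 - exp(-1))
})

test_that("null p-values for unrelated segments are roughly uniform", {
  ps <- withr::with_seed(26, {
    vapply(1:60, function(i) {
      empirical_pvalue(random_aa_string(30), random_aa_string(30),
                       n = 200, seed = 500 + i, mode = "SW")$pvalue
    }, numeric(1))
  })
  expect_gt(min(ps), 0)
  expect_lte(max(ps), 1)
  # a crude calibration check at this small n; the acceptance suite runs
  # the full 500-pair Kolmogorov-Smirnov version
  expect_gt(mean(ps > 0.5), 0.25)
  expect_gt(mean(ps < 0.5), 0.25)
})

test_that("flank similarity scores flanks side by side", {
  sd_of <- function(l, m, r) {
    segment_domain(list(id = "x", sequence = paste0(l, m, r)),
                   nchar(l), nchar(l) + nchar(m))
  }
  a_flank <- withr::with_seed(27, random_aa_string(20))
  core <- "GESGSGKST"
  both_empty <- flank_similarity(sd_of("", core, ""), sd_of("", core, ""))
  expect_equal(both_empty, 0)
  ident <- flank_similarity(sd_of(a_flank, core, a_flank),
                            sd_of(a_flank, core, a_flank))
  expect_equal(ident, 2 * smith_waterman(a_flank, a_flank)$score)
  rand <- withr::with_seed(28, flank_similarity(
    sd_of(random_aa_string(20), core, random_aa_string(20)),
    sd_of(random_aa_string(20), core, random_aa_string(20))
  ))
  expect_lt(rand, ident)
})

test_that("representative selection follows the stated lexicographic order", {
  cands <- tibble::tibble(
    theme_id = "t",
    domain_a = "p",
    domain_b = c("r1", "r2", "r3"),
    mode = "SW",
    match_score = c(80, 70, 75),
    match_identity = 0.7,
    match_pvalue = c(0.001, 0.003, 0.003),
    flank_similarity = c(50, 10, 40),
    retained = TRUE
  )
  sel <- select_representatives(cands, k = 2)
  expect_equal(nrow(sel), 2)
  expect_equal(sort(sel$domain_b), c("r1", "r2")) # p then flank similarity
  # permutation invariance
  sel2 <- select_representatives(cands[c(3, 1, 2), ], k = 2)
  expect_equal(dplyr::arrange(sel, domain_b), dplyr::arrange(sel2, domain_b))
  # fewer candidates than k: all kept
  expect_equal(nrow(select_representatives(cands[1, ], k = 2)), 1)
  # non-retained candidates never selected
  cands$retained[1] <- FALSE
  expect_false("r1" %in% select_representatives(cands, 2)$domain_b)
})

test_that("retention threshold on the p-value is strict", {
  cands <- tibble::tibble(
    theme_id = "t", domain_a = "p", domain_b = c("x", "y"), mode = "SW",
    match_score = 50, match_identity = 0.5,
    match_pvalue = c(0.049, 0.05), flank_similarity = 0
  )
  out <- dplyr::mutate(cands, retained = match_pvalue < 0.05)
  expect_equal(out$retained, c(TRUE, FALSE))
})
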