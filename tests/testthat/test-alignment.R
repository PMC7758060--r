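test_that("local alignment reproduces hand-derived scores", {
  r <- smith_waterman("GKT", "GKT")
  expect_equal(r$score, 16) # 6 + 5 + 5 under BLOSUM62
  expect_equal(r$identity, 1.0)
  expect_equal(r$a_interval, c(0L, 3L))
  expect_equal(r$mode, "local")

  # empty input contract
  e <- smith_waterman("", "GKT")
  expect_equal(e$score, 0)
  expect_equal(e$a_interval, c(0L, 0L))
  expect_equal(nrow(e$pairs), 0)
})

test_that("the two printed phosphate-binding loops share 5/11 positions", {
  a <- "FGLSGTGKTTL"
  b <- "VGPNGSGKSTV"
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  expect_equal(sum(ca == cb), 5) # G, G, G, K, T
  expect_equal(ca[ca == cb], c("G", "G", "G", "K", "T"))
  # the global alignment of the pair is the ungapped one
  g <- needleman_wunsch(a, b)
  expect_equal(g$length, 11)
  expect_equal(g$identity, 5 / 11)
  # each loop aligned to itself is a perfect local match
  expect_equal(smith_waterman(b, b)$identity, 1.0)
})

test_that("global alignment handles degenerate cases", {
  r <- needleman_wunsch("AAA", "AAA")
  expect_equal(r$identity, 1.0)
  expect_equal(r$score, 12)
  expect_error(needleman_wunsch("A", ""), "non-empty")
  expect_equal(needleman_wunsch("A", "G")$score, 0) # BLOSUM62[A,G]
})

test_that("scores match the exhaustive enumeration oracle (tiny strings)", {
  set.seed(41)
  for (i in 1:12) {
    a <- random_aa_string(sample(1:5, 1))
    b <- random_aa_string(sample(1:5, 1))
    expect_equal(smith_waterman(a, b)$score,
                 enumerate_align_score(a, b, local = TRUE),
                 info = paste(a, b))
    expect_equal(needleman_wunsch(a, b)$score,
                 enumerate_align_score(a, b, local = FALSE),
                 info = paste(a, b))
    # the cached recursion agrees with the pure enumeration
    expect_equal(oracle_align_score(a, b, local = TRUE),
                 enumerate_align_score(a, b, local = TRUE))
    expect_equal(oracle_align_score(a, b, local = FALSE),
                 enumerate_align_score(a, b, local = FALSE))
  }
})

test_that("scores match an independent reference implementation", {
  set.seed(42)
  b62_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = b62_env)
  b62 <- b62_env$BLOSUM62
  for (i in 1:25) {
    a <- random_aa_string(sample(2:8, 1))
    b <- random_aa_string(sample(2:8, 1))
    ref_local <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = b62, gapOpening = 11, gapExtension = 1,
      type = "local", scoreOnly = TRUE
    )
    expect_equal(smith_waterman(a, b)$score, max(0, ref_local),
                 info = paste(a, b))
    ref_global <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = b62, gapOpening = 11, gapExtension = 1,
      type = "global", scoreOnly = TRUE
    )
    expect_equal(needleman_wunsch(a, b)$score, ref_global,
                 info = paste(a, b))
  }
})

test_that("alignment scores satisfy the structural invariants", {
  set.seed(43)
  for (i in 1:30) {
    a <- random_aa_string(sample(2:8, 1))
    b <- random_aa_string(sample(2:8, 1))
    sw_ab <- smith_waterman(a, b)$score
    nw_ab <- needleman_wunsch(a, b)$score
    # symmetry under a symmetric matrix
    expect_equal(sw_ab, smith_waterman(b, a)$score)
    expect_equal(nw_ab, needleman_wunsch(b, a)$score)
    # local dominates max(0, global)
    expect_gte(sw_ab, max(0, nw_ab))
  }
})

test_that("affine gaps: one length-2 gap never costs more than two length-1 gaps", {
  # direct check on the cost model plus a worked alignment: aligning
  # ACDEFG to ACFG must pay one gap of length 2 (cost 13), not two of 1
  aln <- needleman_wunsch("ACDEFG", "ACFG")
  expect_equal(aln$score, 4 + 9 + 6 + 6 - (11 + 2 * 1))
  gaps <- is.na(aln$pairs$b_idx)
  expect_equal(sum(gaps), 2)
  expect_equal(diff(which(gaps)), 1) # contiguous gap
})

test_that("deterministic traceback: repeated runs are identical", {
  set.seed(44)
  a <- random_aa_string(30)
  b <- random_aa_string(30)
  r1 <- smith_waterman(a, b)
  r2 <- smith_waterman(a, b)
  expect_identical(r1, r2)
})

test_that("aligned pairs are strictly increasing and inside bounds", {
  set.seed(45)
  for (i in 1:10) {
    a <- random_aa_string(sample(5:20, 1))
    b <- random_aa_string(sample(5:20, 1))
    for (r in list(smith_waterman(a, b), needleman_wunsch(a, b))) {
      ai <- r$pairs$a_idx[!is.na(r$pairs$a_idx)]
      bi <- r$pairs$b_idx[!is.na(r$pairs$b_idx)]
      expect_true(all(diff(ai) > 0))
      expect_true(all(diff(bi) > 0))
      expect_true(all(ai >= 0 & ai < nchar(a)))
      expect_true(all(bi >= 0 & bi < nchar(b)))
      if (r$mode == "local") expect_gte(r$score, 0)
    }
  }
})

test_that("unknown symbols are rejected by the aligner", {
  expect_error(smith_waterman("GKT", "GK1"), "alphabet")
  expect_error(needleman_wunsch("GKB", "GKT"), "alphabet")
})

test_that("X scores as the matrix minimum", {
  m <- blosum62()
  expect_equal(unname(unclass(m)["X", "X"]), -4)
  expect_equal(unname(unclass(m)["X", "G"]), -4)
  expect_true(all(unclass(m)["X", ] == min(unclass(m))))
})

test_that("profile alignment degenerates to sequence alignment", {
  s <- "GESGSGKST"
  msa <- theme_alignment("one", s)
  # a single-sequence profile scanned against its own sequence recovers a
  # full-width, all-diagonal local alignment
  prof <- build_profile(msa, pseudocount = 1)
  r <- profile_align_local(prof, s)
  expect_equal(r$a_interval, c(0L, nchar(s)))
  expect_equal(r$b_interval, c(0L, nchar(s)))
  expect_true(all(!is.na(r$pairs$a_idx) & !is.na(r$pairs$b_idx)))
})

test_that("profile alignment handles tiny and hopeless cases", {
  # width-3 profile vs length-1 string: the best single-column match wins
  scores <- matrix(-1, nrow = 3, ncol = 20,
                   dimnames = list(NULL, aa_alphabet()[1:20]))
  scores[2, "G"] <- 7
  r <- profile_align_local(scores, "G")
  expect_equal(r$score, 7)
  expect_equal(r$a_interval, c(1L, 2L)) # second profile column
  # all-negative score table -> empty alignment at score 0
  neg <- matrix(-5, nrow = 4, ncol = 20,
                dimnames = list(NULL, aa_alphabet()[1:20]))
  r0 <- profile_align_local(neg, "GKTA")
  expect_equal(r0$score, 0)
  expect_equal(nrow(r0$pairs), 0)
  # empty profile is an error
  expect_error(profile_align_local(neg[0, , drop = FALSE], "GKT"), "zero columns")
})
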