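test_that("superposing a set on itself is the identity", {
  pts <- generate_loop_coords(11)$base
  sup <- kabsch_superpose(pts, pts)
  expect_lt(sup$rmsd, 1e-9)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-9)
  expect_equal(sup$n_atoms, 11)
})

test_that("an exact rigid motion is recovered to numerical precision", {
  lc <- generate_loop_coords(11, noise_sigma = 0)
  sup <- kabsch_superpose(lc$base, lc$moved)
  expect_lt(sup$rmsd, 1e-9)
  expect_equal(sup$rotation, lc$rotation, tolerance = 1e-8)
  expect_equal(as.vector(sup$translation), lc$translation, tolerance = 1e-8)
  # proper rotation
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  expect_equal(t(sup$rotation) %*% sup$rotation, diag(3), tolerance = 1e-9)
})

test_that("superposition errors on mismatched, tiny, or collinear input", {
  pts <- generate_loop_coords(8)$base
  expect_error(kabsch_superpose(pts, pts[1:5, ]), "counts differ")
  expect_error(kabsch_superpose(pts[1:2, ], pts[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("RMSD is invariant under rigid pre-transformation", {
  lc <- generate_loop_coords(11, noise_sigma = 0.4, seed = 7)
  base_rmsd <- kabsch_superpose(lc$base, lc$moved)$rmsd
  R2 <- rotation_matrix(1.1, c(2, -1, 3))
  pre <- lc$base %*% t(R2) + matrix(c(-4, 8, 1), 11, 3, byrow = TRUE)
  expect_equal(kabsch_superpose(pre, lc$moved)$rmsd, base_rmsd,
               tolerance = 1e-9)
  # and the fit never does worse than leaving the points in place
  raw_rmsd <- sqrt(mean(rowSums((lc$base - lc$moved)^2)))
  expect_lte(base_rmsd, raw_rmsd + 1e-12)
})

test_that("noise-model RMSD matches the degrees-of-freedom expectation", {
  # one copy perturbed by isotropic per-axis noise sigma: the rigid fit
  # absorbs 6 of the 3n coordinate degrees of freedom, so
  # E[rmsd] ~ sigma * sqrt(3 - 6/n)
  n <- 11
  sigma <- 0.3
  rmsds <- vapply(1:100, function(s) {
    lc <- generate_loop_coords(n, noise_sigma = sigma, seed = s)
    kabsch_superpose(lc$base, lc$moved)$rmsd
  }, numeric(1))
  expected <- sigma * sqrt(3 - 6 / n)
  expect_lt(abs(mean(rmsds) - expected) / expected, 0.10)
})

test_that("loop extraction orders residues and reports missing atoms", {
  coords <- generate_loop_coords(11)$base
  path <- withr::local_tempfile(fileext = ".pdb")
  write_loop_pdb(path, coords, resno_start = 150)
  model <- read_structure(path)
  loop <- extract_loop(model, loop_selection("A", 150, 160))
  expect_equal(nrow(loop), 11)
  expect_equal(unname(loop[1, ]), unname(coords[1, ]), tolerance = 1e-3)
  # missing residue in range -> error naming it
  expect_error(extract_loop(model, loop_selection("A", 150, 161)), "161")
  # a sidechain atom absent from a glycine/CA-only trace -> error
  expect_error(extract_loop(model, loop_selection("A", 150, 160, atom = "CB")),
               "CB")
})

test_that("ligand transplant preserves internal geometry exactly", {
  lc <- generate_loop_coords(11, noise_sigma = 0)
  ligand <- matrix(c(1, 1, 4, 2, 0.5, 5, 0, 1.5, 6), ncol = 3, byrow = TRUE)
  donor_path <- withr::local_tempfile(fileext = ".pdb")
  acc_path <- withr::local_tempfile(fileext = ".pdb")
  write_loop_pdb(donor_path, lc$base, resno_start = 247, ligand = ligand)
  moved_ligand <- ligand %*% t(lc$rotation) +
    matrix(lc$translation, 3, 3, byrow = TRUE)
  write_loop_pdb(acc_path, lc$moved, resno_start = 150)
  donor <- read_structure(donor_path)
  acceptor <- read_structure(acc_path)
  out <- transplant_ligand(donor, acceptor,
                           loop_selection("A", 247, 257),
                           loop_selection("A", 150, 160), "GTP")
  sup <- attr(out, "superposition")
  expect_lt(sup$rmsd, 1e-3) # PDB coordinates carry 3 decimals
  placed <- as.matrix(dplyr::filter(out, is_het)[, c("x", "y", "z")])
  # the placed ligand reproduces the donor pose in the acceptor frame
  expect_equal(placed, moved_ligand, tolerance = 5e-3,
               ignore_attr = TRUE)
  # rigid map: ligand-loop distances preserved
  loop_now <- extract_loop(out, loop_selection("A", 150, 160))
  d_before <- as.vector(outer(seq_len(3), seq_len(11), function(i, j) {
    sqrt(rowSums((ligand[i, , drop = FALSE] - lc$base[j, , drop = FALSE])^2))
  }))
  d_after <- as.vector(outer(seq_len(3), seq_len(11), function(i, j) {
    sqrt(rowSums((placed[i, , drop = FALSE] - loop_now[j, , drop = FALSE])^2))
  }))
  expect_equal(d_after, d_before, tolerance = 1e-2)
})

test_that("transplant onto the donor itself leaves the ligand in place", {
  lc <- generate_loop_coords(11)
  ligand <- matrix(c(0, 0, 3, 1, 1, 5), ncol = 3, byrow = TRUE)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_loop_pdb(path, lc$base, resno_start = 247, ligand = ligand)
  model <- read_structure(path)
  out <- transplant_ligand(model, model,
                           loop_selection("A", 247, 257),
                           loop_selection("A", 247, 257), "GTP")
  # the original ligand sits at residue 900; the transplanted copy is
  # renumbered past it
  placed <- as.matrix(dplyr::filter(out, is_het,
                                    resno > 900)[, c("x", "y", "z")])
  expect_equal(placed, ligand, tolerance = 1e-3, ignore_attr = TRUE)
  expect_error(
    transplant_ligand(model, model, loop_selection("A", 247, 257),
                      loop_selection("A", 247, 257), "ATP"),
    "no HETATM"
  )
})

test_that("transplanted output writes a valid PDB with a provenance remark", {
  lc <- generate_loop_coords(11)
  ligand <- matrix(c(0, 0, 3, 1, 1, 5, 2, 2, 7), ncol = 3, byrow = TRUE)
  donor_path <- withr::local_tempfile(fileext = ".pdb")
  acc_path <- withr::local_tempfile(fileext = ".pdb")
  write_loop_pdb(donor_path, lc$base, resno_start = 247, ligand = ligand)
  write_loop_pdb(acc_path, lc$moved, resno_start = 150)
  out_path <- withr::local_tempfile(fileext = ".pdb")
  res <- run_overlay(donor_path, acc_path, ligand_resname = "GTP",
                     out_path = out_path, verbose = FALSE)
  expect_lt(res$superposition$rmsd, 1e-3)
  lines <- readLines(out_path)
  expect_true(any(grepl("^REMARK.*RMSD", lines)))
  reread <- read_structure(out_path)
  expect_equal(sum(reread$is_het), 3)
  expect_equal(sum(!reread$is_het), 11)
})
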