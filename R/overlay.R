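#' Select a loop from a structure
#'
#' A loop selection names a chain, an inclusive author-numbered residue
#' range, and the atom to trace (default the Cα, `"CA"`).
#'
#' @param chain Chain identifier.
#' @param from,to Inclusive residue-number range (`from <= to`).
#' @param atom Atom name (default `"CA"`).
#' @return A `loop_selection` list.
#' @export
loop_selection <- function(chain, from, to, atom = "CA") {
  if (from > to) abort("`from` must not exceed `to`")
  structure(list(chain = chain, from = as.integer(from), to = as.integer(to),
                 atom = atom),
            class = "loop_selection")
}

#' Extract ordered loop coordinates
#'
#' Returns one coordinate per residue in the selection, ordered by residue
#' number (insertion-code variants after their base number). Every residue
#' in the range must carry the named atom; missing ones are an error that
#' names them.
#'
#' @param model A `structure_model` ([read_structure()]).
#' @param sel A [loop_selection()].
#' @return An n x 3 numeric matrix of coordinates (Angstrom).
#' @export
extract_loop <- function(model, sel) {
  at <- dplyr::filter(model, !.data$is_het, .data$chain == sel$chain,
                      .data$resno >= sel$from, .data$resno <= sel$to,
                      .data$atom == sel$atom)
  at <- dplyr::arrange(at, .data$resno, .data$insert)
  present <- unique(at$resno)
  missing <- setdiff(seq(sel$from, sel$to), present)
  if (length(missing) > 0) {
    abort(sprintf("atom '%s' missing for chain %s residue(s): %s",
                  sel$atom, sel$chain, paste(missing, collapse = ", ")))
  }
  as.matrix(at[, c("x", "y", "z")])
}

#' Kabsch superposition of two matched point sets
#'
#' Computes the least-squares optimal proper rotation and translation
#' mapping `mobile` onto `fixed` (reflections rejected by a determinant
#' sign flip) and the post-transform RMSD. The two sets must have equal
#' counts (>= 3) and must not be collinear.
#'
#' @param mobile,fixed n x 3 coordinate matrices with matching row order.
#' @return A `loop_superposition`: list with `rotation` (3 x 3, determinant
#'   +1), `translation` (length-3), `rmsd` (Angstrom), `n_atoms`. The
#'   transform maps a mobile-frame point `p` to `rotation %*% p +
#'   translation`.
#' @export
kabsch_superpose <- function(mobile, fixed) {
  mobile <- as.matrix(mobile)
  fixed <- as.matrix(fixed)
  if (nrow(mobile) != nrow(fixed)) {
    abort(sprintf("point counts differ: %d vs %d", nrow(mobile), nrow(fixed)))
  }
  n <- nrow(mobile)
  if (n < 3) abort("superposition needs at least 3 points")
  cm <- colMeans(mobile)
  cf <- colMeans(fixed)
  A <- sweep(mobile, 2, cm)
  B <- sweep(fixed, 2, cf)
  for (M in list(A, B)) {
    if (svd(M, nu = 0, nv = 0)$d[2] < 1e-8) {
      abort("degenerate (collinear) point set; superposition is ill-defined")
    }
  }
  H <- t(A) %*% B # cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- cf - as.vector(R %*% cm)
  moved <- mobile %*% t(R) + matrix(t_vec, n, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - fixed)^2)))
  structure(
    list(rotation = R, translation = t_vec, rmsd = rmsd, n_atoms = n),
    class = "loop_superposition"
  )
}

#' @rdname kabsch_superpose
#' @param coords An n x 3 matrix to transform.
#' @param sup A `loop_superposition`.
#' @export
apply_superposition <- function(coords, sup) {
  coords <- as.matrix(coords)
  coords %*% t(sup$rotation) +
    matrix(sup$translation, nrow(coords), 3, byrow = TRUE)
}

#' @export
print.loop_superposition <- function(x, ...) {
  cat(sprintf("<loop_superposition> %d atoms, RMSD %.4f A\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}

#' @export
tidy.loop_superposition <- function(x, ...) {
  tibble::tibble(
    term = c("rmsd", "n_atoms", sprintf("t%s", c("x", "y", "z"))),
    value = c(x$rmsd, x$n_atoms, x$translation)
  )
}

#' @export
glance.loop_superposition <- function(x, ...) {
  tibble::tibble(rmsd = x$rmsd, n_atoms = x$n_atoms,
                 det_rotation = det(x$rotation))
}

#' Transplant a ligand by loop superposition
#'
#' Superposes the donor loop onto the acceptor loop (residue i to residue
#' i: the two selections must span equally many residues), applies the
#' resulting rigid map to every HETATM of the named ligand residue in the
#' donor, and returns the acceptor model with the transformed ligand
#' appended (renumbered past the acceptor's last residue, placed on the
#' acceptor selection's chain). The superposition RMSD is attached as the
#' `superposition` attribute and recorded in the REMARK header when the
#' model is written.
#'
#' @param donor,acceptor `structure_model` tibbles.
#' @param donor_sel,acceptor_sel [loop_selection()]s of equal length.
#' @param ligand_resname 3-letter HETATM residue name to transplant.
#' @return A `structure_model` of the acceptor plus the placed ligand, with
#'   attribute `superposition` (the `loop_superposition`).
#' @export
transplant_ligand <- function(donor, acceptor, donor_sel, acceptor_sel,
                              ligand_resname) {
  lig <- dplyr::filter(donor, .data$is_het, .data$resid == ligand_resname)
  if (nrow(lig) == 0) {
    abort(sprintf("no HETATM residue named '%s' in the donor", ligand_resname))
  }
  sup <- kabsch_superpose(extract_loop(donor, donor_sel),
                          extract_loop(acceptor, acceptor_sel))
  new_xyz <- apply_superposition(as.matrix(lig[, c("x", "y", "z")]), sup)
  lig$x <- new_xyz[, 1]
  lig$y <- new_xyz[, 2]
  lig$z <- new_xyz[, 3]
  # renumber transplanted residues past the acceptor's numbering
  base <- max(acceptor$resno)
  lig$resno <- base + as.integer(factor(paste(lig$chain, lig$resno, lig$insert),
                                        levels = unique(paste(lig$chain, lig$resno, lig$insert))))
  lig$insert <- ""
  lig$chain <- acceptor_sel$chain
  out <- dplyr::bind_rows(acceptor, lig)
  class(out) <- c("structure_model", class(tibble::tibble()))
  attr(out, "superposition") <- sup
  out
}

#' Write a transplant result with provenance REMARKs
#'
#' @param model A [transplant_ligand()] result.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_transplant <- function(model, path) {
  sup <- attr(model, "superposition")
  remarks <- if (!is.null(sup)) {
    sprintf("LOOP SUPERPOSITION RMSD %.4f A OVER %d ATOMS", sup$rmsd, sup$n_atoms)
  }
  write_structure(model, path, remarks = remarks)
}
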