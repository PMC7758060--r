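#' Read a PDB-format structure into an atom tibble
#'
#' Parses ATOM/HETATM records (via bio3d), keeping only the first MODEL and
#' resolving alternate locations to blank-or-'A'. Insertion codes are
#' honored; occupancy and B-factor are ignored. Residue numbering is the
#' file's author numbering, verbatim.
#'
#' @param path Path to a PDB file.
#' @return A `structure_model`: a tibble with columns `chain`, `resno`,
#'   `insert`, `resid` (3-letter residue name), `atom` (atom name),
#'   `element`, `x`, `y`, `z` (Angstrom), `is_het`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) abort("no ATOM/HETATM records found")
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
    abort("non-finite atom coordinates")
  }
  out <- tibble::tibble(
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid,
    atom = at$elety,
    element = ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                     substr(gsub("[0-9]", "", at$elety), 1, 1),
                     trimws(at$elesy)),
    x = at$x, y = at$y, z = at$z,
    is_het = at$type == "HETATM"
  )
  class(out) <- c("structure_model", class(out))
  out
}

#' Write an atom tibble to PDB format
#'
#' Atom records are written in row order; optional REMARK lines are placed
#' at the top of the file.
#'
#' @param model A `structure_model` tibble.
#' @param path Output path.
#' @param remarks Optional character vector of REMARK payload lines.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, remarks = NULL) {
  bio3d::write.pdb(
    file = path,
    type = ifelse(model$is_het, "HETATM", "ATOM"),
    xyz = as.vector(t(as.matrix(model[, c("x", "y", "z")]))),
    resno = model$resno,
    resid = model$resid,
    chain = model$chain,
    insert = ifelse(nzchar(model$insert), model$insert, ""),
    elety = model$atom,
    elesy = model$element,
    eleno = seq_len(nrow(model))
  )
  if (!is.null(remarks)) {
    body <- readLines(path)
    writeLines(c(sprintf("REMARK   3 %s", remarks), body), path)
  }
  invisible(path)
}
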