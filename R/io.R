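#' Read a labeled domain database from FASTA
#'
#' Headers follow the dialect `>id|lineage|fgroup` (e.g.
#' `>e1ko7A1|2004|2004.1.2.1`): the lineage label plays the role of an ECOD
#' X-group and the fgroup label that of an F-group. Sequences are upper-cased
#' and `*` terminators stripped; any symbol outside the 21-letter alphabet,
#' a malformed header, or a duplicated id is an error.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `lineage`, `fgroup`, `sequence`, one
#'   row per entry in file order.
#' @export
read_domain_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  header_ln <- grep("^>", lines)
  if (length(header_ln) == 0) {
    return(tibble::tibble(id = character(), lineage = character(),
                          fgroup = character(), sequence = character()))
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  fields <- strsplit(headers, "|", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) != 3L)
  if (length(bad) > 0) {
    abort(sprintf("malformed header at line %d: '>%s' (expected >id|lineage|fgroup)",
                  header_ln[bad[1]], headers[bad[1]]))
  }
  ids <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate domain id: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(gsub("*", "", as.character(set), fixed = TRUE))
  if (any(!nzchar(ids)) || any(!nzchar(seqs))) {
    abort("every entry needs a non-empty id and sequence")
  }
  for (i in seq_along(seqs)) encode_seq(seqs[[i]], paste0("sequence '", ids[i], "'"))
  tibble::tibble(
    id = unname(ids),
    lineage = vapply(fields, `[[`, "", 2),
    fgroup = vapply(fields, `[[`, "", 3),
    sequence = unname(seqs)
  )
}

#' Write a domain database to FASTA
#'
#' Inverse of [read_domain_fasta()]; one unwrapped sequence line per record.
#'
#' @param domains A tibble with `id`, `lineage`, `fgroup`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_fasta <- function(domains, path) {
  writeLines(
    as.vector(rbind(
      sprintf(">%s|%s|%s", domains$id, domains$lineage, domains$fgroup),
      domains$sequence
    )),
    path
  )
  invisible(path)
}

#' Theme alignments
#'
#' A theme is carried around as an ungapped-core multiple sequence alignment:
#' equal-length gapped rows plus the ids they came from.
#' `theme_alignment()` validates and constructs one; `read_theme_msa()` reads
#' one from aligned FASTA, dropping all-gap columns with a warning.
#'
#' @param theme_id Theme identifier.
#' @param rows Character vector of equal-length gapped residue strings.
#' @param source_ids Ids of the aligned sequences (defaults to row names or
#'   `row<i>`).
#' @return A `theme_alignment` object (list with `theme_id`, `rows`,
#'   `source_ids`, `width`).
#' @export
theme_alignment <- function(theme_id, rows, source_ids = NULL) {
  if (length(rows) < 1) abort("a theme alignment needs at least one row")
  widths <- nchar(rows)
  if (length(unique(widths)) != 1) {
    abort("ragged theme alignment: rows have unequal lengths")
  }
  if (widths[1] < 1) abort("theme alignment rows must be non-empty")
  if (is.null(source_ids)) {
    source_ids <- names(rows) %||% paste0("row", seq_along(rows))
  }
  mat <- do.call(rbind, strsplit(toupper(rows), ""))
  resid <- setdiff(unique(as.vector(mat)), "-")
  if (!all(resid %in% AA_ALPHABET21)) {
    abort(sprintf("theme alignment contains symbols outside the alphabet: %s",
                  paste(setdiff(resid, AA_ALPHABET21), collapse = ", ")))
  }
  all_gap <- apply(mat == "-", 2, all)
  if (any(all_gap)) {
    warn(sprintf("dropping %d all-gap column(s) from theme '%s'",
                 sum(all_gap), theme_id))
    mat <- mat[, !all_gap, drop = FALSE]
    if (ncol(mat) == 0) abort("theme alignment has no non-gap columns")
    rows <- apply(mat, 1, paste, collapse = "")
  }
  structure(
    list(theme_id = theme_id, rows = unname(rows),
         source_ids = unname(source_ids), width = nchar(rows[[1]])),
    class = "theme_alignment"
  )
}

#' @rdname theme_alignment
#' @param path Path to an aligned FASTA file.
#' @export
read_theme_msa <- function(path, theme_id = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort("theme alignment file has zero rows")
  if (is.null(theme_id)) {
    theme_id <- sub("\\.[^.]*$", "", basename(path))
  }
  theme_alignment(theme_id, as.character(set), source_ids = names(set))
}

#' @export
print.theme_alignment <- function(x, ...) {
  cat(sprintf("<theme_alignment> '%s': %d rows x %d columns\n",
              x$theme_id, length(x$rows), x$width))
  invisible(x)
}

#' Write and read theme-hit tables
#'
#' Hits are stored internally with 0-based half-open intervals; the TSV is
#' human-facing and prints 1-based inclusive `start`/`end`. `read_hits_table`
#' converts back, so a round trip is the identity.
#'
#' @param hits A hits tibble as produced by [scan_database()].
#' @param path Output (or input) TSV path.
#' @return `write_hits_table()` returns `path` invisibly; `read_hits_table()`
#'   the hits tibble.
#' @export
write_hits_table <- function(hits, path) {
  out <- tibble::tibble(
    theme_id = hits$theme_id,
    domain_id = hits$domain_id,
    lineage = hits$lineage,
    fgroup = hits$fgroup,
    start = hits$start + 1L,
    end = hits$end,
    score = hits$score,
    evalue = hits$evalue,
    coverage = hits$coverage,
    aln_length = hits$aln_length
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_hits_table
#' @export
read_hits_table <- function(path) {
  cols <- readr::cols(
    theme_id = readr::col_character(),
    domain_id = readr::col_character(),
    lineage = readr::col_character(),
    fgroup = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    score = readr::col_double(),
    evalue = readr::col_double(),
    coverage = readr::col_double(),
    aln_length = readr::col_integer()
  )
  hits <- readr::read_tsv(path, col_types = cols, progress = FALSE)
  dplyr::mutate(hits, start = .data$start - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
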