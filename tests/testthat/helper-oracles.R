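# Independent alignment oracles, written against the scoring definition
# (gap of length L costs open + L * extend) rather than against the
# package's DP. Two routes:
#  * oracle_align_score(): top-down recursion over suffixes with caching.
#  * enumerate_align_score(): pure enumeration of every monotone alignment
#    (no caching); only feasible for very short strings.

oracle_sub_score <- function(m, x, y) unclass(m)[x, y]

# best score of aligning a[i..] with b[j..], given the previous column type
# ("M", "X" = gap in b, "Y" = gap in a); global mode must consume both tails
oracle_align_score <- function(a, b, m = blosum62(), open = 11, extend = 1,
                               local = FALSE) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); mm <- length(cb)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, prev) {
    if (i > n && j > mm) return(0)
    key <- paste(i, j, prev)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    if (i <= n && j <= mm) {
      best <- max(best, oracle_sub_score(m, ca[i], cb[j]) + rec(i + 1, j + 1, "M"))
    }
    if (i <= n) {
      best <- max(best, -extend - (if (prev == "X") 0 else open) + rec(i + 1, j, "X"))
    }
    if (j <= mm) {
      best <- max(best, -extend - (if (prev == "Y") 0 else open) + rec(i, j + 1, "Y"))
    }
    memo[[key]] <- best
    best
  }
  if (!local) return(rec(1, 1, "M"))
  # local: best path that starts and ends with an aligned pair, or empty
  lmemo <- new.env(parent = emptyenv())
  lrec <- function(i, j, prev) {
    # best (possibly ended) local continuation from (i, j) given prev state
    key <- paste(i, j, prev)
    hit <- lmemo[[key]]
    if (!is.null(hit)) return(hit)
    best <- 0 # stop here
    if (i <= n && j <= mm) {
      best <- max(best, oracle_sub_score(m, ca[i], cb[j]) + lrec(i + 1, j + 1, "M"))
    }
    if (i <= n && prev != "stoponly") {
      best <- max(best, -extend - (if (prev == "X") 0 else open) + lrec(i + 1, j, "X"))
    }
    if (j <= mm) {
      best <- max(best, -extend - (if (prev == "Y") 0 else open) + lrec(i, j + 1, "Y"))
    }
    lmemo[[key]] <- best
    best
  }
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(mm)) {
      best <- max(best, oracle_sub_score(m, ca[i], cb[j]) + lrec(i + 1, j + 1, "M"))
    }
  }
  best
}

# pure enumeration, no caching: every monotone alignment is generated
enumerate_align_score <- function(a, b, m = blosum62(), open = 11, extend = 1,
                                  local = FALSE) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); mm <- length(cb)
  best <- if (local) 0 else -Inf
  walk <- function(i, j, prev, acc) {
    if (local && prev == "M") best <<- max(best, acc)
    if (i > n && j > mm) {
      if (!local) best <<- max(best, acc)
      return(invisible())
    }
    if (i <= n && j <= mm) {
      walk(i + 1, j + 1, "M", acc + oracle_sub_score(m, ca[i], cb[j]))
    }
    if (i <= n) {
      walk(i + 1, j, "X", acc - extend - (if (prev == "X") 0 else open))
    }
    if (j <= mm) {
      walk(i, j + 1, "Y", acc - extend - (if (prev == "Y") 0 else open))
    }
  }
  if (!local) {
    walk(1, 1, "M", 0)
  } else {
    for (i in seq_len(n)) {
      for (j in seq_len(mm)) {
        walk(i + 1, j + 1, "M", oracle_sub_score(m, ca[i], cb[j]))
      }
    }
  }
  best
}

random_aa_string <- function(n) {
  paste(sample(aa_alphabet()[1:20], n, replace = TRUE), collapse = "")
}

# minimal PDB writer for parser fixtures
pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          alt = " ", het = FALSE, elem = NULL, icode = " ") {
  rec <- if (het) "HETATM" else "ATOM  "
  if (is.null(elem)) elem <- substr(gsub("[0-9]", "", name), 1, 1)
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%s%5d %4s%s%-3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, nm, alt, resn, chain, resno, icode, x, y, z, 1, 20, elem)
}

# a poly-ALA helix trace as PDB CA lines, plus an optional fake ligand
write_loop_pdb <- function(path, coords, chain = "A", resno_start = 1,
                           resn = "ALA", ligand = NULL, ligand_name = "GTP") {
  lines <- character(0)
  for (i in seq_len(nrow(coords))) {
    lines <- c(lines, pdb_atom_line(i, "CA", resn, chain,
                                    resno_start + i - 1,
                                    coords[i, 1], coords[i, 2], coords[i, 3]))
  }
  if (!is.null(ligand)) {
    for (k in seq_len(nrow(ligand))) {
      lines <- c(lines, pdb_atom_line(1000 + k, paste0("P", k), ligand_name,
                                      chain, 900, ligand[k, 1], ligand[k, 2],
                                      ligand[k, 3], het = TRUE, elem = "P"))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}
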