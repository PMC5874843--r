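# XYZ and PDB structure readers/writers.
#
# XYZ: atom count line, comment line, then "element x y z" records; written
# at 1e-6 A precision. PDB: fixed-column ATOM/HETATM records at 1e-3 A; the
# chain ID column carries the polymer-chain index for built systems. Both
# parsers report the offending line number on malformed input.

#' Read a molecular structure file
#'
#' @param path File path.
#' @param format `"xyz"` or `"pdb"`; inferred from the extension when missing.
#' @return A [molecule()].
#' @export
read_structure <- function(path, format = c("auto", "xyz", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     xyz = "xyz", pdb = "pdb",
                     stop_gf(sprintf("cannot infer format of '%s'", path),
                             "gelforge_io_error"))
  }
  if (!file.exists(path)) {
    stop_gf(sprintf("file not found: %s", path), "gelforge_file_error")
  }
  switch(format, xyz = read_xyz(path), pdb = read_pdb(path))
}

#' Write a molecular structure file
#'
#' @param mol A [molecule()].
#' @param path Output path.
#' @param format `"xyz"` or `"pdb"`; inferred from the extension when missing.
#' @param chain_index Optional integer per atom mapped to the PDB chain ID
#'   column (ignored for XYZ).
#' @return `path`, invisibly.
#' @export
write_structure <- function(mol, path, format = c("auto", "xyz", "pdb"),
                            chain_index = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     xyz = "xyz", pdb = "pdb",
                     stop_gf(sprintf("cannot infer format of '%s'", path),
                             "gelforge_io_error"))
  }
  switch(format,
         xyz = write_xyz(mol, path),
         pdb = write_pdb(mol, path, chain_index = chain_index))
  invisible(path)
}

read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop_gf("XYZ file too short", "gelforge_parse_error")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop_gf("line 1: expected an atom count", "gelforge_parse_error")
  if (length(lines) < n + 2L) {
    stop_gf(sprintf("expected %d atom records, found %d", n, length(lines) - 2L),
            "gelforge_parse_error")
  }
  element <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- i + 2L
    fields <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    if (length(fields) < 4L) {
      stop_gf(sprintf("line %d: expected 'element x y z'", ln), "gelforge_parse_error")
    }
    xyz <- suppressWarnings(as.numeric(fields[2:4]))
    if (anyNA(xyz)) {
      stop_gf(sprintf("line %d: malformed coordinate", ln), "gelforge_parse_error")
    }
    element[i] <- fields[1]
    coords[i, ] <- xyz
  }
  molecule(element, coords, name = trimws(lines[2]))
}

write_xyz <- function(mol, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(n_atoms(mol)), mol$name), con)
  writeLines(sprintf("%-2s %14.6f %14.6f %14.6f", mol$element,
                     mol$coords[, 1], mol$coords[, 2], mol$coords[, 3]), con)
  invisible(path)
}

# Multi-model XYZ concatenation (one block per frame).
write_xyz_frames <- function(mols, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    writeLines(c(as.character(n_atoms(mol)), mol$name), con)
    writeLines(sprintf("%-2s %14.6f %14.6f %14.6f", mol$element,
                       mol$coords[, 1], mol$coords[, 2], mol$coords[, 3]), con)
  }
  invisible(path)
}

read_xyz_frames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop_gf(sprintf("line %d: expected an atom count", i), "gelforge_parse_error")
    block <- lines[i:min(i + n + 1L, length(lines))]
    tmp <- tempfile(fileext = ".xyz")
    writeLines(block, tmp)
    frames[[length(frames) + 1L]] <- read_xyz(tmp)
    unlink(tmp)
    i <- i + n + 2L
  }
  frames
}

pdb_chain_ids <- c(LETTERS, letters, as.character(0:9))

read_pdb <- function(path) {
  lines <- readLines(path)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(rec)
  if (!length(idx)) stop_gf("no ATOM/HETATM records found", "gelforge_parse_error")
  n <- length(idx)
  element <- character(n)
  coords <- matrix(NA_real_, n, 3)
  role <- character(n)
  for (k in seq_len(n)) {
    ln <- idx[k]
    line <- lines[ln]
    if (nchar(line) < 54L) {
      stop_gf(sprintf("line %d: truncated ATOM/HETATM record", ln), "gelforge_parse_error")
    }
    xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                         substr(line, 39, 46),
                                         substr(line, 47, 54))))
    if (anyNA(xyz)) {
      stop_gf(sprintf("line %d: malformed coordinate field", ln), "gelforge_parse_error")
    }
    el <- trimws(substr(line, 77, 78))
    if (!nzchar(el)) {
      # fall back on the atom-name column, stripping digits
      el <- gsub("[0-9']", "", trimws(substr(line, 13, 16)))
      el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2)))
      el <- sub(" $", "", el)
    }
    element[k] <- el
    coords[k, ] <- xyz
    role[k] <- trimws(substr(line, 18, 20))
  }
  molecule(element, coords, role = role, name = basename(path))
}

write_pdb <- function(mol, path, chain_index = NULL) {
  n <- n_atoms(mol)
  if (is.null(chain_index)) chain_index <- rep(1L, n)
  chain <- pdb_chain_ids[(chain_index - 1L) %% length(pdb_chain_ids) + 1L]
  resname <- substr(ifelse(nzchar(mol$role), toupper(mol$role), "MOL"), 1, 3)
  serial <- ((seq_len(n) - 1L) %% 99999L) + 1L
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    serial, substr(mol$element, 1, 2), resname, chain,
    ((chain_index - 1L) %% 9999L) + 1L,
    mol$coords[, 1], mol$coords[, 2], mol$coords[, 3], 1, 0, mol$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
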