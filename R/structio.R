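# Structure input and the `structure3d` container.
#
# A structure3d is a light wrapper around an atom table:
#   serial, name, resname, chain, resno (integer author numbering),
#   ins (insertion code, "" if none), resid ("<resno><ins>" as a string),
#   element, x, y, z, vdw, atom_type (NA until assign_atom_types()).
# PDB text is parsed through bio3d; validation, altLoc resolution and
# element/van der Waals assignment happen here.

new_structure3d <- function(atoms, metadata = list()) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  atoms$resid <- paste0(atoms$resno, atoms$ins)
  structure(list(atoms = atoms, metadata = metadata), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("structure3d: %d atoms, %d residues, chains: %s\n",
              nrow(a),
              nrow(unique(a[, c("chain", "resid")])),
              paste(unique(a$chain), collapse = ", ")))
  invisible(x)
}

atom_xyz <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

residue_table <- function(s) {
  unique(s$atoms[, c("chain", "resid", "resno", "ins", "resname")])
}

# Validate ATOM/HETATM records before handing the file to bio3d, so a
# malformed record is reported with its line number.
validate_pdb_lines <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(rec)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("malformed PDB record at line %d: too short", i))
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(coords)))))
      stop(sprintf("malformed PDB record at line %d: non-numeric coordinates", i))
  }
  invisible(TRUE)
}

guess_element <- function(name, elesy) {
  el <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  bad <- el == ""
  if (any(bad)) {
    nm <- toupper(gsub("^[0-9']+", "", name[bad]))
    first1 <- substr(nm, 1L, 1L)
    first2 <- substr(nm, 1L, 2L)
    el[bad] <- ifelse(first2 == "SE", "SE", first1)
  }
  el
}

#' Read a protein structure from PDB text
#'
#' Heavy atoms are retained; hydrogens are dropped; alternate locations are
#' resolved to the highest-occupancy copy (ties to the alphabetically first
#' altLoc). Waters are dropped unless \code{keep_waters}.
#'
#' @param pdb_text character scalar or vector of PDB lines, or a file path.
#' @param model_index 1-based model number for multi-model files.
#' @param keep_waters keep water (HOH/WAT) oxygens.
#' @param radii named vdW radius table, see \code{\link{bondi_radii}}.
#' @return A \code{structure3d}.
#' @export
read_structure <- function(pdb_text, model_index = 1L, keep_waters = FALSE,
                           radii = bondi_radii()) {
  if (length(pdb_text) == 1L && !grepl("\n", pdb_text) && file.exists(pdb_text)) {
    lines <- readLines(pdb_text, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(pdb_text, collapse = "\n"), "\n", fixed = TRUE))
  }
  validate_pdb_lines(lines)
  n_models <- max(1L, sum(grepl("^MODEL ", lines)))
  if (model_index < 1L || model_index > n_models)
    stop(sprintf("model_index %d out of range: file has %d model(s)",
                 model_index, n_models))
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, multi = n_models > 1L, verbose = FALSE)
  at <- pdb$atom
  if (n_models > 1L) {
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)
    at$x <- xyz[, 1L]; at$y <- xyz[, 2L]; at$z <- xyz[, 3L]
  }
  at$element <- guess_element(at$elety, at$elesy)
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  is_water <- at$resid %in% c("HOH", "WAT", "DOD")
  if (!keep_waters) at <- at[!is_water, , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms retained from PDB input")
  # altLoc: keep highest occupancy per (chain, resno, ins, atom name)
  at$alt[is.na(at$alt) | at$alt == ""] <- ""
  if (any(at$alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(key, -occ, at$alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety, sep = "|")), , drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }
  ins <- at$insert
  ins[is.na(ins)] <- ""
  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    resname = toupper(at$resid),
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    ins = ins,
    element = at$element,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE)
  atoms$vdw <- vdw_radius_for(atoms$element, radii)
  atoms$atom_type <- NA_character_
  new_structure3d(atoms, metadata = list(source = "pdb", n_models = n_models,
                                         model_index = model_index))
}

#' Subset a structure by chain
#'
#' @param s a \code{structure3d}.
#' @param chains character vector of chain ids to keep.
#' @return A \code{structure3d} with only the selected chains.
#' @export
subset_chains <- function(s, chains) {
  keep <- s$atoms$chain %in% chains
  if (!any(keep)) stop("no atoms in the requested chains")
  new_structure3d(s$atoms[keep, , drop = FALSE], s$metadata)
}

subset_atoms <- function(s, keep) {
  new_structure3d(s$atoms[keep, , drop = FALSE], s$metadata)
}

#' Write a structure as PDB text
#'
#' Minimal ATOM-record writer used to export fixtures and rotamer
#' placements for inspection.
#'
#' @param s a \code{structure3d}.
#' @param path optional output file; if NULL the lines are returned.
#' @return Character vector of PDB lines (invisibly when written to file).
#' @export
write_structure_pdb <- function(s, path = NULL) {
  a <- s$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial %% 100000L,
    ifelse(nchar(a$name) >= 4L, a$name, paste0(" ", a$name)),
    " ", a$resname, a$chain, a$resno %% 10000L,
    ifelse(a$ins == "", " ", a$ins),
    a$x, a$y, a$z, 1, 0, a$element)
  lines <- c(lines, "END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
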