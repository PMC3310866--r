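# Rotamer-library sidechain placement on an alanine-reduced scaffold,
# steric clash filtering, and amino-acid conformation classification.
#
# Sidechains are built with ideal internal geometry (NeRF placement from
# per-residue internal-coordinate tables) directly from library chi angles
# on the fixed backbone; no local minimization is applied. The clash
# criterion is vdW overlap: two non-bonded heavy atoms clash when their
# distance is below (r1 + r2 - tolerance).

N_CHI <- c(ALA = 0L, GLY = 0L, SER = 1L, CYS = 1L, THR = 1L, VAL = 1L,
           LEU = 2L, ILE = 2L, ASP = 2L, ASN = 2L, HIS = 2L, PHE = 2L,
           TYR = 2L, TRP = 2L, PRO = 2L, MET = 3L, GLU = 3L, GLN = 3L,
           LYS = 4L, ARG = 4L)

# Internal-coordinate sidechain topologies. Each row places one atom from
# three predecessors: torsion = chi[chi_idx] + offset when chi_idx > 0,
# otherwise the fixed offset (ring/terminal-group geometry).
sidechain_topology <- function(restype) {
  row <- function(atom, p1, p2, p3, len, ang, chi, off)
    data.frame(atom = atom, p1 = p1, p2 = p2, p3 = p3, len = len, ang = ang,
               chi = chi, off = off, stringsAsFactors = FALSE)
  switch(restype,
    ALA = NULL, GLY = NULL,
    SER = row("OG", "N", "CA", "CB", 1.43, 110.5, 1L, 0),
    CYS = row("SG", "N", "CA", "CB", 1.81, 114.0, 1L, 0),
    THR = rbind(row("OG1", "N", "CA", "CB", 1.43, 109.5, 1L, 0),
                row("CG2", "N", "CA", "CB", 1.52, 110.5, 1L, -120)),
    VAL = rbind(row("CG1", "N", "CA", "CB", 1.52, 110.5, 1L, 0),
                row("CG2", "N", "CA", "CB", 1.52, 110.5, 1L, 120)),
    LEU = rbind(row("CG", "N", "CA", "CB", 1.52, 116.0, 1L, 0),
                row("CD1", "CA", "CB", "CG", 1.52, 110.5, 2L, 0),
                row("CD2", "CA", "CB", "CG", 1.52, 110.5, 2L, 120)),
    ILE = rbind(row("CG1", "N", "CA", "CB", 1.52, 110.5, 1L, 0),
                row("CG2", "N", "CA", "CB", 1.52, 110.5, 1L, -120),
                row("CD1", "CA", "CB", "CG1", 1.52, 113.0, 2L, 0)),
    MET = rbind(row("CG", "N", "CA", "CB", 1.52, 114.0, 1L, 0),
                row("SD", "CA", "CB", "CG", 1.81, 112.0, 2L, 0),
                row("CE", "CB", "CG", "SD", 1.79, 100.0, 3L, 0)),
    ASP = rbind(row("CG", "N", "CA", "CB", 1.52, 112.6, 1L, 0),
                row("OD1", "CA", "CB", "CG", 1.25, 118.5, 2L, 0),
                row("OD2", "CA", "CB", "CG", 1.25, 118.5, 2L, 180)),
    ASN = rbind(row("CG", "N", "CA", "CB", 1.52, 112.6, 1L, 0),
                row("OD1", "CA", "CB", "CG", 1.23, 120.8, 2L, 0),
                row("ND2", "CA", "CB", "CG", 1.33, 116.4, 2L, 180)),
    GLU = rbind(row("CG", "N", "CA", "CB", 1.52, 114.0, 1L, 0),
                row("CD", "CA", "CB", "CG", 1.52, 112.6, 2L, 0),
                row("OE1", "CB", "CG", "CD", 1.25, 118.5, 3L, 0),
                row("OE2", "CB", "CG", "CD", 1.25, 118.5, 3L, 180)),
    GLN = rbind(row("CG", "N", "CA", "CB", 1.52, 114.0, 1L, 0),
                row("CD", "CA", "CB", "CG", 1.52, 112.6, 2L, 0),
                row("OE1", "CB", "CG", "CD", 1.23, 120.8, 3L, 0),
                row("NE2", "CB", "CG", "CD", 1.33, 116.4, 3L, 180)),
    LYS = rbind(row("CG", "N", "CA", "CB", 1.52, 114.0, 1L, 0),
                row("CD", "CA", "CB", "CG", 1.52, 111.3, 2L, 0),
                row("CE", "CB", "CG", "CD", 1.52, 111.3, 3L, 0),
                row("NZ", "CG", "CD", "CE", 1.47, 110.5, 4L, 0)),
    ARG = rbind(row("CG", "N", "CA", "CB", 1.52, 114.0, 1L, 0),
                row("CD", "CA", "CB", "CG", 1.52, 111.3, 2L, 0),
                row("NE", "CB", "CG", "CD", 1.46, 112.0, 3L, 0),
                row("CZ", "CG", "CD", "NE", 1.33, 124.0, 4L, 0),
                row("NH1", "CD", "NE", "CZ", 1.33, 120.0, 0L, 0),
                row("NH2", "CD", "NE", "CZ", 1.33, 120.0, 0L, 180)),
    HIS = rbind(row("CG", "N", "CA", "CB", 1.50, 113.8, 1L, 0),
                row("ND1", "CA", "CB", "CG", 1.38, 122.7, 2L, 0),
                row("CD2", "CA", "CB", "CG", 1.36, 129.7, 2L, 180),
                row("CE1", "CB", "CG", "ND1", 1.32, 109.0, 0L, 180),
                row("NE2", "CG", "ND1", "CE1", 1.32, 108.0, 0L, 0)),
    PHE = rbind(row("CG", "N", "CA", "CB", 1.50, 113.8, 1L, 0),
                row("CD1", "CA", "CB", "CG", 1.39, 120.7, 2L, 0),
                row("CD2", "CA", "CB", "CG", 1.39, 120.7, 2L, 180),
                row("CE1", "CB", "CG", "CD1", 1.39, 120.0, 0L, 180),
                row("CE2", "CB", "CG", "CD2", 1.39, 120.0, 0L, 180),
                row("CZ", "CG", "CD1", "CE1", 1.39, 120.0, 0L, 0)),
    TYR = rbind(row("CG", "N", "CA", "CB", 1.50, 113.8, 1L, 0),
                row("CD1", "CA", "CB", "CG", 1.39, 120.7, 2L, 0),
                row("CD2", "CA", "CB", "CG", 1.39, 120.7, 2L, 180),
                row("CE1", "CB", "CG", "CD1", 1.39, 120.0, 0L, 180),
                row("CE2", "CB", "CG", "CD2", 1.39, 120.0, 0L, 180),
                row("CZ", "CG", "CD1", "CE1", 1.39, 120.0, 0L, 0),
                row("OH", "CD1", "CE1", "CZ", 1.38, 120.0, 0L, 180)),
    TRP = rbind(row("CG", "N", "CA", "CB", 1.50, 113.8, 1L, 0),
                row("CD1", "CA", "CB", "CG", 1.37, 127.0, 2L, 0),
                row("CD2", "CA", "CB", "CG", 1.43, 126.6, 2L, 180),
                row("NE1", "CB", "CG", "CD1", 1.38, 110.2, 0L, 180),
                row("CE2", "CB", "CG", "CD2", 1.41, 107.2, 0L, 180),
                row("CE3", "CB", "CG", "CD2", 1.40, 133.9, 0L, 0),
                row("CZ2", "CG", "CD2", "CE2", 1.40, 122.4, 0L, 180),
                row("CZ3", "CG", "CD2", "CE3", 1.39, 118.8, 0L, 180),
                row("CH2", "CD2", "CE2", "CZ2", 1.37, 117.5, 0L, 0)),
    PRO = rbind(row("CG", "N", "CA", "CB", 1.50, 104.0, 1L, 0),
                row("CD", "CA", "CB", "CG", 1.50, 105.0, 2L, 0)),
    stop(sprintf("unknown residue type '%s'", restype)))
}

#' Load a rotamer library from a TSV table
#'
#' Expected columns: \code{restype} (3-letter code), \code{chi1..chi4}
#' (degrees, empty/NA when unused), optional \code{freq}. Rows with unknown
#' residue types are skipped with a warning. Ala and Gly always have a
#' single (chi-free) conformer, whether or not the table lists them.
#'
#' @param path TSV file path.
#' @return A \code{rotamer_library}: list of per-type chi matrices.
#' @export
load_rotamer_library <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot("restype" %in% names(tab))
  tab$restype <- toupper(tab$restype)
  bad <- !(tab$restype %in% AA3)
  if (any(bad)) {
    warning(sprintf("skipping %d rotamer row(s) with unknown residue type",
                    sum(bad)))
    tab <- tab[!bad, , drop = FALSE]
  }
  lib <- list()
  for (res in AA3) {
    nchi <- N_CHI[[res]]
    if (nchi == 0L) {
      lib[[res]] <- matrix(numeric(0), nrow = 1L, ncol = 0L)
      next
    }
    rows <- tab[tab$restype == res, , drop = FALSE]
    if (nrow(rows) == 0L) {
      lib[[res]] <- matrix(180, nrow = 1L, ncol = nchi)
      next
    }
    chis <- as.matrix(rows[, paste0("chi", seq_len(nchi)), drop = FALSE])
    storage.mode(chis) <- "double"
    lib[[res]] <- chis
  }
  structure(lib, class = "rotamer_library")
}

#' The shipped synthetic staggered-conformer rotamer library
#'
#' A compact idealized library enumerating canonical gauche-/trans/gauche+
#' chi combinations (aromatic chi2 at +/-90, carboxamide/carboxylate
#' terminal chi at -90/0/90, proline ring pucker pairs). It is a synthetic
#' stand-in table in the standard TSV library format; any user-provided
#' library can be loaded with \code{\link{load_rotamer_library}}.
#'
#' @return A \code{rotamer_library}.
#' @export
default_rotamer_library <- function() {
  path <- system.file("extdata", "rotamers_synthetic.tsv", package = "cdrpref")
  if (!nzchar(path)) stop("shipped rotamer table not found")
  load_rotamer_library(path)
}

#' @export
print.rotamer_library <- function(x, ...) {
  n <- vapply(x, nrow, integer(1))
  cat(sprintf("rotamer_library: %d residue types, %d rotamers total\n",
              length(x), sum(n)))
  invisible(x)
}

# Ideal CB construction from backbone N, CA, C (L-configuration).
ideal_cb <- function(n, ca, c) {
  place_atom(c, n, ca, 1.53, 110.4, CB_IMPROPER)
}
# torsion C-N-CA-CB for an L-amino acid; sign fixed by the chirality test
# dot(CB-CA, cross(N-CA, C-CA)) < 0 as observed in standard L residues.
CB_IMPROPER <- -122.6

residue_sel <- function(s, chain, resid) {
  which(s$atoms$chain == chain & s$atoms$resid == as.character(resid))
}

#' Reduce listed positions of a structure to alanine
#'
#' Listed residues keep only N, CA, C, O and CB; a CB is constructed at the
#' ideal tetrahedral position when absent (Gly). All other residues are
#' untouched.
#'
#' @param s a \code{structure3d}.
#' @param positions data.frame with columns \code{chain}, \code{resid}.
#' @return The reduced \code{structure3d}.
#' @export
build_alanine_scaffold <- function(s, positions) {
  stopifnot(inherits(s, "structure3d"))
  atoms <- s$atoms
  drop <- logical(nrow(atoms))
  extra <- list()
  for (p in seq_len(nrow(positions))) {
    sel <- residue_sel(s, positions$chain[p], positions$resid[p])
    if (length(sel) == 0L)
      stop(sprintf("position %s-%s not found", positions$resid[p], positions$chain[p]))
    nm <- atoms$name[sel]
    need <- c("N", "CA", "C")
    if (!all(need %in% nm))
      stop(sprintf("missing backbone atom(s) %s in residue %s-%s",
                   paste(setdiff(need, nm), collapse = ","),
                   positions$resid[p], positions$chain[p]))
    keep <- nm %in% c("N", "CA", "C", "O", "CB")
    drop[sel[!keep]] <- TRUE
    atoms$resname[sel] <- "ALA"
    if (!("CB" %in% nm)) {
      xyz <- as.matrix(atoms[sel, c("x", "y", "z")])
      rownames(xyz) <- nm
      cb <- ideal_cb(xyz["N", ], xyz["CA", ], xyz["C", ])
      tmpl <- atoms[sel[1L], , drop = FALSE]
      tmpl$name <- "CB"; tmpl$element <- "C"
      tmpl$x <- cb[1L]; tmpl$y <- cb[2L]; tmpl$z <- cb[3L]
      tmpl$vdw <- vdw_radius_for("C")
      tmpl$serial <- max(atoms$serial) + length(extra) + 1L
      tmpl$atom_type <- NA_character_
      extra[[length(extra) + 1L]] <- tmpl
    }
  }
  atoms <- atoms[!drop, , drop = FALSE]
  if (length(extra)) atoms <- rbind(atoms, do.call(rbind, extra))
  new_structure3d(atoms, s$metadata)
}

# Build sidechain atom coordinates for `restype` at a backbone (named xyz
# rows N, CA, CB; CB required except Gly) under chi angles `chi`.
build_sidechain <- function(restype, bb, chi) {
  topo <- sidechain_topology(restype)
  if (is.null(topo)) return(NULL)
  coords <- list(N = bb["N", ], CA = bb["CA", ], CB = bb["CB", ])
  out <- matrix(NA_real_, nrow = nrow(topo), ncol = 3L,
                dimnames = list(topo$atom, NULL))
  for (r in seq_len(nrow(topo))) {
    tor <- if (topo$chi[r] > 0L) chi[topo$chi[r]] + topo$off[r] else topo$off[r]
    p <- place_atom(coords[[topo$p1[r]]], coords[[topo$p2[r]]],
                    coords[[topo$p3[r]]], topo$len[r], topo$ang[r], tor)
    coords[[topo$atom[r]]] <- p
    out[r, ] <- p
  }
  out
}

#' Enumerate clash-filtered rotamer placements at a scaffold position
#'
#' Builds every library rotamer of amino-acid type \code{aa} on the fixed
#' backbone at \code{position} and removes placements in which any built
#' sidechain atom clashes with the rest of the complex (distance below
#' r1 + r2 - \code{clash_tol}; atoms of the mutated residue are exempt).
#'
#' @param scaffold alanine-reduced \code{structure3d}.
#' @param position one-row data.frame (\code{chain}, \code{resid}).
#' @param aa 1-letter or 3-letter amino-acid code.
#' @param library a \code{rotamer_library}.
#' @param clash_tol vdW overlap tolerance in Angstrom.
#' @param keep_clashing keep clash-positive placements (flagged) instead of
#'   dropping them.
#' @param scheme atom typing scheme applied to placement atoms.
#' @return List of placements: each has \code{position}, \code{aa},
#'   \code{rotamer}, \code{chi}, \code{atoms} (full residue heavy-atom
#'   table), \code{xyz}, and \code{clash_free}.
#' @export
enumerate_placements <- function(scaffold, position, aa, library,
                                 clash_tol = 0.6, keep_clashing = FALSE,
                                 scheme = default_atom_typing()) {
  restype <- if (nchar(aa) == 1L) aa_three(aa) else toupper(aa)
  if (is.na(restype) || !(restype %in% AA3))
    stop(sprintf("unknown amino acid '%s'", aa))
  sel <- residue_sel(scaffold, position$chain[1L], position$resid[1L])
  if (length(sel) == 0L)
    stop(sprintf("position %s-%s not in scaffold",
                 position$resid[1L], position$chain[1L]))
  nm <- scaffold$atoms$name[sel]
  bb <- as.matrix(scaffold$atoms[sel, c("x", "y", "z")])
  rownames(bb) <- nm
  if (!all(c("N", "CA", "C") %in% nm))
    stop("scaffold position lacks backbone atoms")
  if (!("CB" %in% nm))
    bb <- rbind(bb, CB = ideal_cb(bb["N", ], bb["CA", ], bb["C", ]))
  other_xyz <- atom_xyz(scaffold)[-sel, , drop = FALSE]
  other_vdw <- scaffold$atoms$vdw[-sel]
  chis <- library[[restype]]
  skey <- paste(scheme$resname, scheme$atom, sep = "|")
  placements <- list()
  for (k in seq_len(nrow(chis))) {
    chi <- as.numeric(chis[k, ])
    sc <- build_sidechain(restype, bb, chi)
    # full residue heavy-atom set: backbone (+CB except Gly) + built atoms
    base_names <- intersect(c("N", "CA", "C", "O"), nm)
    res_names <- c(base_names,
                   if (restype != "GLY") "CB",
                   if (!is.null(sc)) rownames(sc))
    res_xyz <- rbind(bb[base_names, , drop = FALSE],
                     if (restype != "GLY") bb["CB", , drop = FALSE],
                     sc)
    rownames(res_xyz) <- res_names
    el <- substr(res_names, 1L, 1L)
    vdw <- vdw_radius_for(el)
    type <- scheme$type[match(paste(restype, res_names, sep = "|"), skey)]
    clash_free <- TRUE
    if (!is.null(sc) && nrow(other_xyz) > 0L) {
      for (a in seq_len(nrow(sc))) {
        d <- sqrt((other_xyz[, 1L] - sc[a, 1L])^2 +
                    (other_xyz[, 2L] - sc[a, 2L])^2 +
                    (other_xyz[, 3L] - sc[a, 3L])^2)
        lim <- vdw_radius_for(substr(rownames(sc)[a], 1L, 1L)) + other_vdw - clash_tol
        if (any(d < lim)) {
          clash_free <- FALSE
          break
        }
      }
    }
    if (!clash_free && !keep_clashing) next
    placements[[length(placements) + 1L]] <- list(
      position = data.frame(chain = position$chain[1L],
                            resid = as.character(position$resid[1L]),
                            stringsAsFactors = FALSE),
      aa = aa_one(restype), restype = restype, rotamer = k, chi = chi,
      atoms = data.frame(name = res_names, element = el, vdw = vdw,
                         atom_type = type, x = res_xyz[, 1L],
                         y = res_xyz[, 2L], z = res_xyz[, 3L],
                         stringsAsFactors = FALSE),
      xyz = res_xyz, clash_free = clash_free)
  }
  placements
}

#' Export placements as a multi-model PDB file
#'
#' @param placements list of placements from
#'   \code{\link{enumerate_placements}}.
#' @param path output file.
#' @export
write_placements_pdb <- function(placements, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(placements)) {
    p <- placements[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    a <- p$atoms
    writeLines(sprintf(
      "ATOM  %5d %-4s%1s%3s %1s%4s    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)), ifelse(nchar(a$name) >= 4L, a$name, paste0(" ", a$name)),
      " ", p$restype, p$position$chain, p$position$resid,
      a$x, a$y, a$z, 1, 0, a$element), con)
    writeLines("ENDMDL", con)
  }
  invisible(path)
}

# --- conformation classification ----------------------------------------

backbone_dihedrals <- function(s, chain, resid) {
  a <- s$atoms
  res <- residue_table(s)
  res <- res[res$chain == chain, , drop = FALSE]
  i <- which(res$resid == as.character(resid))
  if (length(i) != 1L) stop("residue not found")
  get <- function(rid, name) {
    sel <- which(a$chain == chain & a$resid == rid & a$name == name)
    if (length(sel) != 1L) return(NULL)
    c(a$x[sel], a$y[sel], a$z[sel])
  }
  rid <- res$resid[i]
  phi <- psi <- chi1 <- NA_real_
  if (i > 1L) {
    cprev <- get(res$resid[i - 1L], "C")
    n <- get(rid, "N"); ca <- get(rid, "CA"); cc <- get(rid, "C")
    if (!is.null(cprev) && !is.null(n) && !is.null(ca) && !is.null(cc))
      phi <- dihedral_angle(cprev, n, ca, cc)
  }
  if (i < nrow(res)) {
    n <- get(rid, "N"); ca <- get(rid, "CA"); cc <- get(rid, "C")
    nnext <- get(res$resid[i + 1L], "N")
    if (!is.null(nnext) && !is.null(n) && !is.null(ca) && !is.null(cc))
      psi <- dihedral_angle(n, ca, cc, nnext)
  }
  gamma <- c("OG", "OG1", "SG", "CG", "CG1")
  nm <- a$name[a$chain == chain & a$resid == rid]
  g <- gamma[gamma %in% nm][1L]
  if (!is.na(g)) {
    n <- get(rid, "N"); ca <- get(rid, "CA"); cb <- get(rid, "CB")
    gx <- get(rid, g)
    if (!is.null(n) && !is.null(ca) && !is.null(cb) && !is.null(gx))
      chi1 <- dihedral_angle(n, ca, cb, gx)
  }
  list(phi = phi, psi = psi, chi1 = chi1)
}

backbone_bin <- function(phi, psi) {
  inbin <- function(x, lo, hi) !is.na(x) && x >= lo && x < hi
  if (is.na(phi) || is.na(psi)) return(NA_character_)
  if (inbin(phi, -120, -30) && inbin(psi, -80, 0)) return("helix")
  if (inbin(phi, -180, -90) && (inbin(psi, 90, 180.000001))) return("sheet")
  if (inbin(phi, -90, -20) && inbin(psi, 90, 180.000001)) return("ppii")
  if (inbin(phi, 20, 120) && inbin(psi, -60, 90)) return("left")
  if (inbin(phi, -180, -20) && inbin(psi, 0, 90)) return("bridge")
  "other"
}

chi1_bin <- function(chi1) {
  if (is.na(chi1)) return("")
  if (chi1 >= 0 && chi1 < 120) return("g+")
  if (chi1 >= -120 && chi1 < 0) return("g-")
  "t"
}

#' Classify the backbone/chi1 conformation of a residue
#'
#' Deterministic half-open phi/psi rectangle binning (helix, sheet, PPII,
#' left-handed, bridge, other) crossed with three chi1 bins (g-, t, g+).
#' Residues without computable phi or psi (chain termini) are
#' "unclassified".
#'
#' @param s a \code{structure3d}.
#' @param chain,resid residue address.
#' @return Class id string, e.g. \code{"helix.g-"}; \code{"unclassified"}
#'   at termini.
#' @export
classify_conformation <- function(s, chain, resid) {
  d <- backbone_dihedrals(s, chain, resid)
  bb <- backbone_bin(d$phi, d$psi)
  if (is.na(bb)) return("unclassified")
  cb <- chi1_bin(d$chi1)
  if (cb == "") bb else paste(bb, cb, sep = ".")
}
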