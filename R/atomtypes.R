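# Atom typing scheme, van der Waals radii and reference residue areas.
#
# The typing scheme groups protein heavy atoms into physicochemical classes
# (amide/charged/aromatic nitrogens, carbonyl/carboxyl/hydroxyl oxygens,
# aliphatic/aromatic/carbonyl carbons, sulfur, water oxygen). Probability
# density maps are built per atom type, so the scheme is a configuration
# object: `default_atom_typing()` returns the shipped table and any table
# with the same columns can be substituted.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")
names(AA1) <- AA3

aa_three <- function(one) AA3[match(toupper(one), AA1)]
aa_one <- function(three) unname(AA1[toupper(three)])

#' Bondi van der Waals radii (Angstrom) by element
#'
#' @return Named numeric vector; elements not listed fall back to 1.70.
#' @export
bondi_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
}

vdw_radius_for <- function(element, radii = bondi_radii()) {
  r <- radii[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# Atom type codes used by the default scheme.
ATOM_TYPES <- c("N_amide", "N_arg", "N_lys", "N_aromatic",
                "O_carbonyl", "O_carboxyl", "O_hydroxyl",
                "C_aliphatic", "C_aromatic", "C_carbonyl",
                "S_any", "WATER_O", "other")

#' Default protein heavy-atom typing scheme
#'
#' Maps (residue name, atom name) pairs to one of the package's atom type
#' codes. Backbone atoms of every standard residue are covered; sidechain
#' atoms are typed by chemistry (e.g. Tyr OH is a hydroxyl oxygen, Arg NH1
#' a guanidinium nitrogen). Water oxygens (HOH/WAT O) map to \code{WATER_O}.
#'
#' @return data.frame with columns \code{resname}, \code{atom}, \code{type}.
#' @export
default_atom_typing <- function() {
  rows <- list()
  add <- function(res, atoms, type) {
    rows[[length(rows) + 1L]] <<- data.frame(
      resname = res, atom = atoms, type = type, stringsAsFactors = FALSE)
  }
  for (res in AA3) {
    add(res, "N", "N_amide")
    add(res, "CA", "C_aliphatic")
    add(res, "C", "C_carbonyl")
    add(res, "O", "O_carbonyl")
    add(res, "OXT", "O_carboxyl")
    if (res != "GLY") add(res, "CB", "C_aliphatic")
  }
  add("ARG", c("CG", "CD"), "C_aliphatic")
  add("ARG", "CZ", "C_carbonyl")
  add("ARG", c("NE", "NH1", "NH2"), "N_arg")
  add("ASN", "CG", "C_carbonyl")
  add("ASN", "OD1", "O_carbonyl")
  add("ASN", "ND2", "N_amide")
  add("ASP", "CG", "C_carbonyl")
  add("ASP", c("OD1", "OD2"), "O_carboxyl")
  add("CYS", "SG", "S_any")
  add("GLN", "CG", "C_aliphatic")
  add("GLN", "CD", "C_carbonyl")
  add("GLN", "OE1", "O_carbonyl")
  add("GLN", "NE2", "N_amide")
  add("GLU", c("CG"), "C_aliphatic")
  add("GLU", "CD", "C_carbonyl")
  add("GLU", c("OE1", "OE2"), "O_carboxyl")
  add("HIS", "CG", "C_aromatic")
  add("HIS", c("ND1", "NE2"), "N_aromatic")
  add("HIS", c("CD2", "CE1"), "C_aromatic")
  add("ILE", c("CG1", "CG2", "CD1"), "C_aliphatic")
  add("LEU", c("CG", "CD1", "CD2"), "C_aliphatic")
  add("LYS", c("CG", "CD", "CE"), "C_aliphatic")
  add("LYS", "NZ", "N_lys")
  add("MET", c("CG", "CE"), "C_aliphatic")
  add("MET", "SD", "S_any")
  add("PHE", c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"), "C_aromatic")
  add("PRO", c("CG", "CD"), "C_aliphatic")
  add("SER", "OG", "O_hydroxyl")
  add("THR", "OG1", "O_hydroxyl")
  add("THR", "CG2", "C_aliphatic")
  add("TRP", c("CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
      "C_aromatic")
  add("TRP", "NE1", "N_aromatic")
  add("TYR", c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"), "C_aromatic")
  add("TYR", "OH", "O_hydroxyl")
  add("VAL", c("CG1", "CG2"), "C_aliphatic")
  add(c("HOH", "WAT", "DOD"), "O", "WATER_O")
  do.call(rbind, rows)
}

#' Assign atom types to a structure
#'
#' Every heavy atom gets an \code{atom_type} from the scheme; pairs the
#' scheme does not cover are assigned the reserved type \code{"other"} and
#' counted in a warning.
#'
#' @param s a \code{structure3d}.
#' @param scheme typing table as from \code{\link{default_atom_typing}}.
#' @return The structure with an \code{atom_type} column filled in.
#' @export
assign_atom_types <- function(s, scheme = default_atom_typing()) {
  stopifnot(inherits(s, "structure3d"))
  if (is.null(scheme) || nrow(scheme) == 0L)
    stop("atom typing scheme is empty")
  key <- paste(s$atoms$resname, s$atoms$name, sep = "|")
  skey <- paste(scheme$resname, scheme$atom, sep = "|")
  idx <- match(key, skey)
  type <- scheme$type[idx]
  n_unknown <- sum(is.na(type))
  if (n_unknown > 0L)
    warning(sprintf("%d atom(s) not covered by the typing scheme; assigned 'other'",
                    n_unknown))
  type[is.na(type)] <- "other"
  s$atoms$atom_type <- type
  s
}

# Theoretical maximum SASA per residue (Angstrom^2), Tien et al. style
# values, used as the denominator of relative SASA in the Levy-style
# core/rim classification.
max_residue_sasa <- function() {
  c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLN = 225,
    GLU = 223, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
    MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
    TYR = 263, VAL = 174)
}
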