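# Interface core/rim classification (Levy-style) and CDR contact flags.
#
# An interface residue is any residue whose SASA changes on complexation.
# Relative SASA (rASA) is residue SASA divided by the residue type's
# theoretical maximum; core = rASA >= core_cut free AND < core_cut in the
# complex; rim = interface residue that is not core. A CDR position is a
# "contact" position when at least one heavy atom of one clash-free rotamer
# of any amino-acid type reaches within `contact_cutoff` of an antigen
# atom; positions too distant to make any such contact are non-contact.

#' Classify an antibody-antigen interface
#'
#' @param complex a \code{structure3d} containing both molecules.
#' @param side_a_chains,side_b_chains chain ids of the two sides (side A is
#'   the antibody side carrying the CDR positions).
#' @param cdr_positions optional data.frame with columns \code{chain},
#'   \code{resid} of CDR positions on side A.
#' @param core_cut relative-SASA threshold of the core definition.
#' @param contact_cutoff heavy-atom distance (Angstrom) defining a contact
#'   CDR position.
#' @param contact_method \code{"rotamer"} (enumerate clash-free rotamers of
#'   all 20 types at each CDR position) or \code{"residue"} (use the atoms
#'   present in the structure).
#' @param library rotamer library for \code{contact_method = "rotamer"}.
#' @param n_points SASA quadrature points.
#' @return An \code{interface_classification}: list with \code{residues}
#'   (per-residue table with SASA, delta fraction and class) and \code{cdr}
#'   (per-position contact flags), plus the inputs used.
#' @export
classify_interface <- function(complex, side_a_chains, side_b_chains,
                               cdr_positions = NULL,
                               core_cut = 0.25, contact_cutoff = 6.0,
                               contact_method = c("rotamer", "residue"),
                               library = NULL, n_points = 240L) {
  stopifnot(inherits(complex, "structure3d"))
  contact_method <- match.arg(contact_method)
  if (length(intersect(side_a_chains, side_b_chains)) > 0L)
    stop("side A and side B chains overlap")
  chains <- unique(complex$atoms$chain)
  if (!all(c(side_a_chains, side_b_chains) %in% chains))
    stop("some requested chains are absent from the complex")

  sasa_cx <- compute_sasa(complex, n_points = n_points)
  side <- ifelse(complex$atoms$chain %in% side_a_chains, "A",
                 ifelse(complex$atoms$chain %in% side_b_chains, "B", NA))
  res_rows <- list()
  for (sd in c("A", "B")) {
    ch <- if (sd == "A") side_a_chains else side_b_chains
    iso <- subset_chains(complex, ch)
    sasa_iso <- compute_sasa(iso, n_points = n_points)
    key_iso <- paste(sasa_iso$residue$chain, sasa_iso$residue$resid, sep = "|")
    rc <- sasa_cx$residue[sasa_cx$residue$chain %in% ch, , drop = FALSE]
    key_cx <- paste(rc$chain, rc$resid, sep = "|")
    free <- sasa_iso$residue$sasa[match(key_cx, key_iso)]
    maxs <- max_residue_sasa()[rc$resname]
    maxs[is.na(maxs)] <- mean(max_residue_sasa())
    delta <- free - rc$sasa
    dfrac <- ifelse(free > 1e-9, pmax(0, pmin(1, delta / free)), 0)
    rel_free <- free / maxs
    rel_cx <- rc$sasa / maxs
    is_iface <- delta > 1e-6
    cls <- ifelse(!is_iface, "non_interface",
                  ifelse(rel_free >= core_cut & rel_cx < core_cut, "core", "rim"))
    res_rows[[sd]] <- data.frame(side = sd, chain = rc$chain, resid = rc$resid,
                                 resname = rc$resname, sasa_free = free,
                                 sasa_complex = rc$sasa,
                                 delta_fraction = dfrac,
                                 rel_free = rel_free, rel_complex = rel_cx,
                                 class = cls, stringsAsFactors = FALSE)
  }
  residues <- do.call(rbind, res_rows)
  rownames(residues) <- NULL

  cdr <- NULL
  if (!is.null(cdr_positions) && nrow(cdr_positions) > 0L) {
    akey <- paste(residues$chain, residues$resid, sep = "|")
    pkey <- paste(cdr_positions$chain, cdr_positions$resid, sep = "|")
    if (!all(pkey %in% akey[residues$side == "A"]))
      stop("some cdr_positions are absent from side A")
    bxyz <- atom_xyz(subset_chains(complex, side_b_chains))
    contact <- logical(nrow(cdr_positions))
    if (contact_method == "residue") {
      for (p in seq_len(nrow(cdr_positions))) {
        sel <- complex$atoms$chain == cdr_positions$chain[p] &
          complex$atoms$resid == cdr_positions$resid[p]
        axyz <- atom_xyz(complex)[sel, , drop = FALSE]
        contact[p] <- min_cross_dist(axyz, bxyz) <= contact_cutoff
      }
    } else {
      if (is.null(library)) library <- default_rotamer_library()
      scaffold <- build_alanine_scaffold(complex, cdr_positions)
      for (p in seq_len(nrow(cdr_positions))) {
        pos <- cdr_positions[p, , drop = FALSE]
        hit <- FALSE
        for (aa in AA1) {
          pl <- enumerate_placements(scaffold, pos, aa, library)
          for (q in pl) {
            if (q$clash_free &&
                min_cross_dist(q$xyz, bxyz) <= contact_cutoff) {
              hit <- TRUE
              break
            }
          }
          if (hit) break
        }
        contact[p] <- hit
      }
    }
    i <- match(pkey, akey)
    cdr <- data.frame(chain = cdr_positions$chain, resid = cdr_positions$resid,
                      contact = contact,
                      delta_fraction = residues$delta_fraction[i],
                      class = residues$class[i], stringsAsFactors = FALSE)
  }
  structure(list(residues = residues, cdr = cdr, core_cut = core_cut,
                 contact_cutoff = contact_cutoff), class = "interface_classification")
}

min_cross_dist <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(Inf)
  m <- Inf
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1L] - a[i, 1L])^2 + (b[, 2L] - a[i, 2L])^2 + (b[, 3L] - a[i, 3L])^2
    m <- min(m, min(d2))
  }
  sqrt(m)
}

#' @export
print.interface_classification <- function(x, ...) {
  tab <- table(x$residues$class)
  cat("interface_classification:\n")
  print(tab)
  if (!is.null(x$cdr))
    cat(sprintf("CDR positions: %d contact, %d non-contact\n",
                sum(x$cdr$contact), sum(!x$cdr$contact)))
  invisible(x)
}

#' Write an interface report as TSV
#'
#' @param x an \code{interface_classification}.
#' @param path output file.
#' @export
write_interface_tsv <- function(x, path) {
  df <- x$residues[, c("chain", "resid", "resname", "sasa_free",
                       "sasa_complex", "delta_fraction", "class")]
  names(df)[2L] <- "resnum"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
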