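# Position x amino-acid scoring: atomistic contact term X, hydration-
# mediated term Y, structural propensity Z, rotamer aggregation
# (X = max over rotamers, Y = min over rotamers), per-antigen-atom contact
# maps and W-vs-term correlations.
#
# The log convention throughout is L(v) = log10(max(v, p_ref) / p_ref) with
# p_ref = 1e-10: a PDM value at or below the reference probability
# contributes 0, so all L terms are finite and non-negative, and X >= 0.

pdm_log <- function(v, p_ref) log10(pmax(v, p_ref) / p_ref)

#' Atomistic contact score of one rotamer placement
#'
#' X(rotamer k) = sum over the placed residue's n heavy atoms of
#' log10(max(AVE(PDM_m), p_ref) / p_ref), where AVE(PDM_m) is the mean
#' antigen-side PDM value of atom m's type over the cells inside atom m's
#' vdW sphere.
#'
#' @param placement a placement from \code{\link{enumerate_placements}}.
#' @param antigen_maps named list of \code{grid3d} PDMs, one per atom type
#'   occurring in the placement.
#' @param p_ref reference probability.
#' @param sidechain_only sum over sidechain atoms only instead of all
#'   heavy atoms.
#' @return Scalar X value (finite, >= 0).
#' @export
contact_score <- function(placement, antigen_maps, p_ref = 1e-10,
                          sidechain_only = FALSE) {
  a <- placement$atoms
  if (sidechain_only)
    a <- a[!(a$name %in% c("N", "CA", "C", "O")), , drop = FALSE]
  if (nrow(a) == 0L) return(0)
  x <- 0
  for (i in seq_len(nrow(a))) {
    tt <- a$atom_type[i]
    if (is.na(tt) || is.null(antigen_maps[[tt]]))
      stop(sprintf("no PDM supplied for atom type '%s'", tt))
    ave <- suppressWarnings(
      average_pdm_over_atom(antigen_maps[[tt]], c(a$x[i], a$y[i], a$z[i]),
                            a$vdw[i]))
    x <- x + pdm_log(ave, p_ref)
  }
  x
}

#' Hydration-mediated score of one placement
#'
#' Y = - sum over cells inside the antigen volume of L(water PDM of the
#' antibody residue) - sum over cells inside the antibody volume of
#' L(water PDM of the antigen) + sum over the overlap region (cells where
#' both water maps exceed p_ref and that lie in neither molecular volume)
#' of both L terms. The two negative sums are the desolvation penalties of
#' the two binding sites; the positive sum is the water-mediated
#' interaction reward.
#'
#' @param water_map_ab water PDM generated by the placed antibody residue
#'   alone.
#' @param water_map_ag water PDM of the antigen surface.
#' @param mask_ab,mask_ag 0/1 molecular-volume masks of antibody and
#'   antigen on the same grid.
#' @param p_ref reference probability.
#' @return Scalar Y value (finite).
#' @export
hydration_score <- function(water_map_ab, water_map_ag, mask_ab, mask_ag,
                            p_ref = 1e-10) {
  for (g in list(water_map_ag, mask_ab, mask_ag)) {
    if (!all(g$dim == water_map_ab$dim) || g$spacing != water_map_ab$spacing ||
        max(abs(g$origin - water_map_ab$origin)) > 1e-6)
      stop("hydration_score: grids do not match")
  }
  lab <- pdm_log(water_map_ab$values, p_ref)
  lag <- pdm_log(water_map_ag$values, p_ref)
  in_ab <- mask_ab$values > 0
  in_ag <- mask_ag$values > 0
  overlap <- water_map_ab$values > p_ref & water_map_ag$values > p_ref &
    !in_ab & !in_ag
  -sum(lab[in_ag]) - sum(lag[in_ab]) + sum(lab[overlap] + lag[overlap])
}

#' Structural propensity Z from a count profile
#'
#' Bayesian pseudo-counted log-odds in half-bit units: with effective count
#' M'_j = sum_k C_jk and pseudo-count B'_j = B + M - M'_j,
#' Z_ji = 2 log2( ((C_ji + B'_j p_i) / (M'_j + B'_j)) / p_i ). With no gaps
#' (M'_j = M) and B = sqrt(M) this reduces to the experimental-preference
#' form.
#'
#' @param C counts matrix (positions x 20 amino acids, one-letter column
#'   names).
#' @param M number of rows of the underlying alignment profile.
#' @param p background probabilities over the 20 types (sums to 1).
#' @param B pseudo-count base; default sqrt(M).
#' @return Matrix of Z values, same shape as \code{C}.
#' @export
structural_propensity <- function(C, M, p, B = sqrt(M)) {
  C <- as.matrix(C)
  if (is.null(colnames(C))) colnames(C) <- AA1
  if (!is.null(names(p))) p <- p[colnames(C)]
  if (any(p <= 0 & colSums(C) > 0))
    stop("zero background probability for an observed amino acid")
  Mp <- rowSums(C)
  if (any(Mp > M + 1e-9)) stop("row counts exceed M")
  Bp <- B + M - Mp
  q <- (C + outer(Bp, p)) / (Mp + Bp)
  2 * log2(sweep(q, 2L, p, "/"))
}

#' Score all (position, amino acid) pairs on a scaffold
#'
#' For each CDR position j and type i all clash-free rotamers are placed
#' and scored; X_ji is the maximum contact score over rotamers and Y_ji the
#' minimum hydration score. Types with no clash-free rotamer get X = Y = 0
#' and are flagged sterically excluded.
#'
#' @param scaffold alanine-reduced antibody-side \code{structure3d}
#'   (complex context: include the antigen atoms for the clash filter by
#'   passing the whole complex reduced at the CDR positions).
#' @param positions data.frame (\code{chain}, \code{resid}) of CDR
#'   positions.
#' @param antigen_maps named per-atom-type list of antigen PDMs for X.
#' @param library a \code{rotamer_library}.
#' @param types 1-letter amino-acid codes to score (default all 20).
#' @param stats optional \code{contact_statistics} for the Y term.
#' @param water_map_ag optional antigen water PDM (enables Y).
#' @param mask_ab,mask_ag optional molecular-volume masks on the water-map
#'   grid (required when Y is computed).
#' @param p_ref reference probability.
#' @param clash_tol clash tolerance passed to the placement filter.
#' @return A \code{score_table} data.frame: position, aa, X, Y,
#'   n_rotamers, excluded; per-rotamer values in
#'   \code{attr(, "rotamer_scores")}.
#' @export
score_positions <- function(scaffold, positions, antigen_maps, library,
                            types = AA1, stats = NULL, water_map_ag = NULL,
                            mask_ab = NULL, mask_ag = NULL,
                            p_ref = 1e-10, clash_tol = 0.6) {
  compute_y <- !is.null(stats) && !is.null(water_map_ag) &&
    !is.null(mask_ab) && !is.null(mask_ag)
  rows <- list()
  per_rot <- list()
  for (p in seq_len(nrow(positions))) {
    pos <- positions[p, , drop = FALSE]
    lab <- paste0(pos$resid, "-", pos$chain)
    cls <- tryCatch(classify_conformation(scaffold, pos$chain, pos$resid),
                    error = function(e) "unclassified")
    for (aa in types) {
      pl <- enumerate_placements(scaffold, pos, aa, library,
                                 clash_tol = clash_tol)
      if (length(pl) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          position = lab, aa = aa, X = 0, Y = 0, n_rotamers = 0L,
          excluded = TRUE, stringsAsFactors = FALSE)
        next
      }
      xs <- vapply(pl, contact_score, numeric(1),
                   antigen_maps = antigen_maps, p_ref = p_ref)
      ys <- rep(0, length(pl))
      if (compute_y) {
        restype <- pl[[1L]]$restype
        for (k in seq_along(pl)) {
          bbk <- pl[[k]]$xyz
          fr <- local_frame(bbk["N", ], bbk["CA", ], bbk["C", ])
          wab <- build_water_pdm_for_residue(restype, cls, fr, stats,
                                             water_map_ag, p_ref)
          # antibody volume: scaffold mask plus the placed sidechain
          mab <- mask_ab
          extra <- setdiff(rownames(bbk), c("N", "CA", "C", "O", "CB"))
          if (length(extra)) {
            vals <- mab$values
            for (nm2 in extra) {
              idx <- cells_within_radius(mab, bbk[nm2, ],
                                         vdw_radius_for(substr(nm2, 1L, 1L)))
              vals[idx] <- 1
            }
            mab <- grid3d(mab$origin, mab$spacing, mab$dim, vals)
          }
          ys[k] <- hydration_score(wab, water_map_ag, mab, mask_ag, p_ref)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        position = lab, aa = aa, X = max(xs), Y = min(ys),
        n_rotamers = length(pl), excluded = FALSE, stringsAsFactors = FALSE)
      per_rot[[paste(lab, aa)]] <- data.frame(rotamer = vapply(pl, `[[`, 0L, "rotamer"),
                                              X = xs, Y = ys)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("score_table", class(out))
  attr(out, "p_ref") <- p_ref
  attr(out, "rotamer_scores") <- per_rot
  out
}

#' Write a score table as TSV
#'
#' @param x a \code{score_table} (optionally with a Z column merged in).
#' @param path output file.
#' @export
write_score_table_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-antigen-atom contact-strength map
#'
#' For each antigen atom, the mean over binder models of the summed
#' L-contributions of map cells inside that atom's vdW sphere that lie
#' within \code{shell} of any placed CDR atom of the model.
#'
#' @param antigen atom-typed \code{structure3d}.
#' @param model_placements list of models; each model is a list of
#'   placements.
#' @param maps per-atom-type list of PDMs around the binder models.
#' @param shell attribution shell in Angstrom.
#' @param p_ref reference probability.
#' @return Numeric vector, one non-negative strength per antigen atom.
#' @export
antigen_contact_map <- function(antigen, model_placements, maps,
                                shell = 6.0, p_ref = 1e-10) {
  stopifnot(length(model_placements) >= 1L)
  axyz <- atom_xyz(antigen)
  n <- nrow(axyz)
  acc <- numeric(n)
  for (model in model_placements) {
    pxyz <- do.call(rbind, lapply(model, function(p) p$xyz))
    for (i in seq_len(n)) {
      tt <- antigen$atoms$atom_type[i]
      g <- maps[[tt]]
      if (is.null(g)) next
      idx <- cells_within_radius(g, axyz[i, ], antigen$atoms$vdw[i])
      if (length(idx) == 0L) next
      ctr <- grid_centers(g)[idx, , drop = FALSE]
      near <- rep(FALSE, length(idx))
      if (!is.null(pxyz) && nrow(pxyz) > 0L) {
        for (a in seq_len(nrow(pxyz))) {
          d2 <- (ctr[, 1L] - pxyz[a, 1L])^2 + (ctr[, 2L] - pxyz[a, 2L])^2 +
            (ctr[, 3L] - pxyz[a, 3L])^2
          near <- near | d2 <= shell^2
          if (all(near)) break
        }
      }
      if (any(near))
        acc[i] <- acc[i] + sum(pdm_log(g$values[idx[near]], p_ref))
    }
  }
  acc / length(model_placements)
}

#' Correlate experimental preferences with score terms per position
#'
#' Pearson correlation of W against each supplied term over the amino-acid
#' types at each position; positions where either vector has zero variance
#' are reported NA.
#'
#' @param score_table data.frame with columns position, aa and any of
#'   X, Y, Z.
#' @param preference_table data.frame with columns position, aa, W.
#' @return data.frame: position, cc_WX, cc_WY, cc_WZ (columns present for
#'   the terms available).
#' @export
correlate_preferences <- function(score_table, preference_table) {
  terms <- intersect(c("X", "Y", "Z"), names(score_table))
  m <- merge(as.data.frame(score_table), preference_table,
             by = c("position", "aa"))
  pos <- unique(m$position)
  out <- data.frame(position = pos, stringsAsFactors = FALSE)
  for (tm in terms) out[[paste0("cc_W", tm)]] <- NA_real_
  for (i in seq_along(pos)) {
    sub <- m[m$position == pos[i], , drop = FALSE]
    if (nrow(sub) < 3L) next
    for (tm in terms) {
      if (stats::sd(sub$W) > 0 && stats::sd(sub[[tm]]) > 0)
        out[[paste0("cc_W", tm)]][i] <- stats::cor(sub$W, sub[[tm]])
    }
  }
  out
}
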