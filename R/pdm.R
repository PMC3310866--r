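# Knowledge-based probability density maps (PDMs).
#
# Contact statistics are harvested around buried ("interior") residues of a
# structure library: every neighbouring heavy atom (or crystallographic
# water oxygen) within a shell of the source residue is recorded in the
# source residue's local N-CA-C frame, keyed by (residue type, conformation
# class) and binned into a 3-D offset histogram per target atom type. A
# query structure then deposits, residue by residue, its class-conditioned
# histograms into a world grid; the accumulated map is normalized to a
# discrete probability over the grid. A pairwise interaction-preference
# filter removes deposits of target atom types that do not interact with
# any atom type present in the source residue.

hist_grid_spec <- function(shell_max, spacing) {
  half <- ceiling(shell_max / spacing)
  dim <- 2L * half + 1L
  list(half = half, dim = dim, spacing = spacing)
}

offset_to_bin <- function(offsets, spec) {
  ijk <- round(offsets / spec$spacing) + spec$half + 1
  ok <- ijk >= 1 & ijk <= spec$dim
  ok <- ok[, 1L] & ok[, 2L] & ok[, 3L]
  idx <- rep(NA_integer_, nrow(offsets))
  idx[ok] <- as.integer((ijk[ok, 3L] - 1) * spec$dim^2 +
                          (ijk[ok, 2L] - 1) * spec$dim + ijk[ok, 1L])
  idx
}

bin_to_offset <- function(idx, spec) {
  idx0 <- idx - 1L
  k <- idx0 %/% (spec$dim^2)
  j <- (idx0 %% (spec$dim^2)) %/% spec$dim
  i <- idx0 %% spec$dim
  (cbind(i, j, k) - spec$half) * spec$spacing
}

#' Harvest interior contact statistics from a structure library
#'
#' @param structures list of \code{structure3d} (atom-typed or not; types
#'   are assigned with \code{scheme} when absent). Read waters with
#'   \code{keep_waters = TRUE} to harvest hydration statistics.
#' @param scheme atom typing scheme.
#' @param shell_max contact shell radius in Angstrom around the source
#'   residue's atoms.
#' @param spacing histogram bin size in Angstrom.
#' @param burial_cut relative-SASA cutoff below which a source residue
#'   counts as interior.
#' @param n_points SASA quadrature points used for the burial test.
#' @return A \code{contact_statistics} object: per-(residue type,
#'   conformation class) histograms per target atom type, a pairwise
#'   atom-type contact count matrix, and the total harvested contact count.
#' @export
collect_interior_contacts <- function(structures, scheme = default_atom_typing(),
                                      shell_max = 6.0, spacing = 1.0,
                                      burial_cut = 0.05, n_points = 120L) {
  if (length(structures) == 0L) stop("empty structure library")
  spec <- hist_grid_spec(shell_max, spacing)
  hist <- list()
  types <- ATOM_TYPES
  pair <- matrix(0, length(types), length(types), dimnames = list(types, types))
  n_total <- 0L
  for (s in structures) {
    if (all(is.na(s$atoms$atom_type))) s <- assign_atom_types(s, scheme)
    sasa <- compute_sasa(s, n_points = n_points)
    maxs <- max_residue_sasa()[sasa$residue$resname]
    maxs[is.na(maxs)] <- mean(max_residue_sasa())
    rel <- sasa$residue$sasa / maxs
    buried <- sasa$residue[rel < burial_cut & sasa$residue$resname %in% AA3, ,
                           drop = FALSE]
    if (nrow(buried) == 0L) next
    axyz <- atom_xyz(s)
    for (b in seq_len(nrow(buried))) {
      sel <- residue_sel(s, buried$chain[b], buried$resid[b])
      nm <- s$atoms$name[sel]
      if (!all(c("N", "CA", "C") %in% nm)) next
      bb <- axyz[sel, , drop = FALSE]
      rownames(bb) <- nm
      fr <- local_frame(bb["N", ], bb["CA", ], bb["C", ])
      cls <- classify_conformation(s, buried$chain[b], buried$resid[b])
      key <- paste(buried$resname[b], cls, sep = "|")
      # neighbours: atoms of other, non-adjacent residues within the shell
      same_chain <- s$atoms$chain == buried$chain[b]
      adjacent <- same_chain &
        abs(s$atoms$resno - s$atoms$resno[sel[1L]]) <= 1L &
        s$atoms$ins == s$atoms$ins[sel[1L]]
      cand <- which(!adjacent | !same_chain)
      cand <- setdiff(cand, sel)
      if (length(cand) == 0L) next
      dmin <- rep(Inf, length(cand))
      for (i in sel) {
        d2 <- (axyz[cand, 1L] - axyz[i, 1L])^2 +
          (axyz[cand, 2L] - axyz[i, 2L])^2 + (axyz[cand, 3L] - axyz[i, 3L])^2
        dmin <- pmin(dmin, d2)
      }
      nb <- cand[dmin <= shell_max^2]
      if (length(nb) == 0L) next
      loc <- to_local(fr, axyz[nb, , drop = FALSE])
      bins <- offset_to_bin(loc, spec)
      ttypes <- s$atoms$atom_type[nb]
      keep <- !is.na(bins) & ttypes %in% types
      if (!any(keep)) next
      if (is.null(hist[[key]])) hist[[key]] <- list()
      for (i in which(keep)) {
        tt <- ttypes[i]
        if (is.null(hist[[key]][[tt]]))
          hist[[key]][[tt]] <- numeric(spec$dim^3)
        hist[[key]][[tt]][bins[i]] <- hist[[key]][[tt]][bins[i]] + 1
        n_total <- n_total + 1L
        # nearest source atom type for the pairwise preference tally
        d2 <- (axyz[sel, 1L] - axyz[nb[i], 1L])^2 +
          (axyz[sel, 2L] - axyz[nb[i], 2L])^2 +
          (axyz[sel, 3L] - axyz[nb[i], 3L])^2
        st <- s$atoms$atom_type[sel[which.min(d2)]]
        if (st %in% types) pair[st, tt] <- pair[st, tt] + 1
      }
    }
  }
  structure(list(hist = hist, pair = pair, spec = spec,
                 shell_max = shell_max, spacing = spacing,
                 n_contacts = n_total), class = "contact_statistics")
}

#' @export
print.contact_statistics <- function(x, ...) {
  cat(sprintf("contact_statistics: %d contacts, %d (residue, class) keys\n",
              x$n_contacts, length(x$hist)))
  invisible(x)
}

#' Pairwise atomistic interaction-preference filter
#'
#' Preference is the log2 odds of the observed pair frequency against the
#' frequency expected from the marginals of the (symmetrized) pair-count
#' table; pairs below \code{threshold} (and pairs never observed) are
#' flagged non-interacting.
#'
#' @param stats a \code{contact_statistics} or a raw symmetric pair-count
#'   matrix with atom types as dimnames.
#' @param threshold preference cutoff.
#' @return An \code{interaction_filter}: list with \code{preference},
#'   \code{interacting} (logical matrix) and \code{threshold}.
#' @export
build_interaction_filter <- function(stats, threshold = 0) {
  pair <- if (inherits(stats, "contact_statistics")) stats$pair else as.matrix(stats)
  if (sum(pair) == 0) stop("empty contact statistics")
  sym <- pair + t(pair)
  tot <- sum(sym)
  pm <- rowSums(sym) / tot
  expected <- tot * outer(pm, pm)
  pref <- suppressWarnings(log2(sym / expected))
  pref[!is.finite(pref) & sym == 0] <- -Inf
  interacting <- is.finite(pref) & pref >= threshold
  structure(list(preference = pref, interacting = interacting,
                 threshold = threshold), class = "interaction_filter")
}

#' Write the preference filter as a TSV matrix
#'
#' @param filter an \code{interaction_filter}.
#' @param path output file.
#' @export
write_filter_tsv <- function(filter, path) {
  m <- filter$preference
  utils::write.table(cbind(atom_type = rownames(m), as.data.frame(m)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Does any atom type present in the source residue interact with the
# target type under the filter? NULL filter admits everything.
residue_admits_target <- function(filter, source_types, target_type) {
  if (is.null(filter)) return(TRUE)
  st <- intersect(unique(source_types), rownames(filter$interacting))
  if (length(st) == 0L || !(target_type %in% colnames(filter$interacting)))
    return(FALSE)
  any(filter$interacting[st, target_type])
}

# Deposit one residue's class-conditioned histogram into world-grid values
# by trilinear splatting (each transformed histogram count is shared among
# the 8 surrounding cells), which keeps maps stable under rigid rotation
# of the query. Weight 1 per covered residue: the histogram is normalized
# before deposition, making the map invariant to the total count scale of
# the statistics library.
deposit_residue <- function(values, grid, stats, key, target_type, frame) {
  h <- stats$hist[[key]][[target_type]]
  if (is.null(h) || sum(h) == 0) return(NULL)
  nz <- which(h > 0)
  off <- bin_to_offset(nz, stats$spec)
  world <- to_world(frame, off)
  w <- h[nz] / sum(h)
  u <- sweep(world, 2L, grid$origin, "-") / grid$spacing
  i0 <- floor(u)
  f <- u - i0
  any_dep <- FALSE
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ii <- i0[, 1L] + dx; jj <- i0[, 2L] + dy; kk <- i0[, 3L] + dz
    wt <- w * (if (dx) f[, 1L] else 1 - f[, 1L]) *
      (if (dy) f[, 2L] else 1 - f[, 2L]) *
      (if (dz) f[, 3L] else 1 - f[, 3L])
    ok <- ii >= 0 & ii < grid$dim[1L] & jj >= 0 & jj < grid$dim[2L] &
      kk >= 0 & kk < grid$dim[3L] & wt > 0
    if (!any(ok)) next
    idx <- kk[ok] * grid$dim[1L] * grid$dim[2L] + jj[ok] * grid$dim[1L] +
      ii[ok] + 1L
    agg <- rowsum(wt[ok], idx)
    values[as.integer(rownames(agg))] <-
      values[as.integer(rownames(agg))] + agg[, 1L]
    any_dep <- TRUE
  }
  if (!any_dep) return(NULL)
  values
}

#' Build a probability density map of one atom type around a query
#'
#' Every query residue with computable backbone frame deposits its
#' class-conditioned, filter-restricted offset histogram into the grid;
#' the accumulated map is normalized to sum 1 over the grid. Residues (or
#' whole queries) not covered by the statistics contribute a uniform prior,
#' so a query with no covered residue yields a uniform map.
#'
#' @param query atom-typed \code{structure3d}.
#' @param target_atom_type atom type code (or \code{"WATER_O"}).
#' @param stats a \code{contact_statistics}.
#' @param filter optional \code{interaction_filter}.
#' @param grid optional \code{grid3d}; default covers the query plus the
#'   statistics shell.
#' @param p_ref reference probability; cells below it are stored as 0.
#' @param smoothing passes of the separable (1,2,1)/4 box kernel applied
#'   to the accumulated map (damps grid-resampling noise; 0 disables).
#' @return A \code{grid3d} with attributes \code{p_ref} and
#'   \code{atom_type}; values are non-negative and sum to 1.
#' @export
build_pdm <- function(query, target_atom_type, stats, filter = NULL,
                      grid = NULL, p_ref = 1e-10, smoothing = 1L) {
  stopifnot(inherits(query, "structure3d"), inherits(stats, "contact_statistics"))
  if (all(is.na(query$atoms$atom_type)))
    query <- assign_atom_types(query)
  if (is.null(grid))
    grid <- grid_for_structure(query, spacing = stats$spacing,
                               margin = stats$shell_max + 2)
  values <- numeric(prod(grid$dim))
  n_uniform <- 0L
  res <- residue_table(query)
  res <- res[res$resname %in% AA3, , drop = FALSE]
  axyz <- atom_xyz(query)
  for (b in seq_len(nrow(res))) {
    sel <- residue_sel(query, res$chain[b], res$resid[b])
    nm <- query$atoms$name[sel]
    if (!all(c("N", "CA", "C") %in% nm)) next
    bb <- axyz[sel, , drop = FALSE]
    rownames(bb) <- nm
    cls <- classify_conformation(query, res$chain[b], res$resid[b])
    key <- paste(res$resname[b], cls, sep = "|")
    if (!residue_admits_target(filter, query$atoms$atom_type[sel],
                               target_atom_type))
      next
    fr <- local_frame(bb["N", ], bb["CA", ], bb["C", ])
    upd <- deposit_residue(values, grid, stats, key, target_atom_type, fr)
    if (is.null(upd)) n_uniform <- n_uniform + 1L else values <- upd
  }
  ncell <- length(values)
  if (n_uniform > 0L) values <- values + n_uniform / ncell
  if (sum(values) == 0) values <- rep(1, ncell)
  arr <- array(values, grid$dim)
  for (pass in seq_len(smoothing)) arr <- smooth_121(arr)
  values <- as.vector(arr)
  values <- values / sum(values)
  values[values < p_ref] <- 0
  s <- sum(values)
  if (s > 0) values <- values / s
  g <- grid3d(grid$origin, grid$spacing, grid$dim, array(values, grid$dim))
  attr(g, "p_ref") <- p_ref
  attr(g, "atom_type") <- target_atom_type
  g
}

# separable (1,2,1)/4 kernel along each axis with reflecting boundaries:
# exactly mass-preserving and leaves a uniform field uniform
smooth_121 <- function(arr) {
  d <- dim(arr)
  for (ax in 1:3) {
    sl_lo <- slice.index(arr, ax) > 1L
    sl_hi <- slice.index(arr, ax) < d[ax]
    up <- array(0, d)
    dn <- array(0, d)
    up[sl_lo] <- arr[sl_hi]
    up[!sl_lo] <- arr[!sl_lo]
    dn[sl_hi] <- arr[sl_lo]
    dn[!sl_hi] <- arr[!sl_hi]
    arr <- 0.5 * arr + 0.25 * (up + dn)
  }
  arr
}

#' Build the water-oxygen PDM around a query
#'
#' As \code{\link{build_pdm}} with target \code{WATER_O}; if the statistics
#' library contains no water contacts the map is uniform with a warning.
#'
#' @inheritParams build_pdm
#' @return A \code{grid3d}.
#' @export
build_water_pdm <- function(query, stats, filter = NULL, grid = NULL,
                            p_ref = 1e-10) {
  has_water <- any(vapply(stats$hist, function(h) "WATER_O" %in% names(h),
                          logical(1)))
  if (!has_water)
    warning("statistics library contains no water contacts; map is uniform")
  build_pdm(query, "WATER_O", stats, filter = filter, grid = grid,
            p_ref = p_ref)
}

# Water PDM generated by a single placed residue of known type/class
# (used for the per-rotamer antibody-side hydration map). When the
# statistics do not cover (restype, class) the backbone-keyed Ala
# histogram of the same class is used; only when that is also absent does
# the map fall back to uniform.
build_water_pdm_for_residue <- function(restype, class, frame, stats,
                                        grid, p_ref = 1e-10, smoothing = 1L) {
  values <- numeric(prod(grid$dim))
  key <- paste(restype, class, sep = "|")
  upd <- deposit_residue(values, grid, stats, key, "WATER_O", frame)
  if (is.null(upd))
    upd <- deposit_residue(values, grid, stats, paste("ALA", class, sep = "|"),
                           "WATER_O", frame)
  if (is.null(upd)) values <- rep(1, length(values)) else values <- upd
  arr <- array(values, grid$dim)
  for (pass in seq_len(smoothing)) arr <- smooth_121(arr)
  values <- as.vector(arr)
  values <- values / sum(values)
  values[values < p_ref] <- 0
  s <- sum(values)
  if (s > 0) values <- values / s
  g <- grid3d(grid$origin, grid$spacing, grid$dim, array(values, grid$dim))
  attr(g, "p_ref") <- p_ref
  g
}

#' Average PDM value over an atom's van der Waals volume
#'
#' Mean of the map cells whose centers fall inside the atom's vdW sphere;
#' 0 when no cell center is enclosed. An atom entirely outside the grid
#' returns 0 with a warning.
#'
#' @param map a \code{grid3d}.
#' @param center numeric 3-vector, atom position.
#' @param vdw atom van der Waals radius.
#' @return Scalar AVE value.
#' @export
average_pdm_over_atom <- function(map, center, vdw) {
  lo <- map$origin
  hi <- map$origin + (map$dim - 1L) * map$spacing
  if (any(center + vdw < lo) || any(center - vdw > hi)) {
    warning("atom lies outside the map grid; AVE = 0")
    return(0)
  }
  idx <- cells_within_radius(map, center, vdw)
  if (length(idx) == 0L) return(0)
  mean(map$values[idx])
}

#' Hydration-pattern score per atom
#'
#' For each atom, the sum of water-map values within \code{shell} of the
#' atom center; large values flag well-hydrated surface atoms, small values
#' sparsely hydrated (hot-spot-like) ones.
#'
#' @param s a \code{structure3d}.
#' @param water_map water-oxygen \code{grid3d} built for \code{s}.
#' @param shell shell radius in Angstrom.
#' @return Numeric vector, one non-negative score per atom.
#' @export
hydration_pattern_score <- function(s, water_map, shell = 4.0) {
  xyz <- atom_xyz(s)
  out <- numeric(nrow(xyz))
  for (i in seq_len(nrow(xyz))) {
    idx <- cells_within_radius(water_map, xyz[i, ], shell)
    out[i] <- if (length(idx)) sum(water_map$values[idx]) else 0
  }
  out
}
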