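# Synthetic fixtures: toy complexes, contact-statistics libraries with
# planted geometry, simulated phage-display selections and planted
# feature/label tables. Every generator is deterministic per seed and
# returns a manifest sufficient to recompute the expected values asserted
# in tests.

ideal_backbone_chain <- function(n_residues, resnames, chain_id,
                                 phi = -120, psi = 130, start_serial = 1L) {
  stopifnot(n_residues >= 1L)
  if (length(resnames) == 1L) resnames <- rep(resnames, n_residues)
  stopifnot(length(resnames) == n_residues)
  n <- c(0, 0, 0)
  ca <- c(1.458, 0, 0)
  cc <- place_atom(c(0, 1, 0), n, ca, 1.525, 111.2, -55)
  rows <- list()
  add_atom <- function(res, name, xyz, element) {
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = 0L, name = name, resname = resnames[res],
      chain = chain_id, resno = res, ins = "", element = element,
      x = xyz[1L], y = xyz[2L], z = xyz[3L],
      vdw = vdw_radius_for(element), atom_type = NA_character_,
      stringsAsFactors = FALSE)
  }
  for (r in seq_len(n_residues)) {
    add_atom(r, "N", n, "N")
    add_atom(r, "CA", ca, "C")
    add_atom(r, "C", cc, "C")
    if (r < n_residues) {
      n_next <- place_atom(n, ca, cc, 1.329, 116.2, psi)
      o <- place_atom(n, ca, cc, 1.231, 120.8, psi + 180)
      add_atom(r, "O", o, "O")
      ca_next <- place_atom(ca, cc, n_next, 1.458, 121.7, 180)
      c_next <- place_atom(cc, n_next, ca_next, 1.525, 111.2, phi)
      if (toupper(resnames[r]) != "GLY")
        add_atom(r, "CB", ideal_cb(n, ca, cc), "C")
      n <- n_next; ca <- ca_next; cc <- c_next
    } else {
      o <- place_atom(n, ca, cc, 1.231, 120.8, psi + 180)
      add_atom(r, "O", o, "O")
      if (toupper(resnames[r]) != "GLY")
        add_atom(r, "CB", ideal_cb(n, ca, cc), "C")
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- start_serial + seq_len(nrow(atoms)) - 1L
  atoms
}

#' Generate a toy two-chain complex
#'
#' Two ideal-geometry polypeptide chains facing each other across a gap
#' along z. Deterministic per seed (the seed drives a small coordinate
#' jitter emulating experimental noise; jitter_sd = 0 gives exact ideal
#' geometry).
#'
#' @param seed integer seed.
#' @param n_residues_a,n_residues_b chain lengths.
#' @param interface_gap closest heavy-atom distance between the chains in
#'   Angstrom.
#' @param resnames_a,resnames_b residue names (recycled).
#' @param jitter_sd coordinate noise (Angstrom).
#' @return list with \code{structure} (a \code{structure3d}) and
#'   \code{manifest} (seed, sizes, atom counts per chain).
#' @export
make_toy_complex <- function(seed = 1L, n_residues_a = 6L, n_residues_b = 6L,
                             interface_gap = 4.0,
                             resnames_a = "ALA", resnames_b = "ALA",
                             jitter_sd = 0) {
  set.seed(seed)
  a <- ideal_backbone_chain(n_residues_a, resnames_a, "A")
  b <- ideal_backbone_chain(n_residues_b, resnames_b, "B",
                            start_serial = nrow(a) + 1L)
  # flip chain B and set the z separation to the requested gap
  b$z <- -b$z
  b$x <- -b$x + mean(range(a$x)) + mean(range(b$x))
  b$z <- b$z - (max(b$z) - min(a$z)) - interface_gap
  # the z offset bounds the gap from below; iterate to the true closest
  # heavy-atom distance
  axyz <- as.matrix(a[, c("x", "y", "z")])
  for (it in 1:3) {
    bxyz <- as.matrix(b[, c("x", "y", "z")])
    dmin <- min_cross_dist(axyz, bxyz)
    if (abs(dmin - interface_gap) < 0.05) break
    b$z <- b$z + (dmin - interface_gap)
  }
  if (jitter_sd > 0) {
    for (col in c("x", "y", "z")) {
      a[[col]] <- a[[col]] + stats::rnorm(nrow(a), 0, jitter_sd)
      b[[col]] <- b[[col]] + stats::rnorm(nrow(b), 0, jitter_sd)
    }
  }
  s <- new_structure3d(rbind(a, b), metadata = list(source = "make_toy_complex",
                                                    seed = seed))
  list(structure = s,
       manifest = list(seed = seed, n_residues_a = n_residues_a,
                       n_residues_b = n_residues_b,
                       interface_gap = interface_gap,
                       n_atoms = nrow(s$atoms),
                       n_atoms_a = nrow(a), n_atoms_b = nrow(b)))
}

#' Generate a structure library with a planted contact geometry
#'
#' Each structure holds a short ideal chain whose middle residue is the
#' source, one planted target atom at a fixed offset in the source's
#' N-CA-C local frame, and a randomized cage of decoy carbon atoms
#' surrounding the source (burying it and feeding decoy contacts).
#'
#' @param seed integer seed.
#' @param n_structures library size.
#' @param planted_offset 3-vector, target-atom offset in the source local
#'   frame (Angstrom).
#' @param target \code{list(resname, atom)} of the planted atom (default
#'   Ser OG, a hydroxyl oxygen; use \code{list(resname = "HOH",
#'   atom = "O")} to plant hydration statistics).
#' @param source_restype residue-type label of the source residue (the
#'   chain is backbone-only, so the label keys the statistics without
#'   changing geometry).
#' @param n_cage decoy cage atoms per structure.
#' @param cage_radius range of cage radii from the source CA.
#' @return list with \code{structures} (list of \code{structure3d}) and
#'   \code{manifest} (planted offset, source key data, cage counts).
#' @export
make_structure_library <- function(seed = 1L, n_structures = 5L,
                                   planted_offset = c(3.0, 0, 0),
                                   target = list(resname = "SER", atom = "OG"),
                                   source_restype = "ALA",
                                   n_cage = 60L, cage_radius = c(4.5, 6.0)) {
  set.seed(seed)
  out <- vector("list", n_structures)
  src_class <- NA_character_
  for (s in seq_len(n_structures)) {
    a <- ideal_backbone_chain(3L, "ALA", "A")
    a$resname[a$resno == 2L] <- toupper(source_restype)
    sel <- which(a$resno == 2L)
    bb <- as.matrix(a[sel, c("x", "y", "z")])
    rownames(bb) <- a$name[sel]
    fr <- local_frame(bb["N", ], bb["CA", ], bb["C", ])
    tpos <- drop(to_world(fr, planted_offset))
    el <- substr(target$atom, 1L, 1L)
    planted <- data.frame(serial = nrow(a) + 1L, name = target$atom,
                          resname = target$resname, chain = "B",
                          resno = 10L, ins = "", element = el,
                          x = tpos[1L], y = tpos[2L], z = tpos[3L],
                          vdw = vdw_radius_for(el),
                          atom_type = NA_character_, stringsAsFactors = FALSE)
    u <- matrix(stats::rnorm(3L * n_cage), ncol = 3L)
    u <- u / sqrt(rowSums(u^2))
    rad <- stats::runif(n_cage, cage_radius[1L], cage_radius[2L])
    cage_xyz <- sweep(u * rad, 2L, bb["CA", ], "+")
    cage <- data.frame(serial = nrow(a) + 1L + seq_len(n_cage), name = "CB",
                       resname = "ALA", chain = "C",
                       resno = 100L + seq_len(n_cage), ins = "",
                       element = "C", x = cage_xyz[, 1L], y = cage_xyz[, 2L],
                       z = cage_xyz[, 3L], vdw = vdw_radius_for("C"),
                       atom_type = NA_character_, stringsAsFactors = FALSE)
    st <- new_structure3d(rbind(a, planted, cage),
                          metadata = list(source = "make_structure_library",
                                          seed = seed, index = s))
    if (s == 1L)
      src_class <- classify_conformation(st, "A", "2")
    out[[s]] <- st
  }
  list(structures = out,
       manifest = list(seed = seed, n_structures = n_structures,
                       planted_offset = planted_offset,
                       source = list(resname = toupper(source_restype),
                                     chain = "A", resid = "2",
                                     class = src_class),
                       target = target, n_cage = n_cage))
}

#' Simulate a phage-display selection dataset
#'
#' Sequences are drawn position-independently with probability
#' proportional to p_i * enrichment_ji over the NNK background p.
#'
#' @param seed integer seed.
#' @param positions window position labels.
#' @param enrichment matrix (positions x 20, one-letter columns) of
#'   enrichment factors (> 0); default all 1 (pure background).
#' @param M number of selected sequences.
#' @param p background probabilities.
#' @return list with \code{sequences}, \code{positions} and
#'   \code{manifest} (exact draw tallies and sampling probabilities).
#' @export
simulate_selection <- function(seed = 1L, positions = paste0("pos", 1:5),
                               enrichment = NULL, M = 200L,
                               p = nnk_background()) {
  set.seed(seed)
  k <- length(positions)
  if (is.null(enrichment))
    enrichment <- matrix(1, k, 20L, dimnames = list(positions, AA1))
  stopifnot(all(enrichment > 0), nrow(enrichment) == k, M >= 1L)
  if (is.null(colnames(enrichment))) colnames(enrichment) <- AA1
  prob <- sweep(enrichment, 2L, p[colnames(enrichment)], "*")
  prob <- prob / rowSums(prob)
  draws <- matrix("", M, k)
  for (j in seq_len(k))
    draws[, j] <- sample(colnames(prob), M, replace = TRUE, prob = prob[j, ])
  sequences <- apply(draws, 1L, paste0, collapse = "")
  tallies <- t(apply(draws, 2L, function(col) table(factor(col, levels = AA1))))
  dimnames(tallies) <- list(positions, AA1)
  list(sequences = sequences, positions = positions,
       manifest = list(seed = seed, M = M, tallies = tallies,
                       probabilities = prob))
}

#' Planted feature/label tables for the preference-model pipeline
#'
#' X, Y, Z are drawn from standard normals; the label deltaW is the
#' indicator of a logistic score of the features (plus Gaussian noise)
#' exceeding 1/2, i.e. of the linear score being non-negative. W is set to
#' the noiseless linear score so signs are consistent with deltaW at
#' noise_sd = 0.
#'
#' @param seed integer seed.
#' @param n_positions number of interface positions.
#' @param weights named vector \code{c(x=, y=, z=)} of generating slopes.
#' @param intercept generating intercept.
#' @param noise_sd label-noise standard deviation on the linear score.
#' @param margin optional score margin: linear scores are resampled until
#'   |score| >= margin, producing a consistently learnable rule (used by
#'   the noiseless-consistency checks; 0 disables).
#' @return list with \code{score_table}, \code{preference_table} (long
#'   data.frames) and \code{manifest} (generating weights and exact
#'   labels).
#' @export
make_planted_model_tables <- function(seed = 1L, n_positions = 24L,
                                      weights = c(x = 2, y = -1.5, z = 1),
                                      intercept = 0, noise_sd = 0,
                                      margin = 0) {
  set.seed(seed)
  positions <- sprintf("pos%02d", seq_len(n_positions))
  n <- n_positions * 20L
  X <- stats::rnorm(n); Y <- stats::rnorm(n); Z <- stats::rnorm(n)
  eta <- intercept + weights[["x"]] * X + weights[["y"]] * Y +
    weights[["z"]] * Z
  if (margin > 0 && any(weights != 0)) {
    for (it in 1:100) {
      bad <- abs(eta) < margin
      if (!any(bad)) break
      nb <- sum(bad)
      X[bad] <- stats::rnorm(nb); Y[bad] <- stats::rnorm(nb)
      Z[bad] <- stats::rnorm(nb)
      eta[bad] <- intercept + weights[["x"]] * X[bad] +
        weights[["y"]] * Y[bad] + weights[["z"]] * Z[bad]
    }
  }
  eta_noisy <- eta + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  deltaW <- (eta_noisy >= 0) * 1L
  score_table <- data.frame(position = rep(positions, 20L),
                            aa = rep(AA1, each = n_positions),
                            X = X, Y = Y, Z = Z, stringsAsFactors = FALSE)
  preference_table <- data.frame(position = score_table$position,
                                 aa = score_table$aa,
                                 W = eta, deltaW = deltaW,
                                 stringsAsFactors = FALSE)
  list(score_table = score_table, preference_table = preference_table,
       manifest = list(seed = seed, weights = weights, intercept = intercept,
                       noise_sd = noise_sd, n_positions = n_positions))
}

#' Write a fixture bundle to a directory
#'
#' Writes structures as PDB, sequences as FASTA/TSV and the manifest as a
#' plain-text key-value file.
#'
#' @param fixture a generator result (list with manifest).
#' @param dir output directory (created if needed).
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(fixture$structure))
    write_structure_pdb(fixture$structure, file.path(dir, "complex.pdb"))
  if (!is.null(fixture$structures))
    for (i in seq_along(fixture$structures))
      write_structure_pdb(fixture$structures[[i]],
                          file.path(dir, sprintf("lib_%03d.pdb", i)))
  if (!is.null(fixture$sequences))
    writeLines(paste0(">seq", seq_along(fixture$sequences), "\n",
                      fixture$sequences),
               file.path(dir, "selection.fasta"))
  mf <- fixture$manifest
  lines <- character(0)
  flat <- function(prefix, x) {
    if (is.list(x)) {
      for (nm in names(x)) flat(paste0(prefix, nm, "."), x[[nm]])
    } else {
      lines <<- c(lines, paste0(sub("\\.$", "", prefix), " = ",
                                paste(format(x), collapse = " ")))
    }
  }
  flat("", mf)
  writeLines(lines, file.path(dir, "manifest.txt"))
  invisible(dir)
}
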