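# Shrake-Rupley solvent accessible surface area.
#
# Deterministic golden-spiral quadrature on each atom's solvent-expanded
# sphere; a point is accessible when it lies outside every neighbouring
# atom's expanded sphere. Defaults: probe 1.4 Angstrom, 960 points.

golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' @param s a \code{structure3d}.
#' @param probe_radius probe sphere radius in Angstrom.
#' @param n_points quadrature points per atom (>= 92).
#' @return list with \code{atom} (numeric vector, Angstrom^2) and
#'   \code{residue} (data.frame chain, resid, resname, sasa).
#' @export
compute_sasa <- function(s, probe_radius = 1.4, n_points = 960L) {
  stopifnot(inherits(s, "structure3d"))
  if (nrow(s$atoms) == 0L) stop("empty structure")
  if (n_points < 92L) stop("n_points must be >= 92")
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  xyz <- atom_xyz(s)
  r <- s$atoms$vdw + probe_radius
  n <- nrow(xyz)
  sph <- golden_spiral_points(n_points)
  out <- numeric(n)
  # neighbour search via cutoff on pairwise distances, chunked by atom
  maxr <- max(r)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1L] - xyz[i, 1L])^2 + (xyz[, 2L] - xyz[i, 2L])^2 +
      (xyz[, 3L] - xyz[i, 3L])^2
    nb <- which(d2 < (r[i] + maxr)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (r[i] + r[nb])^2]
    pts <- sph * r[i]
    pts <- sweep(pts, 2L, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- (pts[acc, 1L, drop = FALSE] - xyz[j, 1L])^2 +
        (pts[acc, 2L, drop = FALSE] - xyz[j, 2L])^2 +
        (pts[acc, 3L, drop = FALSE] - xyz[j, 3L])^2
      # points exactly on a neighbour's expanded sphere (degenerate
      # coincident-sphere case) are owned by the lower-index atom, so a
      # shared surface is counted once
      eps <- 1e-7 * r[j]^2
      buried <- dj < r[j]^2 - eps | (abs(dj - r[j]^2) <= eps & j < i)
      acc[acc] <- !buried
    }
    out[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  key <- paste(s$atoms$chain, s$atoms$resid, sep = "|")
  agg <- tapply(out, key, sum)
  rt <- residue_table(s)
  residue <- data.frame(chain = rt$chain, resid = rt$resid,
                        resname = rt$resname,
                        sasa = as.numeric(agg[paste(rt$chain, rt$resid, sep = "|")]),
                        stringsAsFactors = FALSE)
  list(atom = out, residue = residue)
}
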