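# Regular 3-D grids: construction, occupancy masks and OpenDX scalar I/O.
#
# A grid3d is list(origin = numeric(3), spacing = scalar Angstrom,
# dim = integer(3), values = 3-D array). Cell (i,j,k) has its center at
# origin + (c(i,j,k) - 1) * spacing.

#' Construct a regular 3-D grid
#'
#' @param origin coordinates of the first cell center.
#' @param spacing cell edge length in Angstrom (> 0).
#' @param dim integer vector of three cell counts.
#' @param values optional array of cell values (default all zero).
#' @return A \code{grid3d} object.
#' @export
grid3d <- function(origin, spacing, dim, values = NULL) {
  if (spacing <= 0) stop("grid spacing must be > 0")
  dim <- as.integer(dim)
  stopifnot(length(origin) == 3L, length(dim) == 3L, all(dim >= 1L))
  if (is.null(values)) values <- array(0, dim = dim)
  stopifnot(all(base::dim(values) == dim))
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dim = dim, values = values), class = "grid3d")
}

#' Grid covering a structure's bounding box plus a margin
#'
#' @param s a \code{structure3d}.
#' @param spacing cell size in Angstrom.
#' @param margin extra space beyond the bounding box on every side.
#' @return A \code{grid3d} of zeros.
#' @export
grid_for_structure <- function(s, spacing = 1.0, margin = 8.0) {
  xyz <- atom_xyz(s)
  lo <- apply(xyz, 2L, min) - margin
  hi <- apply(xyz, 2L, max) + margin
  dim <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  grid3d(lo, spacing, dim)
}

# n x 3 matrix of all cell centers, in array order (first index fastest).
grid_centers <- function(g) {
  ii <- seq_len(g$dim[1L]) - 1L
  jj <- seq_len(g$dim[2L]) - 1L
  kk <- seq_len(g$dim[3L]) - 1L
  cbind(g$origin[1L] + g$spacing * rep(ii, times = g$dim[2L] * g$dim[3L]),
        g$origin[2L] + g$spacing * rep(rep(jj, each = g$dim[1L]), times = g$dim[3L]),
        g$origin[3L] + g$spacing * rep(kk, each = g$dim[1L] * g$dim[2L]))
}

# Map points (n x 3) to linear cell indices; NA when outside the grid.
grid_cell_index <- function(g, xyz) {
  xyz <- matrix(xyz, ncol = 3L)
  idx <- sweep(xyz, 2L, g$origin, "-") / g$spacing
  ijk <- round(idx) + 1
  ok <- ijk[, 1L] >= 1 & ijk[, 1L] <= g$dim[1L] &
    ijk[, 2L] >= 1 & ijk[, 2L] <= g$dim[2L] &
    ijk[, 3L] >= 1 & ijk[, 3L] <= g$dim[3L]
  out <- rep(NA_integer_, nrow(xyz))
  out[ok] <- as.integer((ijk[ok, 3L] - 1) * g$dim[1L] * g$dim[2L] +
                          (ijk[ok, 2L] - 1) * g$dim[1L] + ijk[ok, 1L])
  out
}

# Linear indices of cells whose centers lie within `radius` of `center`.
cells_within_radius <- function(g, center, radius) {
  lo <- floor((center - radius - g$origin) / g$spacing) + 1
  hi <- ceiling((center + radius - g$origin) / g$spacing) + 1
  lo <- pmax(lo, 1); hi <- pmin(hi, g$dim)
  if (any(lo > hi)) return(integer(0))
  ii <- seq.int(lo[1L], hi[1L]); jj <- seq.int(lo[2L], hi[2L])
  kk <- seq.int(lo[3L], hi[3L])
  ctr <- expand.grid(i = ii, j = jj, k = kk)
  cx <- g$origin[1L] + (ctr$i - 1) * g$spacing
  cy <- g$origin[2L] + (ctr$j - 1) * g$spacing
  cz <- g$origin[3L] + (ctr$k - 1) * g$spacing
  d2 <- (cx - center[1L])^2 + (cy - center[2L])^2 + (cz - center[3L])^2
  sel <- d2 <= radius^2
  as.integer((ctr$k[sel] - 1) * g$dim[1L] * g$dim[2L] +
               (ctr$j[sel] - 1) * g$dim[1L] + ctr$i[sel])
}

#' Boolean molecular-volume mask of a structure on a grid
#'
#' A cell is occupied when its center lies within the van der Waals radius
#' (optionally expanded by \code{expand}) of any atom.
#'
#' @param s a \code{structure3d}.
#' @param grid a \code{grid3d} covering the structure.
#' @param expand radial expansion in Angstrom added to every vdW radius.
#' @return A \code{grid3d} whose values are 0/1.
#' @export
volume_mask <- function(s, grid, expand = 0) {
  stopifnot(inherits(s, "structure3d"), inherits(grid, "grid3d"))
  vals <- array(0, dim = grid$dim)
  xyz <- atom_xyz(s)
  r <- s$atoms$vdw + expand
  for (i in seq_len(nrow(xyz))) {
    idx <- cells_within_radius(grid, xyz[i, ], r[i])
    vals[idx] <- 1
  }
  grid3d(grid$origin, grid$spacing, grid$dim, vals)
}

#' Write a grid in OpenDX scalar format
#'
#' @param g a \code{grid3d}.
#' @param path output file path.
#' @export
write_dx <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- g$dim
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1L], d[2L], d[3L]),
    sprintf("origin %.6f %.6f %.6f", g$origin[1L], g$origin[2L], g$origin[3L]),
    sprintf("delta %.6f 0 0", g$spacing),
    sprintf("delta 0 %.6f 0", g$spacing),
    sprintf("delta 0 0 %.6f", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1L], d[2L], d[3L]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # DX order: z varies fastest, x slowest
  vals <- g$values[cbind(rep(seq_len(d[1L]), each = d[2L] * d[3L]),
                         rep(rep(seq_len(d[2L]), each = d[3L]), times = d[1L]),
                         rep(seq_len(d[3L]), times = d[1L] * d[2L]))]
  n <- length(vals)
  pad <- (3 - n %% 3) %% 3
  vals <- c(vals, rep(NA_real_, pad))
  m <- matrix(vals, ncol = 3L, byrow = TRUE)
  lines <- apply(m, 1L, function(row) paste(formatC(row[!is.na(row)],
                                                    format = "e", digits = 6),
                                            collapse = " "))
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar grid
#'
#' Supports the regular-grid subset written by \code{\link{write_dx}}.
#'
#' @param path DX file path.
#' @return A \code{grid3d}.
#' @export
read_dx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  gp <- grep("class gridpositions counts", lines, value = TRUE)[1L]
  dim <- as.integer(strsplit(trimws(sub(".*counts", "", gp)), "\\s+")[[1L]])
  org <- as.numeric(strsplit(trimws(sub("^origin", "",
                                        grep("^origin", lines, value = TRUE)[1L])), "\\s+")[[1L]])
  deltas <- grep("^delta", lines, value = TRUE)
  sp <- as.numeric(strsplit(trimws(sub("^delta", "", deltas[1L])), "\\s+")[[1L]])[1L]
  start <- grep("data follows", lines)[1L] + 1L
  end <- grep("^attribute", lines)
  end <- if (length(end)) end[1L] - 1L else length(lines)
  vals <- as.numeric(unlist(strsplit(trimws(lines[start:end]), "\\s+")))
  vals <- vals[!is.na(vals)]
  stopifnot(length(vals) == prod(dim))
  arr <- array(0, dim = dim)
  arr[cbind(rep(seq_len(dim[1L]), each = dim[2L] * dim[3L]),
            rep(rep(seq_len(dim[2L]), each = dim[3L]), times = dim[1L]),
            rep(seq_len(dim[3L]), times = dim[1L] * dim[2L]))] <- vals
  grid3d(org, sp, dim, arr)
}
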