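# Synthetic OPC point patterns: homogeneous Poisson background with
# hyperdense Poisson disc foci, plus grid-tiling into ROIs.

#' Generate a synthetic OPC point pattern with hyperdense foci
#'
#' Cells are placed as a homogeneous Poisson process of intensity
#' `bg_density` over a square region, plus independent Poisson "excess"
#' points inside each focal disc so that the total intensity inside a focus
#' equals that focus's `density`. The foci footprints are retained as the
#' ground-truth hyperdensity mask.
#'
#' @param region_area Region area, mm^2; the region is the square
#'   `[0, sqrt(region_area)]^2`.
#' @param bg_density Background intensity, cells per mm^2 (>= 0).
#' @param foci List of foci, each `list(center = c(x, y), radius = r,
#'   density = rho)` with `rho > bg_density`; every focus must lie entirely
#'   inside the region. Overlapping foci are allowed.
#' @param seed Master integer seed (uses the `"foci"` substream).
#' @return An `opc_pattern`: list with `points` (data frame `x`, `y`,
#'   `in_focus`), `region_side`, `region_area`, `bg_density`, `foci`.
#' @export
generate_opc_pattern <- function(region_area = 1, bg_density = 150,
                                 foci = list(), seed = 1L) {
  stopifnot(region_area > 0, bg_density >= 0)
  side <- sqrt(region_area)
  for (f in foci) {
    if (f$density <= max(bg_density, 0)) stop("focus density must exceed bg_density")
    if (f$radius <= 0) stop("focus radius must be > 0")
    if (f$center[1] - f$radius < 0 || f$center[1] + f$radius > side ||
        f$center[2] - f$radius < 0 || f$center[2] + f$radius > side)
      stop("focus lies (partly) outside the region")
  }
  pts <- with_seed(substream_seed(seed, "foci"), {
    n_bg <- stats::rpois(1L, bg_density * region_area)
    x <- stats::runif(n_bg, 0, side)
    y <- stats::runif(n_bg, 0, side)
    for (f in foci) {
      excess <- f$density - bg_density
      n_f <- stats::rpois(1L, excess * pi * f$radius^2)
      r <- f$radius * sqrt(stats::runif(n_f))
      th <- stats::runif(n_f, 0, 2 * pi)
      x <- c(x, f$center[1] + r * cos(th))
      y <- c(y, f$center[2] + r * sin(th))
    }
    data.frame(x = x, y = y)
  })
  pts$in_focus <- in_any_focus(pts$x, pts$y, foci)
  structure(list(points = pts, region_side = side, region_area = region_area,
                 bg_density = bg_density, foci = foci, seed = seed),
            class = "opc_pattern")
}

in_any_focus <- function(x, y, foci) {
  hit <- rep(FALSE, length(x))
  for (f in foci)
    hit <- hit | ((x - f$center[1])^2 + (y - f$center[2])^2 <= f$radius^2)
  hit
}

#' Area fraction of the ground-truth hyperdensity mask
#'
#' Fraction of the region covered by the union of focal discs. Disjoint foci
#' are summed analytically (`pi r^2 / A`); overlapping foci fall back to
#' numerical integration on a fine grid of cell centers.
#'
#' @param pattern An `opc_pattern`.
#' @param n_grid Grid resolution per side for the overlap fallback.
#' @return Scalar fraction in `[0, 1]`.
#' @export
focus_area_fraction <- function(pattern, n_grid = 1024L) {
  foci <- pattern$foci
  if (!length(foci)) return(0)
  overlap <- FALSE
  if (length(foci) > 1) {
    for (i in seq_len(length(foci) - 1L)) for (j in (i + 1L):length(foci)) {
      dd <- sqrt(sum((foci[[i]]$center - foci[[j]]$center)^2))
      if (dd < foci[[i]]$radius + foci[[j]]$radius) overlap <- TRUE
    }
  }
  if (!overlap)
    return(sum(vapply(foci, function(f) pi * f$radius^2, numeric(1))) /
             pattern$region_area)
  g <- (seq_len(n_grid) - 0.5) / n_grid * pattern$region_side
  xx <- rep(g, times = n_grid)
  yy <- rep(g, each = n_grid)
  mean(in_any_focus(xx, yy, foci))
}

#' Tile a point pattern into square ROIs with cell counts
#'
#' Lays a regular grid of square ROIs over the region and counts cells per
#' tile; each tile carries a ground-truth label (`in_focus`) stating whether
#' its center lies inside a focal disc.
#'
#' @param pattern An `opc_pattern`.
#' @param tile_size ROI side length, mm. The grid uses
#'   `floor(region_side / tile_size)` tiles per side; a sliver at the far
#'   edge may be left uncovered.
#' @return Data frame `roi_id`, `x_mm`, `y_mm` (tile centers), `area_mm2`,
#'   `cell_count`, `in_focus`.
#' @export
roi_grid_counts <- function(pattern, tile_size) {
  stopifnot(tile_size > 0, tile_size <= pattern$region_side)
  nt <- floor(pattern$region_side / tile_size)
  ix <- floor(pattern$points$x / tile_size)
  iy <- floor(pattern$points$y / tile_size)
  ok <- ix >= 0 & ix < nt & iy >= 0 & iy < nt
  tile <- ix[ok] * nt + iy[ok]
  counts <- tabulate(tile + 1L, nbins = nt * nt)
  id <- seq_len(nt * nt) - 1L
  cx <- (id %/% nt + 0.5) * tile_size
  cy <- (id %% nt + 0.5) * tile_size
  data.frame(roi_id = id + 1L, x_mm = cx, y_mm = cy,
             area_mm2 = tile_size^2, cell_count = counts,
             in_focus = in_any_focus(cx, cy, pattern$foci))
}
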