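# ROI hyperdensity classification, coverage, cell density and g-ratio.

#' Classify an ROI by its Pdgfra+ cell count
#'
#' Applies the focal-hyperdensity count rule: fewer than four cells marks a
#' non-hyperdensity ROI, more than six marks an OPC hyperdensity ROI, and
#' counts of four to six are indeterminate (excluded from contrasts but
#' counted in total area).
#'
#' @param cell_count Nonnegative integer count(s).
#' @return Character vector in `{"non_hyperdensity", "indeterminate",
#'   "hyperdensity"}`.
#' @examples
#' classify_roi(c(3, 5, 7))
#' @export
classify_roi <- function(cell_count) {
  if (!is.numeric(cell_count) || any(!is.finite(cell_count)) ||
      any(cell_count < 0) || any(cell_count != round(cell_count)))
    stop("cell_count must be nonnegative integer(s)")
  ifelse(cell_count < 4, "non_hyperdensity",
         ifelse(cell_count > 6, "hyperdensity", "indeterminate"))
}

#' Percent of a region covered by hyperdense areas
#'
#' @param hyperdense_areas Areas (same unit as `region_area`) of the
#'   hyperdense ROIs or mask components; indeterminate ROIs contribute to the
#'   denominator only and are simply not passed here.
#' @param region_area Total region area (> 0).
#' @return Coverage in percent, in `[0, 100]`.
#' @export
coverage_percent <- function(hyperdense_areas, region_area) {
  if (!is.numeric(region_area) || region_area <= 0)
    stop("region_area must be > 0")
  if (any(hyperdense_areas < 0)) stop("areas must be nonnegative")
  total <- sum(hyperdense_areas)
  if (total > region_area * (1 + 1e-12))
    stop("hyperdense area exceeds region area")
  100 * total / region_area
}

#' Cell density from a count (or point set) and an area
#'
#' @param cells A nonnegative count, or a data frame / matrix of point
#'   coordinates whose rows are counted.
#' @param area Area in mm^2 (> 0).
#' @return Cells per mm^2.
#' @export
cell_density <- function(cells, area) {
  if (!is.numeric(area) || area <= 0) stop("area must be > 0")
  n <- if (is.data.frame(cells) || is.matrix(cells)) nrow(cells)
       else as.numeric(cells)
  if (n < 0) stop("cell count must be nonnegative")
  n / area
}

#' g-ratio of myelinated fibers
#'
#' The g-ratio is the axonal diameter in its short axis divided by the
#' diameter of the entire fiber (axon plus myelin sheath) in the same axis;
#' lower values indicate thicker myelin relative to the axon.
#'
#' @param axon_diameter Axonal short-axis diameter(s), um (> 0).
#' @param fiber_diameter Whole-fiber diameter(s) in the same axis, um
#'   (>= axon).
#' @return Data frame `axon_diameter_um`, `fiber_diameter_um`, `g_ratio`
#'   with `g_ratio` in `(0, 1]`.
#' @export
g_ratio <- function(axon_diameter, fiber_diameter) {
  if (any(axon_diameter <= 0) || any(fiber_diameter <= 0))
    stop("diameters must be > 0")
  if (any(fiber_diameter < axon_diameter))
    stop("fiber diameter smaller than axon diameter (mis-measured pair)")
  data.frame(axon_diameter_um = axon_diameter,
             fiber_diameter_um = fiber_diameter,
             g_ratio = axon_diameter / fiber_diameter)
}
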