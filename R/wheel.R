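#' Construct a running-wheel geometry
#'
#' A wheel is described by the angular positions of its rungs and its
#' circumference. A `"regular"` wheel has equally spaced rungs; a `"complex"`
#' wheel has irregular spacing, obtained by removing a seeded random subset of
#' positions from a denser regular lattice (the physical construction of
#' complex wheels, where rungs are omitted to force skilled stepping).
#'
#' @param n_rungs Number of rungs present on the wheel (>= 2).
#' @param circumference Wheel circumference in meters (> 0).
#' @param pattern `"regular"` or `"complex"`.
#' @param seed Integer seed used to choose which lattice positions are kept
#'   for a complex wheel; ignored for regular wheels.
#' @param lattice For complex wheels, the size of the underlying regular
#'   lattice from which rungs are dropped (must be >= `n_rungs`).
#' @return An object of class `wheel_geometry`: a list with `n_rungs`,
#'   `rung_angles` (strictly increasing, in `[0, 2*pi)`), `circumference`
#'   and `pattern`.
#' @examples
#' make_wheel(38, 0.38, "regular")
#' make_wheel(22, 0.38, "complex", seed = 1)
#' @export
make_wheel <- function(n_rungs, circumference = 0.38,
                       pattern = c("regular", "complex"),
                       seed = 1L, lattice = 38L) {
  pattern <- match.arg(pattern)
  if (!is.numeric(n_rungs) || length(n_rungs) != 1L || n_rungs < 2 ||
      n_rungs != round(n_rungs))
    stop("invalid wheel geometry: n_rungs must be an integer >= 2")
  if (!is.numeric(circumference) || length(circumference) != 1L ||
      !is.finite(circumference) || circumference <= 0)
    stop("invalid wheel geometry: circumference must be > 0")
  n_rungs <- as.integer(n_rungs)
  if (pattern == "regular") {
    angles <- 2 * pi * (seq_len(n_rungs) - 1L) / n_rungs
  } else {
    if (lattice < n_rungs)
      stop("invalid wheel geometry: lattice must be >= n_rungs")
    keep <- with_seed(seed, sort(sample.int(lattice, n_rungs)))
    angles <- 2 * pi * (keep - 1L) / lattice
  }
  structure(
    list(n_rungs = n_rungs, rung_angles = angles,
         circumference = circumference, pattern = pattern),
    class = "wheel_geometry"
  )
}

#' @export
print.wheel_geometry <- function(x, ...) {
  cat(sprintf("<wheel_geometry> %s, %d rungs, circumference %.3f m\n",
              x$pattern, x$n_rungs, x$circumference))
  invisible(x)
}

validate_wheel <- function(wheel) {
  stopifnot(inherits(wheel, "wheel_geometry"))
  a <- wheel$rung_angles
  if (length(a) != wheel$n_rungs || any(diff(a) <= 0) ||
      any(a < 0) || any(a >= 2 * pi))
    stop("invalid wheel geometry: rung angles must be strictly increasing in [0, 2*pi)")
  invisible(wheel)
}
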