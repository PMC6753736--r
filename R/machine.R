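# Machine constants and test plans.

#' Nominal machine constants
#'
#' @param SAD source-to-axis distance in cm (nominal 100).
#' @param SDD source-to-detector distance in cm (nominal 180; 140 in the
#'   large-phantom configuration).
#' @param field_size radiation field size `c(width, height)` in cm at the
#'   isocentric plane (nominal 20 x 20).
#' @param epid_size physical EPID panel size `c(width, height)` in cm.
#' @return object of class `machine_constants`.
#' @export
machine_constants <- function(SAD = 100, SDD = 180, field_size = c(20, 20),
                              epid_size = c(43, 43)) {
  stopifnot(is.numeric(SAD), is.numeric(SDD), length(field_size) == 2L,
            length(epid_size) == 2L)
  if (!(SAD > 0 && SDD > SAD))
    stop("machine constants require 0 < SAD < SDD")
  if (any(field_size <= 0) || any(epid_size <= 0))
    stop("field and EPID sizes must be positive")
  structure(list(SAD = SAD, SDD = SDD, field_size = as.numeric(field_size),
                 epid_size = as.numeric(epid_size)),
            class = "machine_constants")
}

#' Evenly spaced gantry angles
#'
#' `n` angles spanning `[-180, 180]` degrees inclusive (the two endpoints are
#' the same physical gantry position, imaged twice).
#'
#' @param n number of gantry angles (>= 2).
#' @return numeric vector of angles in degrees.
#' @export
gantry_angle_grid <- function(n) {
  stopifnot(n >= 2L)
  seq(-180, 180, length.out = n)
}

#' Collimator angle grid
#'
#' `n` angles spanning `[-165, 165]` degrees.  The 5-angle case uses the
#' canonical set (-165, -90, 0, 90, 165); other counts are evenly spaced.
#'
#' @param n number of collimator angles (>= 2).
#' @return numeric vector of angles in degrees.
#' @export
collimator_angle_grid <- function(n) {
  stopifnot(n >= 2L)
  if (n == 5L) c(-165, -90, 0, 90, 165) else seq(-165, 165, length.out = n)
}

#' Geometric test plan
#'
#' The set of (collimator angle, gantry angle) pairs at which EPID images are
#' simulated, together with the localization noise and machine constants.
#'
#' @param gantry_angles gantry angles in degrees, within `[-180, 180]`.
#' @param collimator_angles collimator angles in degrees, within
#'   `[-165, 165]`.
#' @param sigma_mm standard deviation of the 2D Gaussian localization error
#'   of every measured detector coordinate, in mm (>= 0).
#' @param machine a [machine_constants()] object.
#' @param pairs optional explicit 2-column matrix `(theta, psi)` overriding
#'   the full `collimator x gantry` grid.
#' @return object of class `test_plan` with a `pairs` matrix (columns
#'   `theta`, `psi`).
#' @export
test_plan <- function(gantry_angles, collimator_angles, sigma_mm,
                      machine = machine_constants(), pairs = NULL) {
  stopifnot(inherits(machine, "machine_constants"))
  if (!is.numeric(sigma_mm) || length(sigma_mm) != 1L || sigma_mm < 0)
    stop("sigma_mm must be a single non-negative number")
  if (is.null(pairs)) {
    stopifnot(length(gantry_angles) >= 1L, length(collimator_angles) >= 1L)
    pairs <- as.matrix(expand.grid(theta = as.numeric(collimator_angles),
                                   psi = as.numeric(gantry_angles)))
  } else {
    pairs <- as.matrix(pairs)
    stopifnot(ncol(pairs) == 2L)
    colnames(pairs) <- c("theta", "psi")
  }
  if (any(pairs[, "psi"] < -180 | pairs[, "psi"] > 180))
    stop("gantry angles must lie within [-180, 180] degrees")
  if (any(pairs[, "theta"] < -165 | pairs[, "theta"] > 165))
    stop("collimator angles must lie within [-165, 165] degrees")
  structure(list(pairs = pairs, sigma_mm = sigma_mm, machine = machine),
            class = "test_plan")
}

#' @export
print.test_plan <- function(x, ...) {
  cat("Geometric test plan:", nrow(x$pairs), "images (",
      length(unique(x$pairs[, "psi"])), "gantry x",
      length(unique(x$pairs[, "theta"])), "collimator angles ),",
      "sigma =", x$sigma_mm, "mm\n")
  cat("  SAD", x$machine$SAD, "cm, SDD", x$machine$SDD, "cm, field",
      paste(x$machine$field_size, collapse = " x "), "cm\n")
  invisible(x)
}
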