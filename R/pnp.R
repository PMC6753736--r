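# Perspective-n-point pose of the collimator-mounted module: given a
# resected camera and the known module-local marker geometry, find the rigid
# transform whose projection matches the observations in least squares.
# Gauss-Newton / Levenberg iteration initialized from the nominal pose of the
# plan element (the test plan's angles are known inputs of the procedure).

# Internal PnP on plain matrices.  M: m x 3 module-local marker centers,
# uv: m x 2 observations, P: 3 x 4 camera matrix, R0/t0: initial pose.
# The Levenberg-Marquardt core is compiled (src/fitters.cpp).
pnp_pose <- function(M, uv, P, R0, t0, max_iter = 200L, tol = 1e-10) {
  if (nrow(M) < 4L) stop("module pose estimation needs at least 4 markers")
  fit <- pnp_lm(M, uv, P, R0, t0, max_iter, tol)
  list(R = fit$R, t = drop(fit$t), positions = fit$positions, rms = fit$rms)
}

#' Estimate the collimator-module pose from one image
#'
#' Places the known collimator-module geometry so that its central projection
#' through the given camera matches the observed marker coordinates in least
#' squares (perspective-n-point with a known camera).  The optimization is
#' initialized at the nominal pose implied by the plan element's angles.
#'
#' @param image an `image_record`.
#' @param camera a `camera_model` from [resect_camera()].
#' @param coll_geometry the collimator-mounted [phantom_module()] (>= 4
#'   markers).
#' @return object of class `pose_estimate`: `R` (rotation), `t`
#'   (translation, cm), `positions` (m x 3 reconstructed marker positions in
#'   the room frame) and `rms` reprojection residual (cm).
#' @export
estimate_module_pose <- function(image, camera, coll_geometry) {
  stopifnot(inherits(image, "image_record"), inherits(camera, "camera_model"),
            inherits(coll_geometry, "phantom_module"))
  init <- nominal_module_pose(coll_geometry, image$theta, image$psi)
  fit <- pnp_pose(coll_geometry$centers, image$coll_uv, camera$P,
                  init$R, init$t)
  structure(fit, class = "pose_estimate")
}
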