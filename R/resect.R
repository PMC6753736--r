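# Camera resection: recover the radiation source position and the detector
# plane of one exposure from the known 3D positions of the table-module
# markers and their measured 2D projections.
#
# The EPID is a physical flat panel with an orthonormal in-plane coordinate
# frame, so the camera has 9 free parameters: source position (3), detector
# orientation (3), source-detector distance (1) and principal point (2) --
# zero skew and unit aspect ratio by construction.  The fit minimizes the
# reprojection error by Levenberg-Marquardt iteration, initialized at the
# nominal machine state of the plan element (the plan's angles and nominal
# distances are known inputs of a geometric test; only the observations
# enter the fit).  An unconstrained 12-parameter projective (DLT) fit is
# near-critical for 6-marker modules at oblique gantry angles, which is why
# the physical parameterization is used.

# Internal resection on plain matrices.  X: n x 3 known marker positions
# (room frame), uv: n x 2 observations, psi: nominal gantry angle (deg).
# The Levenberg-Marquardt core is compiled (src/fitters.cpp).
resect <- function(X, uv, psi, machine, max_iter = 200L, tol = 1e-10) {
  n <- nrow(X)
  if (n < 6L) stop("camera resection needs at least 6 markers")
  sv <- svd(sweep(X, 2L, colMeans(X)), nu = 0L)$d
  if (sv[3L] < 1e-8 * max(sv[1L], 1e-300))
    stop("camera resection needs non-coplanar markers")
  ns <- nominal_state(0, psi, machine)
  R0 <- rbind(ns$detector$u_dir, ns$detector$v_dir, ns$beam_dir)
  fit <- resect_lm(X, uv, R0, ns$source, machine$SDD, max_iter, tol)
  R <- fit$R
  C <- drop(fit$C)
  f <- fit$f
  pp <- drop(fit$pp)
  a <- R[3L, ]                          # principal (beam) axis
  K <- rbind(c(f, 0, pp[1L]), c(0, f, pp[2L]), c(0, 0, 1))
  M <- K %*% R
  P <- cbind(M, -drop(M %*% C))
  list(P = P, source = C, axis = a, f = f, pp = pp,
       plane_point = C + f * a,
       rms = sqrt(fit$cost / (2 * n)),
       Minv = t(R) %*% solve(K))
}

#' Resect the EPID camera from one image
#'
#' Recovers the source position and detector-plane pose of one exposure from
#' the table-module marker observations by least-squares reprojection-error
#' minimization over the 9 physical camera parameters (source, detector
#' orientation, source-detector distance, principal point).  With exact
#' (noise-free) data the recovery is exact to numerical precision.
#'
#' @param image an `image_record` from [simulate_image()].
#' @param table_geometry the table-mounted [phantom_module()] (known
#'   geometry; >= 6 non-coplanar markers).
#' @param machine nominal [machine_constants()] used to initialize the fit.
#' @return object of class `camera_model`: `source` (cm), `detector` (a
#'   [plane3()]), `sdd` (distance source -> detector plane, cm), `P` (3 x 4
#'   camera matrix), `rms` reprojection residual (cm).
#' @export
resect_camera <- function(image, table_geometry,
                          machine = machine_constants()) {
  stopifnot(inherits(image, "image_record"),
            inherits(table_geometry, "phantom_module"))
  X <- module_positions(table_geometry, image$theta, image$psi)
  cam <- resect(X, image$table_uv, image$psi, machine)
  structure(list(source = cam$source,
                 detector = plane3(cam$plane_point, cam$axis),
                 sdd = cam$f, P = cam$P, rms = cam$rms, Minv = cam$Minv),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat("Camera model: source (", paste(signif(x$source, 6), collapse = ", "),
      ") cm, SDD ", signif(x$sdd, 6), " cm, RMS residual ",
      signif(x$rms, 3), " cm\n", sep = "")
  invisible(x)
}
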