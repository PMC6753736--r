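# Forward simulator: EPID measurement records under nominal geometry with
# Gaussian perturbation of every measured 2D coordinate.

#' Nominal machine state at a plan element
#'
#' @param theta collimator angle (deg).
#' @param psi gantry angle (deg).
#' @param machine a [machine_constants()].
#' @return list with `source` (cm), `beam_dir` (unit, source -> isocenter),
#'   `detector` (a [detector_frame()] whose 2D frame co-rotates with the
#'   gantry but not the collimator), `coll_axis` (a [line3()]), and
#'   `corners3d` (4 x 3 matrix: field corners A, B, C, D in the isocentric
#'   plane, rotated by `theta` about the collimator axis).
#' @export
nominal_state <- function(theta, psi, machine = machine_constants()) {
  stopifnot(inherits(machine, "machine_constants"))
  Ry <- rodrigues(c(0, deg2rad(psi), 0))
  source <- drop(Ry %*% c(0, 0, machine$SAD))
  beam <- -drop(Ry %*% c(0, 0, 1))
  center <- source + machine$SDD * beam
  u_dir <- drop(Ry %*% c(1, 0, 0))
  v_dir <- c(0, 1, 0)
  hx <- machine$field_size[1L] / 2
  hy <- machine$field_size[2L] / 2
  corners0 <- rbind(A = c(hx, hy, 0), B = c(hx, -hy, 0),
                    C = c(-hx, -hy, 0), D = c(-hx, hy, 0))
  Rz <- rodrigues(c(0, 0, deg2rad(theta)))
  corners <- corners0 %*% t(Rz) %*% t(Ry)
  list(source = source, beam_dir = beam,
       detector = detector_frame(center, beam, u_dir, v_dir),
       coll_axis = line3(source, beam),
       corners3d = corners)
}

#' Simulate one EPID exposure
#'
#' Projects every marker of both phantom modules and the four field corners
#' onto the detector under nominal geometry at `(theta, psi)`, then perturbs
#' each measured coordinate by an i.i.d. Gaussian offset with standard
#' deviation `sigma_mm` (per 2D axis, applied in detector-plane cm).  With
#' `sigma_mm = 0` the observations equal the exact nominal projections.
#'
#' @param theta,psi collimator and gantry angle (deg).
#' @param table,collimator [phantom_module()] objects.
#' @param machine a [machine_constants()].
#' @param sigma_mm localization noise in mm.
#' @return object of class `image_record` with fields `theta`, `psi`,
#'   `table_uv`, `coll_uv`, `corner_uv` (noisy observations, cm) and a
#'   `truth` block (noise-free projections plus the true source/detector)
#'   carried for diagnostics only -- reconstruction never reads it.
#' @export
simulate_image <- function(theta, psi, table, collimator,
                           machine = machine_constants(), sigma_mm = 0) {
  ns <- nominal_state(theta, psi, machine)
  posT <- module_positions(table, theta, psi)
  posC <- module_positions(collimator, theta, psi)
  uvT <- central_projection(ns$source, ns$detector, posT)
  uvC <- central_projection(ns$source, ns$detector, posC)
  uvF <- central_projection(ns$source, ns$detector, ns$corners3d)
  # visibility: collimator markers inside the field, everything on the panel
  fh <- machine$field_size / 2 * machine$SDD / machine$SAD
  eh <- machine$epid_size / 2
  cth <- cos(deg2rad(theta)); sth <- sin(deg2rad(theta))
  u0 <- uvC[, 1L] * cth + uvC[, 2L] * sth
  v0 <- -uvC[, 1L] * sth + uvC[, 2L] * cth
  if (any(abs(u0) > fh[1L] | abs(v0) > fh[2L]))
    stop("collimator marker(s) outside the radiation field at (theta=", theta,
         ", psi=", psi, "); run validate_configuration() for a full report")
  if (any(abs(rbind(uvT, uvC)) > rep(eh, each = nrow(uvT) + nrow(uvC))))
    stop("marker(s) project outside the EPID panel at (theta=", theta,
         ", psi=", psi, "); run validate_configuration() for a full report")
  s_cm <- sigma_mm / 10
  noise <- function(uv) uv + matrix(stats::rnorm(length(uv), sd = s_cm),
                                    nrow(uv), 2L)
  rec <- list(theta = theta, psi = psi,
              table_uv = if (s_cm > 0) noise(uvT) else uvT,
              coll_uv = if (s_cm > 0) noise(uvC) else uvC,
              corner_uv = if (s_cm > 0) noise(uvF) else uvF,
              truth = list(table_uv = uvT, coll_uv = uvC, corner_uv = uvF,
                           source = ns$source,
                           detector = ns$detector))
  class(rec) <- "image_record"
  rec
}

#' Simulate every exposure of a test plan
#'
#' @param plan a [test_plan()].
#' @param table,collimator [phantom_module()] objects.
#' @return list of [simulate_image()] records, one per plan element, in plan
#'   order.  Reproducible given the RNG state.
#' @export
simulate_plan <- function(plan, table, collimator) {
  stopifnot(inherits(plan, "test_plan"))
  lapply(seq_len(nrow(plan$pairs)), function(k)
    simulate_image(unname(plan$pairs[k, "theta"]), unname(plan$pairs[k, "psi"]),
                   table, collimator, plan$machine, plan$sigma_mm))
}

#' Flatten image records to a data frame
#'
#' One row per observation (marker or field corner).
#'
#' @param records list of `image_record`s from [simulate_plan()].
#' @return data frame with columns image, theta, psi, kind, id, u, v.
#' @export
records_to_data_frame <- function(records) {
  do.call(rbind, lapply(seq_along(records), function(k) {
    r <- records[[k]]
    data.frame(image = k, theta = r$theta, psi = r$psi,
               kind = rep(c("table", "collimator", "corner"),
                          c(nrow(r$table_uv), nrow(r$coll_uv), 4L)),
               id = c(seq_len(nrow(r$table_uv)), seq_len(nrow(r$coll_uv)),
                      1:4),
               u = c(r$table_uv[, 1L], r$coll_uv[, 1L], r$corner_uv[, 1L]),
               v = c(r$table_uv[, 2L], r$coll_uv[, 2L], r$corner_uv[, 2L]))
  }))
}
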