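# Reconstruction of linac geometry from measurement records alone.
#
# Chain, per replicate of a test plan:
#   1. per image: camera resection from the table module (known geometry),
#      then PnP pose of the collimator module;
#   2. per gantry angle: collimator rotation axis from the optimal (Kabsch)
#      rotations between wide-separation pairs of collimator-angle marker
#      configurations, direction by extrinsic mean, anchor by least-squares
#      fixed point;
#   3. isocenter = least-squares closest point to the per-gantry-angle axes;
#   4. gantry axis = extrinsic mean of the axes of the optimal rotations
#      between wide-separation pairs of gantry-angle point collections
#      (markers +, optionally, sources);
#   5. per image: SAD, SDD; field corners back-projected into the isocentric
#      plane H (normal to the collimator axis through the isocenter).

# Axis of rotation common to a sequence of corresponding configurations.
# configs: list (in angle order) of m x 3 matrices.  ref_dir: canonical
# hemisphere for the direction.  Returns list(direction, point, angles_deg).
#
# Configurations are paired half the sequence apart rather than
# consecutively: the axis-direction error of a fitted rotation scales as
# 1/sin(angle/2), so small-angle neighbour pairs amplify the marker noise
# while wide pairs (near half a revolution for dense angle grids) do not.
axis_from_configs <- function(configs, ref_dir) {
  k <- length(configs)
  if (k < 2L) stop("need at least two distinct collimator angles")
  off <- max(1L, k %/% 2L)
  np <- k - off
  dirs <- matrix(0, np, 3L)
  A <- matrix(0, 3L, 3L)
  b <- numeric(3L)
  angs <- numeric(np)
  for (j in seq_len(np)) {
    fit <- optimal_rotation(configs[[j]], configs[[j + off]])
    ax <- rotation_axis_of(fit$R, reference = ref_dir)
    dirs[j, ] <- ax$axis
    angs[j] <- ax$angle_deg
    # fixed points of the rigid motion: (I - R) x = t
    B <- diag(3) - fit$R
    A <- A + crossprod(B)
    b <- b + drop(crossprod(B, fit$t))
  }
  d <- extrinsic_mean_directions(dirs)
  # minimal-norm least-squares solution (the system is rank-2 along the axis)
  s <- eigen(A, symmetric = TRUE)
  keep <- s$values > 1e-8 * max(s$values)
  pt <- drop(s$vectors[, keep, drop = FALSE] %*%
               ((t(s$vectors[, keep, drop = FALSE]) %*% b) / s$values[keep]))
  list(direction = d, point = pt, angles_deg = angs)
}

#' Estimate the collimator rotation axis at one gantry angle
#'
#' Takes the reconstructed collimator-module marker configurations for a
#' sequence of collimator angles at a fixed gantry angle and returns the
#' common rotation axis: Kabsch rotations between configuration pairs half
#' the sequence apart, axis directions averaged by extrinsic mean, anchor
#' point from the least-squares fixed point of the rigid motions.
#'
#' @param marker_positions list of m x 3 matrices of reconstructed marker
#'   positions (room frame), ordered by collimator angle (>= 2 entries).
#' @param ref_dir reference direction for axis-sign canonicalization
#'   (typically the nominal beam axis, isocenter -> source).
#' @return a [line3()].
#' @export
estimate_collimator_axis <- function(marker_positions, ref_dir = c(0, 0, 1)) {
  ax <- axis_from_configs(marker_positions, unit3(vec3(ref_dir)))
  line3(ax$point, ax$direction)
}

#' Estimate the isocenter from collimator axes
#'
#' The radiation isocenter is the point minimizing the summed squared
#' distances to the collimator rotation axes collected over gantry angles.
#'
#' @param axes list of [line3()] axes (>= 2, not all parallel).
#' @return isocenter estimate (cm).
#' @export
estimate_isocenter <- function(axes) closest_point_to_lines(axes)

#' Estimate the gantry rotation axis
#'
#' Computes the optimal (Kabsch) rotation between point collections of
#' gantry angles half the sequence apart, takes each rotation's axis
#' (canonicalized to the +Y hemisphere) and returns their extrinsic mean.
#'
#' @param collections list of n x 3 point matrices, one per gantry angle in
#'   angle order; rows must correspond across collections (same markers /
#'   sources in the same order).
#' @return unit direction of the gantry rotation axis.
#' @export
estimate_gantry_axis <- function(collections) {
  k <- length(collections)
  if (k < 2L) stop("need at least two gantry angles")
  off <- max(1L, k %/% 2L)               # wide pairs; see axis_from_configs
  dirs <- matrix(0, k - off, 3L)
  for (j in seq_len(k - off)) {
    fit <- optimal_rotation(collections[[j]], collections[[j + off]])
    dirs[j, ] <- rotation_axis_of(fit$R, reference = c(0, 1, 0))$axis
  }
  extrinsic_mean_directions(dirs)
}

#' Gantry angle from the collimator axis
#'
#' The angle between the local vertical direction and the collimator
#' rotation axis, signed by the X-component of the (isocenter -> source)
#' axis direction.
#'
#' @param axis_dir collimator axis direction, canonicalized isocenter ->
#'   source.
#' @param vertical local vertical direction (default `(0, 0, 1)`).
#' @return signed gantry angle estimate in degrees, in `(-180, 180]`.
#' @export
estimate_gantry_angle <- function(axis_dir, vertical = c(0, 0, 1)) {
  ang <- angle_between(axis_dir, vertical)
  if (axis_dir[1L] < 0) ang <- -ang
  wrap_angle(ang)
}

#' Source-to-axis distance
#'
#' Distance from the source to its orthogonal projection onto the plane
#' normal to the collimator rotation axis and containing the isocenter.
#'
#' @param source reconstructed source position (cm).
#' @param axis collimator axis (a [line3()] or a unit direction).
#' @param isocenter reconstructed isocenter (cm).
#' @return SAD estimate in cm.
#' @export
estimate_sad <- function(source, axis, isocenter) {
  d <- if (inherits(axis, "line3")) axis$direction else unit3(vec3(axis))
  abs(sum((vec3(source) - vec3(isocenter)) * d))
}

#' Source-to-detector distance
#'
#' Unsigned distance from the source to the detector plane.
#'
#' @param source source position (cm).
#' @param detector detector plane (a [plane3()]).
#' @return SDD estimate in cm.
#' @export
estimate_sdd <- function(source, detector) {
  stopifnot(inherits(detector, "plane3"))
  abs(sum((vec3(source) - detector$point) * detector$normal))
}

# Back-project detector observations to the isocentric plane H through the
# camera matrix.  corner_uv: 4 x 2; returns 4 x 3 corner positions.
corners_in_H <- function(corner_uv, source, Minv, axis_dir, isocenter) {
  out <- matrix(0, 4L, 3L)
  for (i in 1:4) {
    dir <- drop(Minv %*% c(corner_uv[i, ], 1))
    den <- sum(dir * axis_dir)
    if (abs(den) < 1e-12 * vnorm(dir))
      stop("degenerate geometry: corner ray parallel to the isocentric plane")
    tt <- sum((isocenter - source) * axis_dir) / den
    out[i, ] <- source + tt * dir
  }
  out
}

field_metrics <- function(corners) {
  e <- corners[c(2:4, 1L), ] - corners          # AB, BC, CD, DA
  len <- sqrt(rowSums(e^2))
  # interior angles at B, C, D, A (between consecutive edges)
  ang <- numeric(4L)
  for (i in 1:4) {
    a <- -e[i, ]; b <- e[if (i == 4L) 1L else i + 1L, ]
    ang[i] <- rad2deg(acos(clamp1(sum(a * b) / (vnorm(a) * vnorm(b)))))
  }
  list(edge_lengths = len, corner_angles = ang)
}

#' Reconstruct the radiation field in the isocentric plane
#'
#' Back-projects the four measured field-corner coordinates along their rays
#' to the plane H normal to the collimator axis through the isocenter, and
#' computes edge lengths, corner angles and deviations from the nominal
#' corners.
#'
#' @param corner_uv 4 x 2 matrix of detector corner coordinates (cm), in
#'   A, B, C, D order.
#' @param camera a `camera_model`.
#' @param axis collimator axis (a [line3()] or unit direction).
#' @param isocenter isocenter estimate (cm).
#' @param nominal_corners optional 4 x 3 matrix of nominal corner positions
#'   for the deviation report.
#' @return object of class `field_reconstruction`: `corners` (4 x 3, cm),
#'   `edge_lengths` (AB, BC, CD, DA; cm), `corner_angles` (at B, C, D, A;
#'   deg), and `corner_deviations` (cm, if nominal corners given).
#' @export
reconstruct_field <- function(corner_uv, camera, axis, isocenter,
                              nominal_corners = NULL) {
  stopifnot(inherits(camera, "camera_model"))
  d <- if (inherits(axis, "line3")) axis$direction else unit3(vec3(axis))
  corners <- corners_in_H(as.matrix(corner_uv), camera$source, camera$Minv,
                          d, vec3(isocenter))
  fm <- field_metrics(corners)
  dev <- if (!is.null(nominal_corners))
    sqrt(rowSums((corners - as.matrix(nominal_corners))^2)) else NULL
  structure(list(corners = corners, edge_lengths = fm$edge_lengths,
                 corner_angles = fm$corner_angles, corner_deviations = dev),
            class = "field_reconstruction")
}

#' Reconstruct full linac geometry from one simulated plan
#'
#' Runs the whole chain (resection, pose, per-gantry-angle collimator axes,
#' isocenter, gantry axis, per-image SAD/SDD, field reconstruction) on the
#' measurement records of one plan replicate.  Only the noisy observations
#' are read; the records' truth blocks are never touched.
#'
#' @param records list of `image_record`s from [simulate_plan()].
#' @param table,collimator the known [phantom_module()] geometries.
#' @param machine a [machine_constants()] (nominal values used for error
#'   reporting and PnP initialization).
#' @param include_sources include the resected source positions in the
#'   gantry-axis point collections (default TRUE).
#' @return object of class `reconstructed_geometry`; see fields in the
#'   implementation: per-gantry-angle axes and angle estimates, global
#'   isocenter and gantry axis, and per-image SAD/SDD/field results.
#' @export
reconstruct_plan <- function(records, table, collimator,
                             machine = machine_constants(),
                             include_sources = TRUE) {
  nimg <- length(records)
  if (nimg < 1L) stop("no records to reconstruct")
  theta <- vapply(records, `[[`, numeric(1L), "theta")
  psi <- vapply(records, `[[`, numeric(1L), "psi")
  Xtab <- module_positions(table, 0, 0)   # table module does not move
  Mloc <- collimator$centers

  sources <- matrix(0, nimg, 3L)
  sdd_img <- numeric(nimg)
  Minvs <- vector("list", nimg)
  marker_pos <- vector("list", nimg)
  resid <- numeric(nimg)
  for (k in seq_len(nimg)) {
    cam <- resect(Xtab, records[[k]]$table_uv, psi[k], machine)
    init <- nominal_module_pose(collimator, theta[k], psi[k])
    pose <- pnp_pose(Mloc, records[[k]]$coll_uv, cam$P, init$R, init$t)
    sources[k, ] <- cam$source
    sdd_img[k] <- cam$f
    Minvs[[k]] <- cam$Minv
    marker_pos[[k]] <- pose$positions
    resid[k] <- cam$rms
  }

  psis <- sort(unique(psi))
  npsi <- length(psis)
  axes <- vector("list", npsi)
  alpha_est <- numeric(npsi)
  for (i in seq_len(npsi)) {
    idx <- which(psi == psis[i])
    idx <- idx[order(theta[idx])]
    if (length(idx) < 2L)
      stop("need at least two collimator angles per gantry angle")
    ref <- c(sin(deg2rad(psis[i])), 0, cos(deg2rad(psis[i])))
    ax <- axis_from_configs(marker_pos[idx], ref)
    axes[[i]] <- line3(ax$point, ax$direction)
    alpha_est[i] <- estimate_gantry_angle(ax$direction)
  }

  if (npsi < 2L) stop("need at least two gantry angles to find the isocenter")
  isocenter <- closest_point_to_lines(axes)

  # gantry axis from per-gantry-angle point collections
  collections <- vector("list", npsi)
  for (i in seq_len(npsi)) {
    idx <- which(psi == psis[i])
    idx <- idx[order(theta[idx])]
    pts <- do.call(rbind, marker_pos[idx])
    if (include_sources) pts <- rbind(pts, sources[idx, , drop = FALSE])
    collections[[i]] <- pts
  }
  gantry_axis <- estimate_gantry_axis(collections)

  # per-image SAD / SDD / field
  sad_img <- numeric(nimg)
  edge_len <- matrix(0, nimg, 4L)
  corner_ang <- matrix(0, nimg, 4L)
  corner_dev <- matrix(0, nimg, 4L)
  for (k in seq_len(nimg)) {
    i <- match(psi[k], psis)
    d <- axes[[i]]$direction
    sad_img[k] <- abs(sum((sources[k, ] - isocenter) * d))
    corners <- corners_in_H(records[[k]]$corner_uv, sources[k, ], Minvs[[k]],
                            d, isocenter)
    fm <- field_metrics(corners)
    edge_len[k, ] <- fm$edge_lengths
    corner_ang[k, ] <- fm$corner_angles
    nomc <- nominal_state(theta[k], psi[k], machine)$corners3d
    corner_dev[k, ] <- sqrt(rowSums((corners - nomc)^2))
  }

  structure(list(
    psis = psis, theta = theta, psi = psi,
    axes = axes, alpha_est = alpha_est,
    isocenter = isocenter, gantry_axis = gantry_axis,
    sources = sources, sad_img = sad_img, sdd_img = sdd_img,
    edge_lengths = edge_len, corner_angles = corner_ang,
    corner_deviations = corner_dev, resection_rms = resid,
    machine = machine), class = "reconstructed_geometry")
}

#' @export
print.reconstructed_geometry <- function(x, ...) {
  cat("Reconstructed linac geometry from", length(x$theta), "images\n")
  cat("  isocenter (cm):", paste(signif(x$isocenter, 4), collapse = ", "), "\n")
  cat("  gantry axis:", paste(signif(x$gantry_axis, 4), collapse = ", "), "\n")
  cat("  SAD (cm): mean", signif(mean(x$sad_img), 6),
      " SDD (cm): mean", signif(mean(x$sdd_img), 6), "\n")
  invisible(x)
}
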