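# Phantom modules: rigid sets of fiducial ball markers.
#
# The table-mounted module does not move with the machine; its pose is a
# fixed translation in the room frame.  The collimator-mounted module is
# centered on the beam axis and co-rotates with the collimator and the
# gantry.

#' Construct a phantom module
#'
#' @param centers n x 3 matrix of ball-marker centers in the module-local
#'   frame (cm).  The local y axis is the direction designated as the gantry
#'   rotation direction.
#' @param mounting `"table"` or `"collimator"`.
#' @param radius ball radius in cm (all markers; default 0.3).
#' @param origin module origin expressed in the room frame (table mounting)
#'   or in the gantry frame at collimator angle 0 (collimator mounting, where
#'   the module is centered on the beam axis).
#' @return object of class `phantom_module`.
#' @export
phantom_module <- function(centers, mounting = c("table", "collimator"),
                           radius = 0.3,
                           origin = if (mounting[1L] == "table") c(0, 7.3, 0)
                                    else c(0, 0, 20)) {
  mounting <- match.arg(mounting)
  centers <- as.matrix(centers)
  if (ncol(centers) != 3L) stop("centers must be an n x 3 matrix")
  if (!is.numeric(radius) || radius <= 0) stop("ball radius must be positive")
  n <- nrow(centers)
  if (mounting == "table" && n < 6L)
    stop("a table-mounted module needs at least 6 markers")
  if (mounting == "collimator" && n < 4L)
    stop("a collimator-mounted module needs at least 4 markers")
  if (mounting == "table") {
    # camera resection needs full 3D spread
    s <- svd(sweep(centers, 2L, colMeans(centers)), nu = 0L)
    if (s$d[3L] < 1e-8 * max(s$d[1L], 1e-300))
      stop("table-module markers must not be coplanar")
  }
  dimnames(centers) <- NULL
  structure(list(centers = centers, mounting = mounting,
                 radius = radius, origin = vec3(origin), n = n),
            class = "phantom_module")
}

#' @export
print.phantom_module <- function(x, ...) {
  cat("Phantom module (", x$mounting, "-mounted): ", x$n,
      " balls of radius ", x$radius, " cm\n", sep = "")
  invisible(x)
}

plane_counts <- function(n, max_per_plane) {
  n_planes <- ceiling(n / max_per_plane)
  counts <- rep(n %/% n_planes, n_planes)
  extra <- n - sum(counts)
  if (extra > 0L) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  counts
}

#' Deterministic parallel-plane ball layout
#'
#' Places `n_balls` markers in parallel planes perpendicular to the module's
#' beam-facing axis (local z), at most `max_per_plane` markers per plane,
#' inside a cube of the given edge.  All markers get strictly distinct
#' coordinates along the gantry-rotation direction (local y) -- the
#' sufficient condition for their projections not to coincide.  Table
#' modules walk a base set of up to 6 markers around the extremes of the
#' (x, z) cross-section (a near-cube-corner arrangement, which keeps camera
#' resection well conditioned at every gantry angle) with evenly spread y;
#' additional markers share a base vertical laterally and sit on interior
#' planes, so dense modules are never worse conditioned than the base
#' skeleton.  Collimator modules place markers on a ring at golden-angle
#' increments.  The generator is a pure function of its arguments.  Note
#' that for dense table modules (> 6 balls in the 8 cm cube) the projected
#' marker disks can come closer than the disk-overlap margin that
#' [validate_configuration()] enforces on dense angle grids; the baseline
#' 6-ball module is overlap-free on every grid plan.
#'
#' @param n_balls number of markers (>= 6 for table, >= 4 for collimator).
#' @param cube_edge bounding-cube edge length in cm.
#' @param mounting `"table"` or `"collimator"`.
#' @param max_per_plane cap on markers per plane (default 4 for table
#'   modules, 3 for collimator modules).
#' @param radius ball radius in cm.
#' @param origin module origin (see [phantom_module()]).
#' @param phase_deg phase of the collimator-module golden-angle ring
#'   (ignored for table modules).
#' @return a [phantom_module()].
#' @export
planar_layout <- function(n_balls, cube_edge, mounting = c("table", "collimator"),
                          max_per_plane = if (mounting[1L] == "table") 4L else 3L,
                          radius = 0.3,
                          origin = if (mounting[1L] == "table") c(0, 7.3, 0)
                                   else c(0, 0, 20),
                          phase_deg = if (mounting[1L] == "table") 37.5 else 65) {
  mounting <- match.arg(mounting)
  if (!is.numeric(n_balls) || n_balls < 1L)
    stop("n_balls must be a positive integer")
  if (cube_edge <= 0) stop("bounding cube edge must be positive")
  if (max_per_plane < 1L) stop("infeasible packing: max_per_plane < 1")
  n <- as.integer(n_balls)
  half <- cube_edge / 2
  margin <- half - radius              # ball, not center, inside the cube
  if (margin <= 0) stop("infeasible packing: cube smaller than a ball")
  n_planes <- as.integer(ceiling(n / max_per_plane))
  i <- seq_len(n) - 1L
  if (mounting == "table") {
    # Corner walk: a base set of (up to 6) markers cycles around the
    # rectangle {x = +/-margin} x {plane z levels} with strictly monotone,
    # evenly spread gantry-axis (y) coordinates.  Extremal x and z at every
    # marker keeps the camera resection well conditioned at every gantry
    # angle (a near-cube-corner configuration), and the even y spread keeps
    # the projected disks from overlapping.  Markers beyond the base set
    # share a base marker's vertical (same x, z; offset in y): adding
    # observations on an existing vertical can only add information, so
    # dense modules are never worse conditioned than the base skeleton.
    n_base <- min(n, 6L)
    np_b <- as.integer(ceiling(n_base / max_per_plane))
    zs <- if (np_b == 1L) 0 else c(-margin, margin)
    walk_x <- rep(c(margin, -margin), each = np_b)
    walk_z <- c(zs, rev(zs))
    jb <- (seq_len(n_base) - 1L) %% (2L * np_b) + 1L
    xb <- walk_x[jb]; zb <- walk_z[jb]
    yb <- if (n_base == 1L) 0 else seq(-margin, margin, length.out = n_base)
    k <- n - n_base
    if (k > 0L) {
      partners <- if (k <= n_base - 2L)
        round(seq(1, n_base, length.out = k + 2L))[2:(k + 1L)]
      else rep(seq_len(n_base), length.out = k)
      ni <- max(2L, as.integer(ceiling(k / max_per_plane)))
      zint <- seq(-margin / 2, margin / 2, length.out = ni)
      spacing <- 2 * margin / (n_base - 1L)
      x <- c(xb, xb[partners])
      z <- c(zb, zint[(seq_len(k) - 1L) %% ni + 1L])
      y <- c(yb, yb[partners] + 0.45 * spacing)
    } else {
      x <- xb; z <- zb; y <- yb
    }
  } else {
    # ring tightened so the projected sweep under collimator rotation stays
    # clear of the table-module detector band
    zs <- if (n_planes == 1L) 0 else seq(-0.6 * margin, 0.6 * margin,
                                         length.out = n_planes)
    z <- zs[(i %% n_planes) + 1L]
    r <- 0.7 * margin
    phi <- deg2rad(phase_deg + i * GOLDEN_ANGLE)
    x <- r * cos(phi)
    y <- r * sin(phi) + (i - (n - 1) / 2) * 0.05   # distinct y
  }
  centers <- cbind(x, y, z)
  if (any(abs(centers) > half))
    stop("infeasible packing: markers fall outside the bounding cube")
  phantom_module(centers, mounting, radius, origin)
}

#' Deterministic spiral ball layout
#'
#' Places markers on a helix whose axis is parallel to the given direction
#' (nominally the gantry rotation axis), spanning the given cuboid.  Axis
#' coordinates are strictly monotone, so all markers have distinct
#' coordinates along the helix axis.
#'
#' @param n_balls number of markers (>= 4).
#' @param cuboid bounding box `c(x, y, z)` extents in cm, where y is the
#'   extent along the helix axis.
#' @param axis helix axis direction (default the gantry axis `(0, 1, 0)`).
#' @param mounting,radius,origin see [phantom_module()].
#' @param turns number of helix turns across the axis span.
#' @return a [phantom_module()].
#' @export
spiral_layout <- function(n_balls, cuboid, axis = c(0, 1, 0),
                          mounting = "table", radius = 0.3,
                          origin = c(0, 0, 0), turns = 2) {
  if (!is.numeric(n_balls) || n_balls < 4L)
    stop("a spiral layout needs at least 4 markers")
  cuboid <- as.numeric(cuboid)
  if (length(cuboid) != 3L || any(cuboid <= 0))
    stop("degenerate cuboid: all three extents must be positive")
  n <- as.integer(n_balls)
  tfrac <- (seq_len(n) - 1L) / (n - 1L)
  m <- 0.9
  rx <- m * cuboid[1L] / 2
  rz <- m * cuboid[3L] / 2
  yy <- m * cuboid[2L] * (tfrac - 0.5)
  phi <- 2 * pi * turns * tfrac
  centers <- cbind(rx * cos(phi), yy, rz * sin(phi))
  a <- unit3(vec3(axis))
  if (sum(a * c(0, 1, 0)) < 1 - 1e-12) {
    v <- cross3(c(0, 1, 0), a)
    ang <- acos(clamp1(a[2L]))
    centers <- centers %*% t(rodrigues(unit3(v) * ang))
  }
  phantom_module(centers, mounting, radius, origin)
}

# Room-frame marker positions of a module at machine angles (theta, psi), deg.
module_positions <- function(module, theta, psi) {
  if (module$mounting == "table") {
    sweep(module$centers, 2L, module$origin, "+")
  } else {
    Rz <- rodrigues(c(0, 0, deg2rad(theta)))
    Ry <- rodrigues(c(0, deg2rad(psi), 0))
    loc <- module$centers %*% t(Rz)
    sweep(loc, 2L, module$origin, "+") %*% t(Ry)
  }
}

# Nominal rigid transform (R0, t0) of the collimator module at (theta, psi):
# room position = R0 %*% local + t0.
nominal_module_pose <- function(module, theta, psi) {
  Rz <- rodrigues(c(0, 0, deg2rad(theta)))
  Ry <- rodrigues(c(0, deg2rad(psi), 0))
  list(R = Ry %*% Rz, t = drop(Ry %*% module$origin))
}

#' Check a phantom/plan configuration for visibility and projection overlap
#'
#' For every plan element, checks that all collimator-module markers project
#' inside the radiation field, that all markers project onto the EPID panel,
#' and that no two projected marker disks (projected center +/- magnified
#' ball radius) overlap.  The configuration is valid iff no violation is
#' found for any plan element.
#'
#' @param table,collimator [phantom_module()] objects.
#' @param plan a [test_plan()].
#' @param machine machine constants (defaults to the plan's).
#' @return object of class `validity_report`: list with logical `valid` and a
#'   `violations` data frame (theta, psi, type, detail).
#' @export
validate_configuration <- function(table, collimator, plan,
                                   machine = plan$machine) {
  stopifnot(inherits(table, "phantom_module"),
            inherits(collimator, "phantom_module"),
            inherits(plan, "test_plan"))
  if (nrow(plan$pairs) < 1L) stop("plan must contain at least one element")
  viol <- list()
  fh <- machine$field_size / 2 * machine$SDD / machine$SAD
  eh <- machine$epid_size / 2
  for (k in seq_len(nrow(plan$pairs))) {
    th <- plan$pairs[k, "theta"]; ps <- plan$pairs[k, "psi"]
    ns <- nominal_state(th, ps, machine)
    posT <- module_positions(table, th, ps)
    posC <- module_positions(collimator, th, ps)
    pos <- rbind(posT, posC)
    uv <- central_projection(ns$source, ns$detector, pos)
    depth <- as.vector(sweep(pos, 2L, ns$source) %*% ns$beam_dir)
    rho <- c(rep(table$radius, table$n), rep(collimator$radius, collimator$n)) *
      machine$SDD / depth
    labs <- c(paste0("table:", seq_len(table$n)),
              paste0("collimator:", seq_len(collimator$n)))
    # collimator markers inside the (theta-rotated) field aperture
    ci <- table$n + seq_len(collimator$n)
    cth <- cos(deg2rad(th)); sth <- sin(deg2rad(th))
    u0 <- uv[ci, 1L] * cth + uv[ci, 2L] * sth
    v0 <- -uv[ci, 1L] * sth + uv[ci, 2L] * cth
    bad <- which(abs(u0) > fh[1L] - rho[ci] | abs(v0) > fh[2L] - rho[ci])
    for (b in bad)
      viol[[length(viol) + 1L]] <- data.frame(
        theta = th, psi = ps, type = "outside_field", detail = labs[ci[b]])
    # every marker on the EPID panel
    bad <- which(abs(uv[, 1L]) > eh[1L] - rho | abs(uv[, 2L]) > eh[2L] - rho)
    for (b in bad)
      viol[[length(viol) + 1L]] <- data.frame(
        theta = th, psi = ps, type = "outside_epid", detail = labs[b])
    # pairwise disk overlap
    d2 <- as.matrix(stats::dist(uv))
    lim <- outer(rho, rho, "+")
    ov <- which(d2 < lim & upper.tri(d2), arr.ind = TRUE)
    if (nrow(ov))
      for (b in seq_len(nrow(ov)))
        viol[[length(viol) + 1L]] <- data.frame(
          theta = th, psi = ps, type = "overlap",
          detail = paste(labs[ov[b, 1L]], labs[ov[b, 2L]], sep = " / "))
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(theta = numeric(), psi = numeric(),
               type = character(), detail = character())
  structure(list(valid = nrow(violations) == 0L, violations = violations),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  if (x$valid) cat("Configuration valid: no visibility or overlap violations\n")
  else {
    cat("Configuration INVALID:", nrow(x$violations), "violations\n")
    print(utils::head(x$violations, 20L))
  }
  invisible(x)
}

#' Export marker centers as a data frame
#'
#' @param x a [phantom_module()].
#' @param ... unused.
#' @return data frame with marker id, local center coordinates and radius.
#' @export
as.data.frame.phantom_module <- function(x, ...) {
  data.frame(id = seq_len(x$n), x = x$centers[, 1L], y = x$centers[, 2L],
             z = x$centers[, 3L], radius = x$radius, mounting = x$mounting)
}
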