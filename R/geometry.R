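# Exact geometric primitives shared by the forward simulator and every
# reconstruction solver.
#
# Room-frame convention: origin at the nominal isocenter; Y = nominal gantry
# rotation axis; Z = local vertical (up); X = Y x Z.  At gantry angle
# psi = 0 the source sits at (0, 0, SAD) and the beam axis points along -Z;
# rotating the gantry by psi moves the source to (SAD sin psi, 0, SAD cos psi).
# The collimator rotates about the source-isocenter axis.  The detector plane
# is normal to the beam axis at distance SDD from the source and co-rotates
# with the gantry but not with the collimator.

#' Construct a 3D vector (cm)
#'
#' @param x,y,z coordinates in cm, or `x` a length-3 numeric.
#' @return numeric length-3 vector.
#' @export
vec3 <- function(x, y = NULL, z = NULL) {
  v <- if (is.null(y)) as.numeric(x) else c(x, y, z)
  if (length(v) != 3L || !all(is.finite(v)))
    stop("vec3 requires three finite coordinates")
  v
}

#' Normalize a vector to unit length
#'
#' @param v numeric length-3 vector.
#' @return unit vector; errors on near-zero input.
#' @export
unit3 <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

#' An unoriented line in 3D
#'
#' Lines are orientation-agnostic: every computation on a `line3` is invariant
#' to flipping the direction or sliding the anchor point along the line.
#'
#' @param point any point on the line (cm).
#' @param direction direction vector (normalized internally).
#' @return object of class `line3` with fields `point` and `direction`.
#' @export
line3 <- function(point, direction) {
  structure(list(point = vec3(point), direction = unit3(vec3(direction))),
            class = "line3")
}

#' A plane in 3D
#'
#' @param point any point on the plane (cm).
#' @param normal normal vector (normalized internally).
#' @return object of class `plane3`.
#' @export
plane3 <- function(point, normal) {
  structure(list(point = vec3(point), normal = unit3(vec3(normal))),
            class = "plane3")
}

#' Orthonormal 2D frame on a detector plane
#'
#' The frame maps a point on the plane to `(u, v)` coordinates in cm relative
#' to `center`.
#'
#' @param center frame origin (cm), on the plane.
#' @param normal plane normal.
#' @param u_dir,v_dir in-plane axis directions; must be orthonormal and
#'   orthogonal to the normal within 1e-9.
#' @return object of class `detector_frame`.
#' @export
detector_frame <- function(center, normal, u_dir, v_dir) {
  center <- vec3(center); normal <- unit3(vec3(normal))
  u_dir <- unit3(vec3(u_dir)); v_dir <- unit3(vec3(v_dir))
  if (abs(sum(u_dir * v_dir)) > 1e-9 || abs(sum(u_dir * normal)) > 1e-9 ||
      abs(sum(v_dir * normal)) > 1e-9)
    stop("detector frame axes must be mutually orthogonal")
  structure(list(center = center, normal = normal,
                 u_dir = u_dir, v_dir = v_dir),
            class = "detector_frame")
}

#' Proper rotation about an arbitrary axis
#'
#' @param axis a [line3()]: the rotation axis (anchor point + direction).
#' @param angle_deg rotation angle in degrees (any real).
#' @return object of class `rotation3` with fields `R` (3x3 proper rotation
#'   matrix) and `anchor` (point the axis passes through).
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  stopifnot(inherits(axis, "line3"))
  R <- rodrigues(axis$direction * deg2rad(angle_deg))
  structure(list(R = R, anchor = axis$point), class = "rotation3")
}

#' Apply a rotation to points
#'
#' @param rot a `rotation3` from [rotation_about_axis()], or a plain 3x3
#'   rotation matrix (anchor at the origin).
#' @param pts numeric length-3 vector or n x 3 matrix of points (cm).
#' @return rotated points, same shape as the input.
#' @export
rotate_points <- function(rot, pts) {
  if (is.matrix(rot)) rot <- structure(list(R = rot, anchor = c(0, 0, 0)),
                                       class = "rotation3")
  stopifnot(inherits(rot, "rotation3"))
  single <- is.null(dim(pts))
  P <- if (single) matrix(pts, 1L, 3L) else as.matrix(pts)
  out <- sweep(P, 2L, rot$anchor) %*% t(rot$R)
  out <- sweep(out, 2L, rot$anchor, "+")
  if (single) drop(out) else out
}

#' Distance from a point to a line
#'
#' @param p point (cm).
#' @param l a [line3()].
#' @return non-negative distance in cm; invariant to the line representation.
#' @export
point_line_distance <- function(p, l) {
  stopifnot(inherits(l, "line3"))
  w <- vec3(p) - l$point
  vnorm(cross3(w, l$direction))
}

#' Intersection of a line and a plane
#'
#' @param l a [line3()].
#' @param pl a [plane3()].
#' @param eps degeneracy threshold on |direction . normal| (default 1e-9).
#' @return the intersection point (cm); errors when the line is (near)
#'   parallel to the plane.
#' @export
line_plane_intersection <- function(l, pl, eps = 1e-9) {
  stopifnot(inherits(l, "line3"), inherits(pl, "plane3"))
  den <- sum(l$direction * pl$normal)
  if (abs(den) <= eps)
    stop("degenerate geometry: line is parallel to the plane")
  t <- sum((pl$point - l$point) * pl$normal) / den
  l$point + t * l$direction
}

#' Central projection of a point onto a detector plane
#'
#' Projects `p` from `source` onto the plane of `frame` and returns the
#' piercing point in the frame's 2D coordinates (cm).  A point in the
#' isocentric plane at lateral offset r maps to offset r * SDD / SAD under
#' nominal geometry.
#'
#' @param source source position (cm).
#' @param frame a [detector_frame()].
#' @param p point to project (single point or n x 3 matrix).
#' @return numeric `(u, v)` (or n x 2 matrix) in cm.
#' @export
central_projection <- function(source, frame, p) {
  stopifnot(inherits(frame, "detector_frame"))
  source <- vec3(source)
  single <- is.null(dim(p))
  P <- if (single) matrix(p, 1L, 3L) else as.matrix(p)
  d0 <- sum((frame$center - source) * frame$normal)
  W <- sweep(P, 2L, source)
  den <- as.vector(W %*% frame$normal)
  if (any(abs(den) < 1e-12))
    stop("degenerate geometry: ray parallel to the detector (or point at the source)")
  s <- d0 / den
  if (any(s <= 0))
    stop("point projects behind the source relative to the detector")
  pier <- sweep(W * s, 2L, source, "+")
  rel <- sweep(pier, 2L, frame$center)
  uv <- cbind(as.vector(rel %*% frame$u_dir), as.vector(rel %*% frame$v_dir))
  if (single) drop(uv) else uv
}

#' Back-projection ray through a detector coordinate
#'
#' @param source source position (cm).
#' @param frame a [detector_frame()].
#' @param uv length-2 detector coordinates (cm).
#' @return a [line3()] through the source and the detector point.
#' @export
back_project <- function(source, frame, uv) {
  pt <- frame$center + uv[1L] * frame$u_dir + uv[2L] * frame$v_dir
  line3(source, pt - vec3(source))
}

#' Least-squares closest point to a set of lines
#'
#' Returns the point minimizing the sum of squared distances to the lines
#' (the radiation-isocenter estimator), solved in closed form via the normal
#' equations of the summed projection operators.
#'
#' @param lines list of [line3()] objects (>= 2, not all parallel).
#' @param cond_max condition-number threshold for declaring the system
#'   degenerate (default 1e8).
#' @return the minimizing point (cm).
#' @export
closest_point_to_lines <- function(lines, cond_max = 1e8) {
  if (!is.list(lines) || length(lines) < 2L)
    stop("need at least two lines")
  A <- matrix(0, 3L, 3L)
  b <- numeric(3L)
  for (l in lines) {
    stopifnot(inherits(l, "line3"))
    Pi <- diag(3) - tcrossprod(l$direction)
    A <- A + Pi
    b <- b + Pi %*% l$point
  }
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1L] <= 0 || ev[1L] / max(ev[3L], .Machine$double.xmin) > cond_max)
    stop("degenerate geometry: lines are (near) mutually parallel")
  drop(solve(A, b))
}

#' Optimal rigid rotation between corresponding point sets (Kabsch)
#'
#' Finds the proper rotation `R` minimizing
#' `sum_i |Y_i - (R (X_i - mean(X)) + mean(Y))|^2`; the reflection branch is
#' excluded.
#'
#' @param X,Y n x 3 matrices of corresponding points, n >= 3, non-collinear
#'   after centering.
#' @return list with `R` (3x3 rotation), `t` (translation such that
#'   `Y ~ X R' + t`), and `rms` residual (cm).
#' @export
optimal_rotation <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y)) || nrow(X) < 3L)
    stop("point sets must match and contain at least 3 points")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  B <- crossprod(Yc, Xc)               # sum_i yc_i xc_i'
  s <- svd(B)
  if (s$d[2L] < 1e-9 * max(s$d[1L], 1e-300))
    stop("degenerate geometry: point set is (near) collinear")
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t <- cy - drop(R %*% cx)
  res <- Yc - Xc %*% t(R)
  list(R = R, t = t, rms = sqrt(mean(rowSums(res^2))))
}

#' Rotation axis and angle of a rotation matrix
#'
#' @param R 3x3 proper rotation matrix.
#' @param reference direction used to pick the axis sign: the returned axis
#'   has a non-negative dot product with it (ties fall back to the +Y
#'   hemisphere).
#' @return list with `axis` (unit vector, `R axis = axis`) and `angle_deg`.
#'   Errors for near-identity rotations (angle < 1e-6 rad), whose axis is
#'   ill-defined.
#' @export
rotation_axis_of <- function(R, reference = c(0, 1, 0)) {
  tr <- R[1L, 1L] + R[2L, 2L] + R[3L, 3L]
  ang <- acos(clamp1((tr - 1) / 2))
  if (ang < 1e-6)
    stop("ill-defined axis: rotation is (near) the identity")
  if (ang < pi - 1e-3) {
    ax <- c(R[3L, 2L] - R[2L, 3L],
            R[1L, 3L] - R[3L, 1L],
            R[2L, 1L] - R[1L, 2L]) / (2 * sin(ang))
  } else {
    B <- R + diag(3)                   # columns are parallel to the axis
    j <- which.max(colSums(B^2))
    ax <- B[, j]
  }
  ax <- unit3(ax)
  s <- sum(ax * reference)
  if (abs(s) < 1e-12) s <- ax[2L]      # tie: +Y hemisphere
  if (s < 0) ax <- -ax
  list(axis = ax, angle_deg = rad2deg(ang))
}

#' Extrinsic (chordal) mean of unit directions
#'
#' The normalized arithmetic mean of the input unit vectors, the minimizer of
#' the summed squared chordal distance over the unit sphere.  Inputs are
#' expected to be pre-aligned to a common hemisphere.
#'
#' @param dirs n x 3 matrix (or length-3 vector) of unit directions.
#' @return unit direction; errors on antipodal cancellation.
#' @export
extrinsic_mean_directions <- function(dirs) {
  D <- if (is.null(dim(dirs))) matrix(dirs, 1L, 3L) else as.matrix(dirs)
  if (nrow(D) < 1L) stop("need at least one direction")
  m <- colMeans(D)
  if (vnorm(m) < 1e-9)
    stop("degenerate geometry: directions cancel (antipodal inputs)")
  m / vnorm(m)
}

#' Angle between two directions
#'
#' @param a,b direction vectors (need not be unit).
#' @return angle in degrees in `[0, 180]`.
#' @export
angle_between <- function(a, b) {
  rad2deg(acos(clamp1(sum(unit3(a) * unit3(b)))))
}
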