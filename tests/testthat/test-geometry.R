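# Geometric primitives against independent numeric oracles.

test_that("rotation about an axis matches the matrix-exponential oracle", {
  p <- c(0, 0, 100)
  expect_equal(rotate_points(rotation_about_axis(line3(c(0, 0, 0), c(0, 1, 0)), 0), p), p)
  expect_equal(rotate_points(rotation_about_axis(line3(c(0, 0, 0), c(0, 1, 0)), 90), p),
               c(100, 0, 0), tolerance = 1e-12)
  # composition: angle a then b equals a + b
  ax <- line3(c(1, -2, 0.5), c(0.3, -1, 2))
  p2 <- rotate_points(rotation_about_axis(ax, 40),
                      rotate_points(rotation_about_axis(ax, 25), p))
  expect_equal(p2, rotate_points(rotation_about_axis(ax, 65), p), tolerance = 1e-10)
  set.seed(11)
  for (k in 1:10) {
    d <- rand_unit()
    ang <- stats::runif(1, -300, 300)
    R <- rotation_about_axis(line3(c(0, 0, 0), d), ang)$R
    Roracle <- as.matrix(Matrix::expm(linacqa:::skew3(d * ang * pi / 180)))
    pts <- matrix(stats::rnorm(60, sd = 10), 20, 3)
    expect_lt(max(abs(rotate_points(R, pts) - pts %*% t(Roracle))), 1e-10)
  }
})

test_that("point-line distance is representation invariant and matches 1-D minimization", {
  l <- line3(c(0, 5, 0), c(0, 1, 0))
  expect_equal(point_line_distance(c(0, -3, 0), l), 0)
  expect_equal(point_line_distance(c(3, 5, 4), l), 5)
  set.seed(21)
  for (k in 1:20) {
    a <- stats::rnorm(3, sd = 5); d <- rand_unit(); p <- stats::rnorm(3, sd = 5)
    l1 <- line3(a, d)
    l2 <- line3(a + 3.7 * d, -d)            # flipped, slid anchor
    dist_oracle <- sqrt(stats::optimize(function(t) sum((p - (a + t * d))^2),
                                        c(-1e3, 1e3), tol = 1e-12)$objective)
    expect_equal(point_line_distance(p, l1), dist_oracle, tolerance = 1e-8)
    expect_equal(point_line_distance(p, l1), point_line_distance(p, l2),
                 tolerance = 1e-12)
  }
})

test_that("line-plane intersection lies on both objects and rejects parallels", {
  expect_equal(line_plane_intersection(line3(c(0, 0, 5), c(0, 0, 1)),
                                       plane3(c(0, 0, -80), c(0, 0, 1))),
               c(0, 0, -80))
  expect_error(line_plane_intersection(line3(c(0, 0, 0), c(1, 0, 0)),
                                       plane3(c(0, 0, -80), c(0, 0, 1))),
               "parallel")
  set.seed(31)
  for (k in 1:20) {
    l <- line3(stats::rnorm(3, sd = 5), rand_unit())
    pl <- plane3(stats::rnorm(3, sd = 5), rand_unit())
    if (abs(sum(l$direction * pl$normal)) < 1e-3) next
    p <- line_plane_intersection(l, pl)
    expect_lt(abs(sum((p - pl$point) * pl$normal)), 1e-9)
    expect_lt(point_line_distance(p, l), 1e-9)
  }
})

test_that("central projection obeys the magnification law and the composition oracle", {
  ns <- nominal_state(0, 0, fix_machine)
  expect_equal(central_projection(ns$source, ns$detector, c(0, 0, 0)), c(0, 0))
  expect_equal(central_projection(ns$source, ns$detector, c(1, 0, 0)),
               c(1.8, 0), tolerance = 1e-12)      # r * SDD / SAD
  set.seed(41)
  for (k in 1:20) {
    p <- c(stats::runif(2, -8, 8), stats::runif(1, -20, 20))
    uv <- central_projection(ns$source, ns$detector, p)
    hit <- line_plane_intersection(line3(ns$source, p - ns$source),
                                   plane3(ns$detector$center, ns$detector$normal))
    rel <- hit - ns$detector$center
    expect_equal(uv, c(sum(rel * ns$detector$u_dir), sum(rel * ns$detector$v_dir)),
                 tolerance = 1e-10)
  }
  expect_error(central_projection(ns$source, ns$detector, ns$source + c(0, 0, 0)),
               "source|parallel")
})

test_that("projection followed by back-projection recovers points on the ray", {
  ns <- nominal_state(30, 60, fix_machine)
  set.seed(43)
  for (k in 1:10) {
    p <- stats::rnorm(3, sd = 6)
    uv <- central_projection(ns$source, ns$detector, p)
    ray <- back_project(ns$source, ns$detector, uv)
    expect_lt(point_line_distance(p, ray), 1e-9)
  }
})

test_that("closest point to lines solves the least-squares problem", {
  l1 <- line3(c(1, 2, 3), c(1, 0, 0))
  l2 <- line3(c(1, 2, 3), c(0, 0, 1))
  expect_equal(closest_point_to_lines(list(l1, l2)), c(1, 2, 3), tolerance = 1e-10)
  expect_error(closest_point_to_lines(list(l1, line3(c(0, 5, 0), c(1, 0, 0)))),
               "parallel")
  expect_error(closest_point_to_lines(list(l1)), "two lines")
  obj <- function(p, lines) sum(vapply(lines, function(l)
    point_line_distance(p, l)^2, numeric(1)))
  set.seed(51)
  for (k in 1:10) {
    lines <- lapply(1:5, function(i) line3(stats::rnorm(3, sd = 4), rand_unit()))
    p <- closest_point_to_lines(lines)
    o <- stats::optim(stats::rnorm(3), obj, lines = lines,
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    expect_equal(p, o$par, tolerance = 1e-4)
    expect_lte(obj(p, lines), o$value + 1e-10)
    cands <- matrix(stats::rnorm(600, sd = 4), 200, 3)
    expect_true(all(obj(p, lines) <= apply(cands, 1, obj, lines = lines) + 1e-12))
  }
})

test_that("Kabsch rotation recovers known rotations and dominates random ones", {
  set.seed(61)
  X <- matrix(stats::rnorm(24, sd = 3), 8, 3)
  expect_equal(optimal_rotation(X, X)$R, diag(3), tolerance = 1e-12)
  R0 <- rand_rotation()
  Y <- X %*% t(R0)
  expect_equal(optimal_rotation(X, Y)$R, R0, tolerance = 1e-10)
  # noisy: closed form beats random rotations
  Yn <- Y + matrix(stats::rnorm(24, sd = 0.05), 8, 3)
  fit <- optimal_rotation(X, Yn)
  resid_of <- function(R) {
    Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Yn, 2, colMeans(Yn))
    sum((Yc - Xc %*% t(R))^2)
  }
  best_rand <- min(vapply(1:500, function(i) resid_of(rand_rotation()), numeric(1)))
  expect_lte(resid_of(fit$R), best_rand)
  # collinear degenerate
  Xc <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(optimal_rotation(Xc, Xc %*% t(R0)), "collinear")
})

test_that("rotation axis extraction leaves the axis invariant", {
  ax <- rotation_axis_of(rotation_about_axis(line3(c(0, 0, 0), c(0, 1, 0)), 30)$R)
  expect_equal(ax$axis, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(ax$angle_deg, 30, tolerance = 1e-10)
  expect_error(rotation_axis_of(diag(3)), "identity")
  set.seed(71)
  for (k in 1:20) {
    R <- rand_rotation()
    a <- rotation_axis_of(R)$axis
    expect_lt(max(abs(drop(R %*% a) - a)), 1e-9)
    expect_gte(sum(a * c(0, 1, 0)), -1e-12)   # canonical hemisphere
  }
  # near-180-degree rotations use the stable branch
  R <- rotation_about_axis(line3(c(0, 0, 0), c(1, 1, 0)), 179.9995)$R
  a <- rotation_axis_of(R, reference = c(1, 1, 0))
  expect_lt(max(abs(drop(R %*% a$axis) - a$axis)), 1e-4)
})

test_that("extrinsic mean minimizes the chordal cost on the sphere", {
  v <- rand_unit()
  expect_equal(extrinsic_mean_directions(rbind(v, v, v)), v, tolerance = 1e-12)
  e <- 1e-3
  expect_equal(extrinsic_mean_directions(rbind(c(sin(e), cos(e), 0),
                                               c(-sin(e), cos(e), 0))),
               c(0, 1, 0), tolerance = 1e-12)
  expect_error(extrinsic_mean_directions(rbind(c(0, 0, 1), c(0, 0, -1))),
               "antipodal|cancel")
  set.seed(81)
  D <- t(vapply(1:50, function(i) unit3(c(0.2, 1, -0.1) + stats::rnorm(3, sd = 0.3)),
                numeric(3)))
  m <- extrinsic_mean_directions(D)
  cost <- function(ang) {
    v <- c(cos(ang[1]) * cos(ang[2]), cos(ang[1]) * sin(ang[2]), sin(ang[1]))
    sum(sweep(D, 2, v)^2)
  }
  o <- stats::optim(c(asin(m[3]), atan2(m[2], m[1])), cost,
                    control = list(reltol = 1e-15, maxit = 2000))
  vo <- c(cos(o$par[1]) * cos(o$par[2]), cos(o$par[1]) * sin(o$par[2]), sin(o$par[1]))
  expect_equal(m, vo, tolerance = 1e-6)
})

test_that("rotations conserve pairwise distances", {
  set.seed(91)
  pts <- matrix(stats::rnorm(30, sd = 5), 10, 3)
  for (k in 1:5) {
    rot <- rotation_about_axis(line3(stats::rnorm(3), rand_unit()),
                               stats::runif(1, 0, 360))
    d0 <- stats::dist(pts)
    d1 <- stats::dist(rotate_points(rot, pts))
    expect_lt(max(abs(d0 - d1)), 1e-10)
  }
})

test_that("lines generated by rotating one line about a common axis meet on that axis", {
  set.seed(95)
  axis <- line3(c(0.5, -1, 2), rand_unit())
  base <- line3(axis$point + c(3, 0, 1), rand_unit())
  lines <- lapply(seq(0, 300, by = 60), function(a) {
    rot <- rotation_about_axis(axis, a)
    line3(rotate_points(rot, base$point),
          rotate_points(rot, base$point + base$direction) -
            rotate_points(rot, base$point))
  })
  p <- closest_point_to_lines(lines)
  expect_lt(point_line_distance(p, axis), 1e-9)
})
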