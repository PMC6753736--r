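# Reconstruction chain: exact recovery on noise-free data, error guards,
# estimator properties.

test_that("camera resection recovers the exact geometry from noise-free data", {
  for (psi in c(-180, -135, -45, 0, 90)) {
    rec <- simulate_image(20, psi, fix_table, fix_coll, fix_machine, 0)
    cam <- resect_camera(rec, fix_table, fix_machine)
    ns <- nominal_state(20, psi, fix_machine)
    expect_lt(max(abs(cam$source - ns$source)), 1e-6)
    expect_lt(min(max(abs(cam$detector$normal - ns$beam_dir)),
                  max(abs(cam$detector$normal + ns$beam_dir))), 1e-8)
    expect_equal(cam$sdd, 180, tolerance = 1e-8)
    expect_lt(cam$rms, 1e-8)
  }
})

test_that("resection rejects under-determined and degenerate marker sets", {
  rec <- simulate_image(0, 0, fix_table, fix_coll, fix_machine, 0)
  expect_error(linacqa:::resect(linacqa:::module_positions(fix_table, 0, 0)[1:5, ],
                                rec$table_uv[1:5, ], 0, fix_machine),
               "at least 6")
  flatX <- cbind(stats::rnorm(6, sd = 3), stats::rnorm(6, sd = 3), 0)
  expect_error(linacqa:::resect(flatX, rec$table_uv, 0, fix_machine),
               "coplanar")
})

test_that("resection residual matches the degrees-of-freedom budget", {
  # 12 observations, 9 parameters: E[sum r^2] = 3 sigma^2,
  # reported rms = sqrt(cost / 12) ~ sigma / 2
  sig <- 0.02
  set.seed(123)
  rms <- replicate(150, {
    rec <- simulate_image(0, 45, fix_table, fix_coll, fix_machine, sig * 10)
    resect_camera(rec, fix_table, fix_machine)$rms
  })
  expect_lt(abs(sqrt(mean(rms^2)) / (sig * 0.5) - 1), 0.2)
})

test_that("module pose is exact on noise-free data and guards small marker sets", {
  rec <- simulate_image(130, -45, fix_table, fix_coll, fix_machine, 0)
  cam <- resect_camera(rec, fix_table, fix_machine)
  pose <- estimate_module_pose(rec, cam, fix_coll)
  tru <- linacqa:::module_positions(fix_coll, 130, -45)
  expect_lt(max(abs(pose$positions - tru)), 1e-6)
  expect_error(linacqa:::pnp_pose(fix_coll$centers[1:3, ], rec$coll_uv[1:3, ],
                                  cam$P, diag(3), c(0, 0, 20)),
               "at least 4")
})

test_that("noisy pose reprojection residual is at most the truth-pose residual", {
  set.seed(77)
  rec <- simulate_image(45, 30, fix_table, fix_coll, fix_machine, 0.3)
  cam <- resect_camera(rec, fix_table, fix_machine)
  pose <- estimate_module_pose(rec, cam, fix_coll)
  proj <- function(X) {
    Xh <- cbind(X, 1)
    z <- drop(Xh %*% cam$P[3, ])
    cbind(drop(Xh %*% cam$P[1, ]) / z, drop(Xh %*% cam$P[2, ]) / z)
  }
  resid_truth <- sum((rec$coll_uv - proj(linacqa:::module_positions(fix_coll, 45, 30)))^2)
  resid_fit <- sum((rec$coll_uv - proj(pose$positions))^2)
  expect_lte(resid_fit, resid_truth + 1e-12)
})

test_that("collimator axis is exact on noise-free data and needs two angles", {
  thetas <- c(-165, -90, 0, 90, 165)
  psi <- 40
  recs <- lapply(thetas, simulate_image, psi = psi, table = fix_table,
                 collimator = fix_coll, machine = fix_machine, sigma_mm = 0)
  cams <- lapply(recs, resect_camera, table_geometry = fix_table,
                 machine = fix_machine)
  configs <- Map(function(r, c) estimate_module_pose(r, c, fix_coll)$positions,
                 recs, cams)
  beam <- c(sin(psi * pi / 180), 0, cos(psi * pi / 180))
  axis <- estimate_collimator_axis(configs, ref_dir = beam)
  expect_lt(max(abs(axis$direction - beam)), 1e-7)
  expect_lt(point_line_distance(nominal_state(0, psi, fix_machine)$source, axis), 1e-6)
  expect_lt(point_line_distance(c(0, 0, 0), axis), 1e-6)
  expect_error(estimate_collimator_axis(configs[1]), "two distinct")
})

test_that("isocenter estimation is the closest point to the axes", {
  axes <- list(line3(c(0, 0, 0), c(0, 0, 1)), line3(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(estimate_isocenter(axes), c(0, 0, 0))
  expect_error(estimate_isocenter(list(line3(c(0, 0, 0), c(0, 0, 1)),
                                       line3(c(1, 0, 0), c(0, 0, 1)))),
               "parallel")
})

test_that("gantry axis recovery: exact data, skew ground truth, guard", {
  set.seed(31)
  base <- matrix(stats::rnorm(30, sd = 5), 10, 3)
  skew_axis <- unit3(c(0.1, 1, -0.05))
  cols <- lapply(seq(0, 240, by = 60), function(a)
    rotate_points(rotation_about_axis(line3(c(0, 0, 0), skew_axis), a), base))
  expect_lt(max(abs(estimate_gantry_axis(cols) - skew_axis)), 1e-8)
  expect_error(estimate_gantry_axis(cols[1]), "two gantry")
})

test_that("gantry angle estimate is the signed angle from vertical", {
  expect_equal(estimate_gantry_angle(c(0, 0, 1)), 0)
  expect_equal(estimate_gantry_angle(c(1, 0, 0)), 90)
  expect_equal(estimate_gantry_angle(c(-1, 0, 0)), -90)
  expect_equal(estimate_gantry_angle(c(sin(2.4), 0, cos(2.4))), 2.4 * 180 / pi,
               tolerance = 1e-10)
})

test_that("SAD and SDD estimators match independent constructions", {
  axis <- line3(c(0, 0, 0), c(0, 0, 1))
  expect_equal(estimate_sad(c(0, 0, 100), axis, c(0, 0, 0)), 100)
  expect_equal(estimate_sad(c(0, 0, 105), axis, c(0, 0, 0)), 105)
  set.seed(41)
  for (k in 1:10) {
    src <- stats::rnorm(3, sd = 50)
    d <- rand_unit()
    iso <- stats::rnorm(3, sd = 2)
    # oracle: foot of the perpendicular via plane intersection
    H <- plane3(iso, d)
    foot <- line_plane_intersection(line3(src, d), H)
    expect_equal(estimate_sad(src, line3(iso + 3 * d, d), iso),
                 sqrt(sum((src - foot)^2)), tolerance = 1e-10)
    pl <- plane3(stats::rnorm(3, sd = 20), rand_unit())
    expect_equal(estimate_sdd(src, pl),
                 sqrt(sum((src - line_plane_intersection(line3(src, pl$normal), pl))^2)),
                 tolerance = 1e-10)
  }
})

test_that("field reconstruction returns the nominal square from exact data", {
  rec <- simulate_image(25, -60, fix_table, fix_coll, fix_machine, 0)
  cam <- resect_camera(rec, fix_table, fix_machine)
  beam <- c(sin(-60 * pi / 180), 0, cos(-60 * pi / 180))
  fr <- reconstruct_field(rec$corner_uv, cam, beam, c(0, 0, 0),
                          nominal_corners = nominal_state(25, -60, fix_machine)$corners3d)
  expect_equal(fr$edge_lengths, rep(20, 4), tolerance = 1e-8)
  expect_equal(fr$corner_angles, rep(90, 4), tolerance = 1e-8)
  expect_lt(max(fr$corner_deviations), 1e-8)
  # rotation invariance: a different collimator angle gives the same shape
  rec2 <- simulate_image(115, -60, fix_table, fix_coll, fix_machine, 0)
  fr2 <- reconstruct_field(rec2$corner_uv, resect_camera(rec2, fix_table, fix_machine),
                           beam, c(0, 0, 0))
  expect_equal(fr2$edge_lengths, fr$edge_lengths, tolerance = 1e-8)
  expect_equal(fr2$corner_angles, fr$corner_angles, tolerance = 1e-8)
})

test_that("full-plan reconstruction is exact at sigma = 0 for varied configurations", {
  configs <- list(
    list(plan = plan_of(5, 5, 0), tab = fix_table, col = fix_coll, m = fix_machine),
    list(plan = plan_of(9, 9, 0), tab = planar_layout(8, 8, "table"),
         col = planar_layout(6, 6, "collimator"), m = fix_machine))
  for (cf in configs) {
    recon <- reconstruct_plan(simulate_plan(cf$plan, cf$tab, cf$col), cf$tab,
                              cf$col, cf$m)
    em <- compute_error_metrics(recon)
    expect_lt(max(abs(em$alpha)), 1e-6)
    expect_lt(em$theta, 1e-6)
    expect_lt(em$l, 1e-6)
    expect_lt(max(abs(em$dSAD)), 1e-6)
    expect_lt(max(abs(em$dSDD)), 1e-6)
    expect_lt(max(abs(em$omega)), 1e-6)
    expect_lt(max(abs(em$L)), 1e-6)
  }
})

test_that("reconstruction never reads the truth blocks", {
  plan <- plan_of(5, 5, 0.2)
  set.seed(17)
  recs <- simulate_plan(plan, fix_table, fix_coll)
  recon1 <- reconstruct_plan(recs, fix_table, fix_coll, fix_machine)
  corrupted <- lapply(recs, function(r) {
    r$truth <- list(table_uv = r$truth$table_uv * NA, source = c(9e9, 0, 0))
    r
  })
  recon2 <- reconstruct_plan(corrupted, fix_table, fix_coll, fix_machine)
  expect_identical(recon1$isocenter, recon2$isocenter)
  expect_identical(recon1$sad_img, recon2$sad_img)
  expect_identical(recon1$alpha_est, recon2$alpha_est)
})

test_that("error dispersion scales about linearly in sigma for small sigma", {
  sds1 <- pooled_sds(plan_of(5, 5, 0.1), fix_table, fix_coll, 60, 101)
  sds2 <- pooled_sds(plan_of(5, 5, 0.2), fix_table, fix_coll, 60, 102)
  for (m in c("s", "L", "alpha", "dSAD")) {
    expect_gt(sds2[[m]] / sds1[[m]], 1.5)
    expect_lt(sds2[[m]] / sds1[[m]], 2.6)
  }
})

test_that("SDD recovery honours the configured nominal (large-phantom setup)", {
  m140 <- machine_constants(SDD = 140)
  big_t <- spiral_layout(18, c(26, 18, 26))
  big_c <- planar_layout(8, 6, "collimator", max_per_plane = 4L)
  plan <- test_plan(c(-90, 0, 90), c(0, 90), 0, m140)
  expect_true(validate_configuration(big_t, big_c, plan)$valid)
  recon <- reconstruct_plan(simulate_plan(plan, big_t, big_c), big_t, big_c, m140)
  expect_equal(mean(recon$sdd_img), 140, tolerance = 1e-8)
  expect_lt(max(abs(compute_error_metrics(recon)$dSAD)), 1e-6)
})
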