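# Shared fixtures and small random-instance generators (all built in code).

fix_machine <- machine_constants()
fix_table <- planar_layout(6, 8, "table")
fix_coll <- planar_layout(4, 6, "collimator")

plan_of <- function(n_gantry, n_coll, sigma_mm, machine = fix_machine)
  test_plan(gantry_angle_grid(n_gantry), collimator_angle_grid(n_coll),
            sigma_mm, machine)

# a tiny plan whose three gantry directions are distinct (the symmetric
# grid with n = 3 has +/-180 deg coinciding, leaving all axes parallel)
small_plan <- function(sigma_mm, n_coll = 2, machine = fix_machine)
  test_plan(c(-90, 0, 90), collimator_angle_grid(n_coll), sigma_mm, machine)

rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v * v))
}

rand_rotation <- function(angle_deg = stats::runif(1, 5, 175)) {
  rotation_about_axis(line3(c(0, 0, 0), rand_unit()), angle_deg)$R
}

# pooled error-metric SDs over replicates of one configuration
pooled_sds <- function(plan, table, coll, n_rep, seed) {
  res <- run_experiment(experiment_config(plan, table, coll, n_rep, seed))
  stats::setNames(res$summary$sd, res$summary$metric)
}
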