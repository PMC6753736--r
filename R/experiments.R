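# Monte Carlo engine: error distributions of the reconstructed geometric
# quantities as a function of test-plan design, phantom design and noise.

#' Experiment configuration
#'
#' The tuple (test plan, phantom modules, noise, replicate count, seed) that
#' conditions the sampling distribution of every reconstructed quantity.
#'
#' @param plan a [test_plan()] (carries sigma and the machine constants).
#' @param table,collimator [phantom_module()] objects.
#' @param n_replicates number of independent replicates (>= 2).
#' @param seed integer seed; every random draw of the experiment derives
#'   from it.
#' @param include_sources passed to [reconstruct_plan()].
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(plan, table, collimator, n_replicates, seed = 1L,
                              include_sources = TRUE) {
  stopifnot(inherits(plan, "test_plan"), inherits(table, "phantom_module"),
            inherits(collimator, "phantom_module"))
  if (!is.numeric(n_replicates) || n_replicates < 2L)
    stop("n_replicates must be at least 2")
  structure(list(plan = plan, table = table, collimator = collimator,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 include_sources = isTRUE(include_sources)),
            class = "experiment_config")
}

#' Error metrics of one reconstructed replicate
#'
#' Differences between reconstructed and nominal values of every controlled
#' quantity:
#' * `alpha` (deg, one per gantry angle): estimated minus nominal angle
#'   between the collimator rotation axis and the vertical;
#' * `theta` (deg, scalar, >= 0): angle between estimated and nominal gantry
#'   rotation axis;
#' * `omega` (deg, 4 per image): field corner angles minus 90;
#' * `L` (cm, 4 per image): field edge lengths minus nominal;
#' * `s` (cm, 3): components of the isocenter position;
#' * `l` (cm, scalar, >= 0): distance of the isocenter from the origin;
#' * `dSAD`, `dSDD` (cm, one per image): estimated minus nominal distances.
#'
#' @param recon a `reconstructed_geometry` from [reconstruct_plan()].
#' @param machine nominal machine constants (defaults to the ones stored in
#'   `recon`).
#' @return object of class `error_sample` (a list of the vectors above).
#' @export
compute_error_metrics <- function(recon, machine = recon$machine) {
  stopifnot(inherits(recon, "reconstructed_geometry"))
  alpha <- wrap_angle(recon$alpha_est - recon$psis)
  theta <- angle_between(recon$gantry_axis, c(0, 1, 0))
  omega <- as.vector(recon$corner_angles - 90)
  L <- as.vector(recon$edge_lengths - machine$field_size[1L])
  s <- as.numeric(recon$isocenter)
  structure(list(alpha = alpha, theta = theta, omega = omega, L = L,
                 s = s, l = vnorm(s),
                 dSAD = recon$sad_img - machine$SAD,
                 dSDD = recon$sdd_img - machine$SDD),
            class = "error_sample")
}

METRIC_UNITS <- c(alpha = "deg", theta = "deg", omega = "deg", L = "cm",
                  s = "cm", l = "cm", dSAD = "cm", dSDD = "cm")

#' Sample standard deviation with a chi-squared confidence interval
#'
#' @param x numeric sample (n >= 2).
#' @param conf confidence level (default 0.95).
#' @return list with `sd`, `ci_low`, `ci_high`, `n`.  With more than one
#'   thousand values the half-width is about +/- 4-5% of the SD.
#' @export
summarize_sd <- function(x, conf = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) stop("need at least two values to estimate a standard deviation")
  s <- stats::sd(x)
  a <- (1 - conf) / 2
  list(sd = s,
       ci_low = s * sqrt((n - 1) / stats::qchisq(1 - a, n - 1)),
       ci_high = s * sqrt((n - 1) / stats::qchisq(a, n - 1)),
       n = n)
}

#' Run a Monte Carlo experiment
#'
#' For each replicate: simulate the plan, reconstruct the geometry, compute
#' the error metrics.  Pools each metric over replicates (and over gantry
#' angles / images / corners / components where the metric has several
#' values per replicate) and summarizes its standard deviation with a
#' chi-squared confidence interval.  Deterministic given the seed; replicate
#' sub-seeds are drawn up front so replicates are independent.
#'
#' Replicates whose reconstruction fails are excluded and counted; more than
#' 1% failures aborts with diagnostics.
#'
#' @param config an [experiment_config()].
#' @param keep_samples keep the per-replicate `error_sample` list (default
#'   TRUE).
#' @param progress print a dot every 50 replicates.
#' @return object of class `experiment_result`: `summary` data frame (one
#'   row per metric: sd, ci, n), `pooled` list of pooled metric vectors,
#'   `samples` (optional), `n_failed`.
#' @export
run_experiment <- function(config, keep_samples = FALSE, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  nrep <- config$n_replicates
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, nrep)
  pooled <- list(alpha = vector("list", nrep), theta = vector("list", nrep),
                 omega = vector("list", nrep), L = vector("list", nrep),
                 s = vector("list", nrep), l = vector("list", nrep),
                 dSAD = vector("list", nrep), dSDD = vector("list", nrep))
  samples <- if (keep_samples) vector("list", nrep) else NULL
  failures <- character(0)
  for (r in seq_len(nrep)) {
    set.seed(rep_seeds[r])
    es <- tryCatch({
      recs <- simulate_plan(config$plan, config$table, config$collimator)
      recon <- reconstruct_plan(recs, config$table, config$collimator,
                                config$plan$machine,
                                include_sources = config$include_sources)
      compute_error_metrics(recon)
    }, error = function(e) e)
    if (inherits(es, "error")) {
      failures <- c(failures, conditionMessage(es))
      next
    }
    for (m in names(pooled)) pooled[[m]][[r]] <- es[[m]]
    if (keep_samples) samples[[r]] <- es
    if (progress && r %% 50L == 0L) cat(".")
  }
  if (progress) cat("\n")
  n_failed <- length(failures)
  if (n_failed > 0.01 * nrep)
    stop("more than 1% of replicates failed to reconstruct (", n_failed,
         " of ", nrep, "); first error: ", failures[1L])
  pooled <- lapply(pooled, function(v) unlist(v, use.names = FALSE))
  summ <- do.call(rbind, lapply(names(pooled), function(m) {
    ss <- summarize_sd(pooled[[m]])
    data.frame(metric = m, units = METRIC_UNITS[[m]], sd = ss$sd,
               ci_low = ss$ci_low, ci_high = ss$ci_high, n_values = ss$n,
               n_replicates = nrep - n_failed)
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, pooled = pooled, samples = samples,
                 n_failed = n_failed, config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Monte Carlo experiment:", x$config$n_replicates, "replicates,",
      nrow(x$config$plan$pairs), "images/replicate, sigma =",
      x$config$plan$sigma_mm, "mm\n")
  if (x$n_failed > 0L) cat("  excluded failed replicates:", x$n_failed, "\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Empirical tail probability of a measured deviation
#'
#' The empirical probability, under the correctly-functioning-device
#' distribution represented by `samples`, that the absolute deviation from
#' the nominal value is at least `delta`.
#'
#' @param samples Monte Carlo samples of the measured quantity.
#' @param nominal nominal value of the quantity.
#' @param delta observed absolute deviation.
#' @return probability in `[0, 1]`.
#' @export
tail_probability <- function(samples, nominal, delta) {
  samples <- samples[is.finite(samples)]
  if (length(samples) == 0L) stop("empty sample")
  if (length(samples) < 100L)
    warning("fewer than 100 samples: tail probability is unreliable")
  mean(abs(samples - nominal) >= delta)
}

#' Tolerated difference for a tail-probability threshold
#'
#' The deviation `Delta_TH` whose tail probability equals `pr_th`: the
#' `(1 - pr_th)` empirical quantile of the absolute deviations.  Satisfies
#' `tail_probability(samples, nominal, Delta_TH) ~ pr_th` within 1/n.
#'
#' @param samples Monte Carlo samples of the measured quantity.
#' @param nominal nominal value.
#' @param pr_th tail-probability threshold in (0, 1).
#' @return tolerated difference, same units as the samples.
#' @export
tolerance_threshold <- function(samples, nominal, pr_th) {
  if (!is.numeric(pr_th) || length(pr_th) != 1L || pr_th <= 0 || pr_th >= 1)
    stop("pr_th must lie strictly between 0 and 1")
  samples <- samples[is.finite(samples)]
  if (length(samples) == 0L) stop("empty sample")
  if (length(samples) < 100L)
    warning("fewer than 100 samples: threshold is unreliable")
  unname(stats::quantile(abs(samples - nominal), probs = 1 - pr_th, type = 1L))
}
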