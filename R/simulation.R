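#' Define a Monte-Carlo scenario
#'
#' A scenario pairs two generative [distribution_spec]s with sample sizes, the
#' set of tests to run, and the Monte-Carlo settings used to estimate each
#' test's rejection rate (statistical power, or the type-I error rate when the
#' two specs are identical).
#'
#' @param spec1,spec2 [distribution_spec] objects for the two samples.
#' @param m,n Sample sizes, at least 1.
#' @param tests Character vector, subset of
#'   `c("ART", "WU2", "pWU2", "WW", "pWW", "Rsf")`.
#' @param n_replicates Number of Monte-Carlo replicates.
#' @param n_permutations Permutations per permutation test.
#' @param level Significance level in (0, 1); a test rejects when
#'   `p <= level`.
#' @param seed Integer master seed; every replicate derives its own RNG
#'   substream from `(seed, id, replicate)`.
#' @param id Scenario identifier string (auto-generated if omitted).
#' @return An object of class `scenario`.
#' @examples
#' scenario(distribution_spec("von_mises", mu = 0, kappa = 2),
#'          distribution_spec("von_mises", mu = 0, kappa = 2),
#'          m = 10, n = 10, tests = "ART",
#'          n_replicates = 100, n_permutations = 199, seed = 1)
#' @export
scenario <- function(spec1, spec2, m, n, tests = TEST_NAMES,
                     n_replicates = 1000, n_permutations = 999,
                     level = 0.05, seed = 1L, id = NULL) {
  stopifnot(inherits(spec1, "distribution_spec"),
            inherits(spec2, "distribution_spec"))
  if (m < 1 || n < 1) stop("`m` and `n` must be >= 1", call. = FALSE)
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("`level` must lie in (0, 1)", call. = FALSE)
  }
  bad <- setdiff(tests, TEST_NAMES)
  if (length(bad)) {
    stop("unknown tests: ", paste(bad, collapse = ", "),
         "; valid names: ", paste(TEST_NAMES, collapse = ", "), call. = FALSE)
  }
  if (is.null(id)) {
    id <- sprintf("%s_vs_%s_m%d_n%d", format(spec1), format(spec2), m, n)
  }
  structure(list(spec1 = spec1, spec2 = spec2, m = as.integer(m),
                 n = as.integer(n), tests = tests,
                 n_replicates = as.integer(n_replicates),
                 n_permutations = as.integer(n_permutations),
                 level = level, seed = as.integer(seed), id = id),
            class = "scenario")
}

# Deterministic 31-bit substream seed from (master seed, scenario id,
# replicate index), so results do not depend on execution order.
substream_seed <- function(seed, id, replicate) {
  h <- 0
  for (k in utf8ToInt(id)) h <- (h * 31 + k) %% 2147483647
  as.integer((h + seed * 7919 + replicate * 1000003) %% 2147483647)
}

#' Monte-Carlo standard error of a rejection-rate estimate
#'
#' @param rate Estimated rejection rate in \[0, 1\].
#' @param n_replicates Number of replicates behind the estimate.
#' @return `sqrt(rate * (1 - rate) / n_replicates)`.
#' @export
mc_standard_error <- function(rate, n_replicates) {
  sqrt(rate * (1 - rate) / n_replicates)
}

#' 95% binomial confidence half-width for a rejection rate
#'
#' The half-width `1.96 * sqrt(rate * (1 - rate) / n_replicates)` of the
#' normal-approximation 95% confidence interval for a Monte-Carlo rejection
#' rate; e.g. at a rate of 0.05 with 10,000 replicates the half-width is about
#' 0.0043, so estimates are accurate to within 0.005.
#'
#' @param rate Rejection rate, strictly inside (0, 1).
#' @param n_replicates Number of replicates, at least 1.
#' @return The half-width, a single non-negative number.
#' @examples
#' binomial_ci_halfwidth(0.05, 10000)
#' @export
binomial_ci_halfwidth <- function(rate, n_replicates) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) ||
      rate <= 0 || rate >= 1) {
    stop("`rate` must lie strictly in (0, 1)", call. = FALSE)
  }
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  1.96 * mc_standard_error(rate, n_replicates)
}

#' Estimate rejection rates for one scenario
#'
#' For each replicate, draws sample 1 from `spec1` (size `m`) and sample 2
#' from `spec2` (size `n`), runs every requested test, and records whether its
#' p-value falls at or below `level`. Permutation tests share one stream of
#' random relabellings per replicate. Fully deterministic given the scenario
#' seed: each replicate runs on its own derived RNG substream.
#'
#' @param scn A [scenario].
#' @return A data frame with one row per test: `scenario_id`, `test`, `rate`,
#'   `mc_se`, `n_replicates`, `n_permutations`, `level`.
#' @examples
#' sp <- distribution_spec("von_mises", mu = 0, kappa = 2)
#' estimate_rejection_rate(scenario(sp, sp, 10, 10, tests = "ART",
#'                                  n_replicates = 50, n_permutations = 99,
#'                                  seed = 1))
#' @export
estimate_rejection_rate <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  tests <- scn$tests
  perm_tests <- intersect(tests, c("ART", "pWU2", "pWW", "Rsf"))
  rej <- setNames(numeric(length(tests)), tests)
  np <- scn$n_permutations
  for (r in seq_len(scn$n_replicates)) {
    set.seed(substream_seed(scn$seed, scn$id, r))
    a <- as.numeric(sample_angles(scn$spec1, scn$m))
    b <- as.numeric(sample_angles(scn$spec2, scn$n))
    if (length(perm_tests)) {
      eng <- perm_engine(a, b, np, seed = NULL,
                         art = "ART" %in% perm_tests,
                         wu2 = "pWU2" %in% perm_tests,
                         ww = "pWW" %in% perm_tests,
                         rsf = "Rsf" %in% perm_tests)
      key <- c(ART = "ART", pWU2 = "WU2", pWW = "WW", Rsf = "Rsf")
      for (t in perm_tests) {
        p <- (eng$n_exceeding[[key[[t]]]] + 1) / (np + 1)
        if (p <= scn$level) rej[t] <- rej[t] + 1
      }
    }
    if ("WU2" %in% tests) {
      p <- watson_u2_pvalue_asymptotic(watson_u2_statistic(a, b))
      if (p <= scn$level) rej["WU2"] <- rej["WU2"] + 1
    }
    if ("WW" %in% tests) {
      p <- watson_wheeler_statistic(a, b)$p_value
      if (p <= scn$level) rej["WW"] <- rej["WW"] + 1
    }
  }
  rate <- rej / scn$n_replicates
  data.frame(scenario_id = scn$id, test = tests, rate = unname(rate),
              mc_se = unname(mc_standard_error(rate, scn$n_replicates)),
              n_replicates = scn$n_replicates,
              n_permutations = scn$n_permutations, level = scn$level,
              row.names = NULL, stringsAsFactors = FALSE)
}

#' Configure a simulation grid
#'
#' Describes one sweep in the simulation study design: a study type, a family,
#' the swept parameter values, and the sample-size pairs. The three study
#' types mirror the standard designs for evaluating two-sample circular
#' tests:
#'
#' * `"null"` — both samples from the identical distribution; the sweep sets
#'   the shared concentration `kappa` (von Mises families) or dispersion
#'   `rho` (wrapped skew-normal, shape `alpha = 30`). Estimates type-I error.
#' * `"dispersion"` — sample 1 fixed at the most dispersed member
#'   (`kappa = 0`, or `rho = 1`), sample 2 swept over `kappa` (0 to 8) or
#'   `rho` (1 to 4).
#' * `"shift"` — both samples share a common shape (`kappa = 2`, or
#'   `rho = 2, alpha = 30`); sample 2's location is rotated by the swept shift
#'   in degrees (0 to 180; for the axial family the shift is the displacement
#'   between mode axes, 0 to 90).
#'
#' @param study `"null"`, `"dispersion"` or `"shift"`.
#' @param family `"von_mises"`, `"axial_von_mises"` or
#'   `"wrapped_skew_normal"`.
#' @param sweep Numeric vector of swept parameter values; `NULL` for the
#'   study's default grid.
#' @param sizes List of `c(m, n)` pairs; default
#'   `(10,10), (20,20), (50,50), (10,50), (50,10)`.
#' @param tests Tests to run (default all six).
#' @param n_replicates,n_permutations Monte-Carlo scale; defaults 1000 and
#'   999. `paper_scale = TRUE` restores 10000 / 10000.
#' @param level Significance level (default 0.05).
#' @param seed Master seed.
#' @param paper_scale Logical; use the full-scale replicate and permutation
#'   counts.
#' @return A list of class `grid_config`.
#' @examples
#' grid_config("shift", "von_mises", sweep = c(0, 90, 180),
#'             sizes = list(c(10, 10)), tests = "ART",
#'             n_replicates = 100, n_permutations = 199, seed = 1)
#' @export
grid_config <- function(study = c("null", "dispersion", "shift"),
                        family = c("von_mises", "axial_von_mises",
                                   "wrapped_skew_normal"),
                        sweep = NULL, sizes = NULL, tests = TEST_NAMES,
                        n_replicates = 1000, n_permutations = 999,
                        level = 0.05, seed = 1L, paper_scale = FALSE) {
  study <- match.arg(study)
  family <- match.arg(family)
  if (is.null(sweep)) {
    sweep <- switch(study,
      null = if (family == "wrapped_skew_normal") c(1, 2, 4) else c(0, 2, 8),
      dispersion = if (family == "wrapped_skew_normal")
        c(1, 1.5, 2, 3, 4) else c(0, 1, 2, 4, 8),
      shift = if (family == "axial_von_mises")
        c(0, 15, 30, 45, 60, 75, 90) else c(0, 30, 60, 90, 120, 150, 180))
  }
  if (!is.numeric(sweep) || !length(sweep)) {
    stop("`sweep` must be a non-empty numeric vector", call. = FALSE)
  }
  if (is.null(sizes)) {
    sizes <- list(c(10, 10), c(20, 20), c(50, 50), c(10, 50), c(50, 10))
  }
  if (!is.list(sizes) || !all(vapply(sizes, length, 1L) == 2L)) {
    stop("`sizes` must be a list of c(m, n) pairs", call. = FALSE)
  }
  if (paper_scale) {
    n_replicates <- 10000
    n_permutations <- 10000
  }
  structure(list(study = study, family = family, sweep = sweep, sizes = sizes,
                 tests = tests, n_replicates = n_replicates,
                 n_permutations = n_permutations, level = level,
                 seed = as.integer(seed)),
            class = "grid_config")
}

# Build the pair of distribution specs for one grid point.
grid_specs <- function(study, family, value) {
  wsn <- family == "wrapped_skew_normal"
  axial <- family == "axial_von_mises"
  mk <- function(...) {
    if (wsn) distribution_spec(family, xi = list(...)$xi, rho = list(...)$rho,
                               alpha = 30)
    else distribution_spec(family, mu = list(...)$mu, kappa = list(...)$kappa)
  }
  switch(study,
    null = if (wsn) list(mk(xi = 0, rho = value), mk(xi = 0, rho = value))
           else list(mk(mu = 0, kappa = value), mk(mu = 0, kappa = value)),
    dispersion =
      if (wsn) list(mk(xi = 0, rho = 1), mk(xi = 0, rho = value))
      else list(mk(mu = 0, kappa = 0), mk(mu = 0, kappa = value)),
    shift = {
      shift_rad <- value * pi / 180
      if (wsn) list(distribution_spec(family, xi = 0, rho = 2, alpha = 30),
                    distribution_spec(family, xi = shift_rad, rho = 2,
                                      alpha = 30))
      else list(mk(mu = 0, kappa = 2), mk(mu = shift_rad, kappa = 2))
    })
}

#' Run a simulation grid
#'
#' Expands a [grid_config] into the cross product of sweep values and sample
#' sizes, estimates rejection rates for every scenario, and returns one tidy
#' row per (scenario point, test). Rows are ordered by sweep value, then size
#' pair, then test. Deterministic given the config (replicate-level RNG
#' substreams are derived from the master seed and scenario id).
#'
#' @param config A [grid_config].
#' @param progress Logical; report per-scenario progress on standard error.
#' @return A data frame with columns `scenario_id`, `study`, `family`,
#'   `spec1`, `spec2`, `sweep_value`, `m`, `n`, `test`, `rate`, `mc_se`,
#'   `n_replicates`, `n_permutations`, `level`, `seed`.
#' @examples
#' cfg <- grid_config("null", "von_mises", sweep = 2, sizes = list(c(8, 8)),
#'                    tests = "ART", n_replicates = 50, n_permutations = 99,
#'                    seed = 1)
#' run_grid(cfg, progress = FALSE)
#' @export
run_grid <- function(config, progress = TRUE) {
  stopifnot(inherits(config, "grid_config"))
  rows <- list()
  for (value in config$sweep) {
    specs <- grid_specs(config$study, config$family, value)
    for (sz in config$sizes) {
      id <- sprintf("%s_%s_v%g_m%d_n%d", config$study, config$family,
                    value, sz[1], sz[2])
      scn <- scenario(specs[[1]], specs[[2]], sz[1], sz[2],
                      tests = config$tests,
                      n_replicates = config$n_replicates,
                      n_permutations = config$n_permutations,
                      level = config$level, seed = config$seed, id = id)
      t0 <- proc.time()[["elapsed"]]
      est <- estimate_rejection_rate(scn)
      if (progress) {
        message(sprintf("[run_grid] %s done in %.1fs", id,
                        proc.time()[["elapsed"]] - t0))
      }
      est$study <- config$study
      est$family <- config$family
      est$spec1 <- format(specs[[1]])
      est$spec2 <- format(specs[[2]])
      est$sweep_value <- value
      est$m <- sz[1]
      est$n <- sz[2]
      est$seed <- config$seed
      rows[[length(rows) + 1L]] <- est
    }
  }
  out <- do.call(rbind, rows)
  out[, c("scenario_id", "study", "family", "spec1", "spec2", "sweep_value",
          "m", "n", "test", "rate", "mc_se", "n_replicates",
          "n_permutations", "level", "seed")]
}

#' Plot power curves from a grid result
#'
#' A basic rate-versus-sweep curve per test, faceted by sample-size pair.
#' Requires ggplot2.
#'
#' @param results A data frame from [run_grid].
#' @return A ggplot object.
#' @export
plot_power_curves <- function(results) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  results$sizes <- sprintf("m=%d, n=%d", results$m, results$n)
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$sweep_value, y = .data$rate,
                               colour = .data$test)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~sizes) +
    ggplot2::labs(x = "swept parameter", y = "rejection rate") +
    ggplot2::ylim(0, 1)
}
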