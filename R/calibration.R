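#' Estimate type I error and power of a design by simulation
#'
#' Runs the trial engine under the null and alternative scenarios of a
#' hypothesis pair with the same seed (common random numbers) and returns
#' the positive-conclusion frequencies with Monte Carlo standard errors.
#'
#' @param design A [make_design()] object.
#' @param hypotheses A [hypothesis_pair()].
#' @param reps Replicates per hypothesis (>= 100).
#' @param seed Optional seed, re-used for both hypotheses.
#' @param ... Passed to [operating_characteristics()].
#' @return List with `type1`, `power`, `se_type1`, `se_power`, `reps` and
#'   the two `trial_oc` objects (`oc_h0`, `oc_h1`).
#' @export
estimate_error_rates <- function(design, hypotheses = hypothesis_pair(),
                                 reps = 10000, seed = NULL, ...) {
  stopifnot(reps >= 100)
  oc0 <- operating_characteristics(design, hypotheses$h0, reps = reps,
                                   seed = seed, ...)
  oc1 <- operating_characteristics(design, hypotheses$h1, reps = reps,
                                   seed = seed, ...)
  list(type1 = oc0$prob_positive, power = oc1$prob_positive,
       se_type1 = oc0$se_positive, se_power = oc1$se_positive,
       reps = reps, oc_h0 = oc0, oc_h1 = oc1)
}

#' Calibrate (lambda, gamma) threshold hyperparameters by grid search
#'
#' Evaluates every grid point with common random numbers (same seed), keeps
#' the points whose estimated type I error does not exceed `alpha_max`, and
#' among them returns the one maximising power (ties broken by larger
#' `lambda`, then larger `gamma`). The stand-alone TOP efficacy rule is
#' conventionally calibrated to a 10% cap (its companion toxicity rule
#' removes roughly half of the false positives); complete designs to 5%.
#'
#' @param kind Design kind, see [make_design()].
#' @param lambda_grid,gamma_grid Numeric grids; defaults span
#'   lambda in \[0.5, 1\] and gamma in \[0.5, 2\] at 0.005 resolution (a
#'   long-running batch job — supply coarse grids for interactive use).
#' @param hypotheses A [hypothesis_pair()].
#' @param alpha_max Type I error cap.
#' @param reps Replicates per grid point and hypothesis.
#' @param seed Seed shared across grid points (common random numbers).
#' @param ... Passed to [make_design()] (e.g. custom looks).
#' @return Object of class `calibration_result`: list with `lambda`,
#'   `gamma`, `type1`, `power`, their standard errors, and `grid` (the full
#'   results table).
#' @export
calibrate_design <- function(kind,
                             lambda_grid = seq(0.5, 1, by = 0.005),
                             gamma_grid = seq(0.5, 2, by = 0.005),
                             hypotheses = hypothesis_pair(),
                             alpha_max = 0.05,
                             reps = 1000, seed = NULL, ...) {
  stopifnot(length(lambda_grid) >= 1, length(gamma_grid) >= 1,
            all(lambda_grid > 0), all(lambda_grid <= 1), all(gamma_grid > 0))
  grid <- expand.grid(lambda = lambda_grid, gamma = gamma_grid)
  grid$type1 <- NA_real_
  grid$power <- NA_real_
  for (i in seq_len(nrow(grid))) {
    des <- make_design(kind, lambda = grid$lambda[i], gamma = grid$gamma[i],
                       hypotheses = hypotheses, ...)
    er <- estimate_error_rates(des, hypotheses, reps = reps, seed = seed)
    grid$type1[i] <- er$type1
    grid$power[i] <- er$power
  }
  grid$se <- sqrt(grid$type1 * (1 - grid$type1) / reps)
  adm <- grid[grid$type1 <= alpha_max, , drop = FALSE]
  if (!nrow(adm)) {
    frontier <- grid[order(grid$type1), , drop = FALSE]
    stop(sprintf(paste0("no grid point attains type I error <= %.3f; ",
                        "closest: lambda = %.3f, gamma = %.3f with ",
                        "type1 = %.4f, power = %.4f"),
                 alpha_max, frontier$lambda[1], frontier$gamma[1],
                 frontier$type1[1], frontier$power[1]))
  }
  adm <- adm[order(-adm$power, -adm$lambda, -adm$gamma), , drop = FALSE]
  best <- adm[1, ]
  structure(list(kind = kind, lambda = best$lambda, gamma = best$gamma,
                 type1 = best$type1, power = best$power,
                 se_type1 = best$se,
                 se_power = sqrt(best$power * (1 - best$power) / reps),
                 alpha_max = alpha_max, reps = reps, seed = seed,
                 grid = grid),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(paste0("Calibrated %s design over %d grid points ",
                     "(%d reps each, alpha cap %.2f)\n",
                     "  lambda = %.3f, gamma = %.3f: type I = %.2f%% ",
                     "(SE %.2f), power = %.2f%%\n"),
              x$kind, nrow(x$grid), x$reps, x$alpha_max, x$lambda, x$gamma,
              100 * x$type1, 100 * x$se_type1, 100 * x$power))
  invisible(x)
}
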