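#' Simulate a single trial under a design
#'
#' Runs one trial chronologically under continuous accrual with binding
#' stopping rules:
#'
#' * a look fires when its patient count is reached — efficacy looks count
#'   biomarker-negative patients, the stand-alone toxicity rule counts all
#'   patients, joint-design looks count biomarker-negative patients only;
#' * TOP looks analyse at the trigger patient's enrollment day, weighting
#'   pending patients by their elapsed fraction of follow-up; the
#'   posterior-probability toxicity rule uses complete 42-day observations
#'   (or already-observed events) available that day;
#' * complete-data efficacy rules (Simon, BOP2) suspend accrual at the look
#'   and defer the analysis until every enrolled efficacy window completes;
#' * a binding stop ends the trial immediately (decision day = analysis day
#'   of the triggering look);
#' * a trial reaching the final look unstopped is analysed on complete data
#'   at the completion of the last required observation window, and is
#'   positive when the final futility rule (and, for joint designs, the
#'   final toxicity rule) is not triggered.
#'
#' @param design A [make_design()] object.
#' @param cohort A [generate_cohort()] cohort with at least `design$n_max`
#'   patients.
#' @return An object of class `trial_result`: list with `decision` (one of
#'   `"positive"`, `"stopped_futility"`, `"stopped_toxicity"`,
#'   `"negative_final"`), `n_enrolled`, `duration` (days from first
#'   enrollment to decision), `stop_look` (label, or `NA`), `early`
#'   (logical).
#' @export
run_trial <- function(design, cohort) {
  stopifnot(inherits(design, "trial_design"), inherits(cohort, "trial_cohort"))
  pts <- cohort$patients
  w <- cohort$windows
  n_max <- design$n_max
  if (nrow(pts) < n_max)
    stop("cohort has ", nrow(pts), " patients; design needs ", n_max)
  idx_all <- seq_len(n_max)
  arrival <- pts$arrival[idx_all]  # shifted in place under accrual suspension
  met_pos <- pts$met_positive[idx_all]
  eff_lat <- pts$eff[idx_all]
  tox_lat <- pts$tox[idx_all]
  t_eff <- pts$t_eff[idx_all]
  t_tox <- pts$t_tox[idx_all]

  eff <- design$eff
  tox <- design$tox
  eff_pop <- which(!met_pos)
  tox_pop <- if (is.null(tox)) integer(0)
             else if (tox$population == "met_neg") eff_pop else idx_all

  # interim schedule: final efficacy look (and, for joint designs, the
  # coinciding final toxicity look) is analysed on complete data at the end
  eff_interim <- eff$looks[-length(eff$looks)]
  tox_interim <- if (is.null(tox)) integer(0)
                 else if (tox$rule == "top") tox$looks[tox$looks < max(tox$looks)]
                 else tox$looks
  ev <- rbind(
    if (length(tox_interim))
      data.frame(k = tox_interim, type = "tox", pri = 0L)[
        tox_interim <= length(tox_pop), , drop = FALSE],
    if (length(eff_interim))
      data.frame(k = eff_interim, type = "eff", pri = 1L)[
        eff_interim <= length(eff_pop), , drop = FALSE]
  )
  if (!is.null(ev) && nrow(ev)) {
    ev$trigger <- ifelse(ev$type == "tox", tox_pop[ev$k], eff_pop[ev$k])
    ev <- ev[order(ev$trigger, ev$pri), , drop = FALSE]
  }

  itop_prior <- function(day) {
    if (is.null(tox) || !isTRUE(tox$informative)) return(tox$prior)
    pos <- which(met_pos & arrival <= day)
    if (!length(pos)) return(tox$prior)
    pc <- endpoint_counts(arrival[pos], tox_lat[pos], t_tox[pos], day,
                          w$t_tox, weighted = FALSE)
    informative_tox_prior(tox$prior, pc$x, pc$m)
  }

  if (!is.null(ev)) for (i in seq_len(nrow(ev))) {
    tr <- ev$trigger[i]
    k <- ev$k[i]
    d <- arrival[tr]
    if (ev$type[i] == "tox") {
      sub <- tox_pop[seq_len(k)]
      if (tox$rule == "pp") {
        tc <- endpoint_counts(arrival[sub], tox_lat[sub], t_tox[sub], d,
                              w$t_tox, weighted = FALSE)
        stop_now <- beta_tail(tc$x, tc$m, tox$cutoff, tox$prior) >
          tox$threshold
      } else {
        tc <- endpoint_counts(arrival[sub], tox_lat[sub], t_tox[sub], d,
                              w$t_tox, weighted = TRUE)
        # threshold indexed by effective information (= n on complete data)
        stop_now <- tc$m > 0 &&
          beta_tail(tc$x, tc$m, tox$cutoff, itop_prior(d)) >
            cn_threshold(min(tc$m, tox$N), tox$N, tox$lambda, tox$gamma)
      }
      if (stop_now)
        return(trial_result("stopped_toxicity", tr, d,
                            paste0("tox@", k), TRUE))
    } else {
      sub <- eff_pop[seq_len(k)]
      if (eff$rule == "top") {
        ec <- endpoint_counts(arrival[sub], eff_lat[sub], t_eff[sub], d,
                              w$t_eff, weighted = TRUE)
        pr_fut <- stats::pbeta(eff$phi, eff$prior[1] + ec$x,
                               eff$prior[2] + ec$m - ec$x)
        # threshold indexed by effective information (= n on complete data)
        if (ec$m > 0 &&
            pr_fut > cn_threshold(min(ec$m, eff$N), eff$N, eff$lambda,
                                  eff$gamma))
          return(trial_result("stopped_futility", tr, d,
                              paste0("eff@", k), TRUE))
      } else {
        # complete-data rule: accrual suspended, analysis deferred until all
        # enrolled efficacy windows complete
        d_an <- d + w$t_eff
        x <- sum(eff_lat[sub])
        stop_now <- if (eff$rule == "simon") x <= eff$r1
          else stats::pbeta(eff$phi, eff$prior[1] + x,
                            eff$prior[2] + k - x) >
               cn_threshold(k, eff$N, eff$lambda, eff$gamma)
        if (stop_now)
          return(trial_result("stopped_futility", tr, d_an,
                              paste0("eff@", k), TRUE))
        if (tr < n_max)
          arrival[(tr + 1):n_max] <- arrival[(tr + 1):n_max] + (d_an - d)
      }
    }
  }

  # final analysis on complete data
  n_eff <- min(max(eff$looks), length(eff_pop))
  fidx <- eff_pop[seq_len(n_eff)]
  d_final <- max(arrival[fidx]) + w$t_eff
  if (length(tox_pop))
    d_final <- max(d_final, max(arrival[tox_pop]) + w$t_tox)
  x <- sum(eff_lat[fidx])
  positive <- switch(eff$rule,
    simon = x > eff$r,
    stats::pbeta(eff$phi, eff$prior[1] + x, eff$prior[2] + n_eff - x) <=
      cn_threshold(n_eff, eff$N, eff$lambda, eff$gamma))
  reason <- if (positive) NA_character_ else "efficacy"
  if (!is.null(tox) && tox$rule == "top") {
    n_t <- min(max(tox$looks), length(tox_pop))
    tidx <- tox_pop[seq_len(n_t)]
    xt <- sum(tox_lat[tidx])
    tox_trig <- beta_tail(xt, n_t, tox$cutoff, itop_prior(d_final)) >
      cn_threshold(n_t, tox$N, tox$lambda, tox$gamma)
    if (tox_trig) {
      positive <- FALSE
      reason <- "toxicity"
    }
  }
  trial_result(if (positive) "positive" else "negative_final",
               n_max, d_final,
               if (positive) NA_character_ else paste0("final_", reason),
               FALSE)
}

trial_result <- function(decision, n_enrolled, duration, stop_look, early) {
  structure(list(decision = decision, n_enrolled = n_enrolled,
                 duration = duration, stop_look = stop_look, early = early),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("Trial %s after %d patients, day %.0f%s\n", x$decision,
              x$n_enrolled, x$duration,
              if (!is.na(x$stop_look)) paste0(" (", x$stop_look, ")") else ""))
  invisible(x)
}

#' Monte Carlo operating characteristics of a design
#'
#' Aggregates [run_trial()] over independently generated cohorts: the
#' probability of a positive conclusion (efficacy with acceptable toxicity),
#' probability of early stopping (any binding stop before the final
#' analysis), average sample size and average trial duration, with binomial
#' Monte Carlo standard errors.
#'
#' @param design A [make_design()] object.
#' @param scenario An [outcome_scenario()].
#' @param reps Number of simulated trials.
#' @param seed Optional integer seed (one RNG stream for the whole run).
#' @param accrual,windows Accrual model and observation windows.
#' @param p_met_positive Biomarker-positive prevalence; defaults to the
#'   design's assumption.
#' @return An object of class `trial_oc` (also a one-row data.frame via
#'   [as.data.frame.trial_oc()]).
#' @export
operating_characteristics <- function(design, scenario, reps = 10000,
                                      seed = NULL,
                                      accrual = accrual_model(),
                                      windows = observation_windows(),
                                      p_met_positive = design$p_met_positive) {
  stopifnot(reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  decisions <- character(reps)
  n_enr <- numeric(reps)
  dur <- numeric(reps)
  early <- logical(reps)
  for (i in seq_len(reps)) {
    cohort <- generate_cohort(design$n_max, scenario, p_met_positive,
                              accrual, windows)
    res <- run_trial(design, cohort)
    decisions[i] <- res$decision
    n_enr[i] <- res$n_enrolled
    dur[i] <- res$duration
    early[i] <- res$early
  }
  p_pos <- mean(decisions == "positive")
  p_early <- mean(early)
  structure(list(
    design = design$kind, label = design$label,
    scenario = scenario,
    prob_positive = p_pos, se_positive = sqrt(p_pos * (1 - p_pos) / reps),
    prob_early_stop = p_early,
    se_early_stop = sqrt(p_early * (1 - p_early) / reps),
    prob_stopped_futility = mean(decisions == "stopped_futility"),
    prob_stopped_toxicity = mean(decisions == "stopped_toxicity"),
    mean_n = mean(n_enr), mean_duration = mean(dur),
    reps = reps, seed = seed), class = "trial_oc")
}

#' @export
print.trial_oc <- function(x, ...) {
  cat(sprintf("Operating characteristics: %s (%d reps)\n", x$label, x$reps))
  cat(sprintf("  scenario: p_eff = %.2f, p_tox = %.2f, r = %.2f\n",
              x$scenario$p_eff, x$scenario$p_tox, x$scenario$r))
  cat(sprintf("  positive: %.2f%% (SE %.2f), early stop: %.2f%%\n",
              100 * x$prob_positive, 100 * x$se_positive,
              100 * x$prob_early_stop))
  cat(sprintf("  mean N: %.1f, mean duration: %.0f days\n",
              x$mean_n, x$mean_duration))
  invisible(x)
}

#' @export
as.data.frame.trial_oc <- function(x, ...) {
  data.frame(design = x$design, label = x$label,
             p_eff = x$scenario$p_eff, p_tox = x$scenario$p_tox,
             r = x$scenario$r,
             prob_positive = x$prob_positive, se_positive = x$se_positive,
             prob_early_stop = x$prob_early_stop,
             prob_stopped_futility = x$prob_stopped_futility,
             prob_stopped_toxicity = x$prob_stopped_toxicity,
             mean_n = x$mean_n, mean_duration = x$mean_duration,
             reps = x$reps, stringsAsFactors = FALSE)
}

#' Factorial sweep of designs over scenarios and correlations
#'
#' Evaluates every design on every scenario at every requested correlation,
#' re-using the same seed for each (scenario, correlation) cell so designs
#' are compared under common random numbers.
#'
#' @param designs List of [make_design()] objects, or kind strings.
#' @param scenarios Data.frame with columns `p_eff`, `p_tox` (e.g. rows of
#'   [scenario_table()]), or a list of [outcome_scenario()] objects whose
#'   correlations are then taken as given.
#' @param r Correlations to sweep: numeric vector and/or preset names
#'   understood by [outcome_scenario()] (default `"pos1"`). Ignored when
#'   `scenarios` is a list of ready scenarios.
#' @param reps Replicates per cell.
#' @param seed Base seed; cell seeds are derived deterministically.
#' @param ... Passed to [operating_characteristics()].
#' @return Long-format data.frame of operating characteristics.
#' @export
scenario_sweep <- function(designs, scenarios = scenario_table(), r = "pos1",
                           reps = 10000, seed = NULL, ...) {
  if (inherits(designs, "trial_design")) designs <- list(designs)
  designs <- lapply(designs, function(d)
    if (is.character(d)) make_design(d) else d)
  stopifnot(length(designs) >= 1)
  if (inherits(scenarios, "outcome_scenario")) scenarios <- list(scenarios)
  cells <- list()
  if (is.data.frame(scenarios)) {
    for (i in seq_len(nrow(scenarios))) for (rv in r) {
      sc <- outcome_scenario(scenarios$p_eff[i], scenarios$p_tox[i], rv,
                             label = if ("label" %in% names(scenarios))
                               scenarios$label[i] else NULL)
      cells[[length(cells) + 1]] <-
        list(sc = sc, id = if ("scenario" %in% names(scenarios))
          scenarios$scenario[i] else i)
    }
  } else {
    for (i in seq_along(scenarios))
      cells[[length(cells) + 1]] <- list(sc = scenarios[[i]], id = i)
  }
  out <- list()
  for (ci in seq_along(cells)) {
    cell_seed <- if (is.null(seed)) NULL else seed + 1000L * ci
    for (d in designs) {
      oc <- operating_characteristics(d, cells[[ci]]$sc, reps = reps,
                                      seed = cell_seed, ...)
      row <- as.data.frame(oc)
      row$scenario <- cells[[ci]]$id
      out[[length(out) + 1]] <- row
    }
  }
  res <- do.call(rbind, out)
  res[, c("scenario", setdiff(names(res), "scenario"))]
}
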