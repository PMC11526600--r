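#' Accrual model
#'
#' Continuous accrual at 5 patients per month corresponds to a mean
#' interpatient arrival time of 6 days. Gaps are exponential by default
#' (Poisson-process accrual); `"fixed"` gives a deterministic grid, useful
#' for exact tests.
#'
#' @param mean_interarrival Mean gap between consecutive arrivals, in days.
#' @param mode `"exponential"` or `"fixed"`.
#' @return An object of class `accrual_model`.
#' @export
accrual_model <- function(mean_interarrival = 6,
                          mode = c("exponential", "fixed")) {
  stopifnot(is.numeric(mean_interarrival), mean_interarrival > 0)
  structure(list(mean_interarrival = mean_interarrival,
                 mode = match.arg(mode)),
            class = "accrual_model")
}

#' Observation windows
#'
#' Efficacy (objective response) is ascertained within `t_eff` days of
#' inclusion and unacceptable toxicity within `t_tox` days. Defaults mirror
#' 8 treatment cycles (180 days) and 2 cycles (42 days).
#'
#' @param t_eff Efficacy observation window, days.
#' @param t_tox Toxicity observation window, days.
#' @return An object of class `observation_windows`.
#' @export
observation_windows <- function(t_eff = 180, t_tox = 42) {
  stopifnot(t_eff > 0, t_tox > 0)
  structure(list(t_eff = t_eff, t_tox = t_tox), class = "observation_windows")
}

#' Simulate arrival days
#'
#' First arrival at day 0; subsequent gaps drawn from the accrual model.
#' Uses the current RNG stream (call `set.seed()` for reproducibility).
#'
#' @param n Number of patients (>= 1).
#' @param accrual An [accrual_model()].
#' @return Non-decreasing numeric vector of arrival days, length `n`.
#' @export
simulate_arrivals <- function(n, accrual = accrual_model()) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be a count >= 1")
  n <- as.integer(n)
  gaps <- accrual_gaps(n, accrual)
  cumsum(c(0, gaps))
}

accrual_gaps <- function(n, accrual) {
  if (n == 1) return(numeric(0))
  switch(accrual$mode,
         exponential = stats::rexp(n - 1, rate = 1 / accrual$mean_interarrival),
         fixed = rep(accrual$mean_interarrival, n - 1))
}

#' Generate a synthetic patient stream
#'
#' Draws, for `n` patients: arrival days from the accrual model; cMET
#' amplification status as independent Bernoulli(`p_met_positive`);
#' correlated (efficacy, toxicity) outcome pairs from the scenario's joint
#' cell probabilities; and, for patients with an event, the event time
#' uniform over the corresponding observation window. All latent values are
#' stored up front — the trial engine reveals them only as follow-up accrues.
#'
#' @param n Number of patients.
#' @param scenario An [outcome_scenario()].
#' @param p_met_positive Prevalence of cMET amplification (default 0.10).
#' @param accrual An [accrual_model()].
#' @param windows An [observation_windows()].
#' @param seed Optional integer; when given, `set.seed(seed)` is called and
#'   the seed recorded in the cohort (and in CSV headers on export).
#' @param met_allocation `"fixed"` (default) places exactly
#'   `round(n * p_met_positive)` biomarker-positive patients at random
#'   positions, so a 90-patient cohort always carries the 81 / 9 split the
#'   design analyses; `"bernoulli"` draws each status independently.
#' @return An object of class `trial_cohort`: list with `patients`
#'   (data.frame: `index`, `arrival`, `gap`, `met_positive`, `eff`, `tox`,
#'   `t_eff`, `t_tox`), `windows`, `scenario`, `p_met_positive`, `seed`.
#' @export
generate_cohort <- function(n, scenario, p_met_positive = 0.10,
                            accrual = accrual_model(),
                            windows = observation_windows(),
                            seed = NULL,
                            met_allocation = c("fixed", "bernoulli")) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be a count >= 1")
  stopifnot(inherits(scenario, "outcome_scenario"),
            inherits(accrual, "accrual_model"),
            inherits(windows, "observation_windows"))
  check_prob(p_met_positive, "p_met_positive")
  met_allocation <- match.arg(met_allocation)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  gaps <- accrual_gaps(n, accrual)
  arrival <- cumsum(c(0, gaps))
  met_positive <- if (met_allocation == "fixed") {
    pos <- rep(FALSE, n)
    n_pos <- round(n * p_met_positive)
    if (n_pos > 0) pos[sample.int(n, n_pos)] <- TRUE
    pos
  } else {
    stats::runif(n) < p_met_positive
  }
  cells <- joint_cell_probs(scenario)
  cell <- sample.int(4L, n, replace = TRUE, prob = cells)
  eff <- cell <= 2L
  tox <- cell == 1L | cell == 3L
  t_eff <- stats::runif(n, 0, windows$t_eff)
  t_tox <- stats::runif(n, 0, windows$t_tox)
  t_eff[!eff] <- NA_real_
  t_tox[!tox] <- NA_real_
  patients <- data.frame(index = seq_len(n), arrival = arrival,
                         gap = c(NA_real_, gaps), met_positive = met_positive,
                         eff = eff, tox = tox, t_eff = t_eff, t_tox = t_tox)
  structure(list(patients = patients, windows = windows, scenario = scenario,
                 p_met_positive = p_met_positive, seed = seed),
            class = "trial_cohort")
}

#' @export
print.trial_cohort <- function(x, ...) {
  p <- x$patients
  cat(sprintf("Trial cohort: %d patients (%d cMET-positive), last arrival day %.1f\n",
              nrow(p), sum(p$met_positive), max(p$arrival)))
  cat(sprintf("  observed rates: eff %.3f, tox %.3f\n",
              mean(p$eff), mean(p$tox)))
  invisible(x)
}

#' Write / read a cohort as CSV
#'
#' One row per patient; the generating seed (when known) is recorded in a
#' `#`-prefixed header comment so fixtures stay self-describing.
#'
#' @param cohort A [generate_cohort()] result.
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the patients data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "trial_cohort"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seqphase2 cohort; seed: %s; t_eff: %g; t_tox: %g",
                     if (is.null(cohort$seed)) "unknown" else cohort$seed,
                     cohort$windows$t_eff, cohort$windows$t_tox), con)
  utils::write.csv(cohort$patients, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
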