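#' Posterior tail probability under a conjugate Beta model
#'
#' With a Beta(a, b) prior and (possibly fractionally weighted) data of `x`
#' events among `m` evaluated, the posterior is Beta(a + x, b + m - x) and
#' the upper tail is \eqn{Pr(p > cutoff \mid D)}. The futility rule of the
#' monitoring designs uses the complement, \eqn{Pr(p \le \phi \mid D)}.
#' Non-integer `x` and `m` are allowed: the weighted likelihood of pending
#' patients plugs directly into the conjugate update.
#'
#' @param x Event count (weighted counts allowed), `0 <= x <= m`.
#' @param m Evaluated count (weighted), `m >= 0`.
#' @param cutoff Probability cutoff in \[0, 1\].
#' @param prior Length-2 positive vector `c(a, b)` of pseudo-counts.
#' @return `Pr(p > cutoff | data)`.
#' @examples
#' beta_tail(0, 0, 0.25)            # uniform prior: 0.75
#' beta_tail(3, 10, 0.25)           # Beta(4, 8) upper tail
#' @export
beta_tail <- function(x, m, cutoff, prior = c(1, 1)) {
  stopifnot(length(prior) == 2, all(prior > 0), all(is.finite(prior)))
  if (!is.numeric(cutoff) || any(cutoff < 0) || any(cutoff > 1))
    stop("cutoff must lie in [0, 1]")
  if (any(x < -1e-12) || any(x > m + 1e-12))
    stop("require 0 <= x <= m")
  stats::pbeta(cutoff, prior[1] + x, prior[2] + m - x, lower.tail = FALSE)
}

#' Effective (weighted) interim counts
#'
#' Summarises the data available at an interim analysis day under the
#' time-to-event weighting of pending patients. For efficacy: a patient with
#' an observed response contributes (1, 1) to (x, m); a patient whose
#' efficacy window is complete without response contributes (0, 1); a
#' pending patient contributes (0, w) with
#' w = (analysis day - arrival) / window. For toxicity the default is the
#' binary posterior-probability convention — integer counts from complete
#' observation windows only — with `tox_weighting = TRUE` switching to the
#' same fractional weighting as efficacy (used by the joint monitoring
#' designs).
#'
#' @param patients Patients data.frame (as in [generate_cohort()]`$patients`);
#'   only patients with `arrival <= analysis_day` are counted.
#' @param analysis_day Calendar day of the analysis (>= 0).
#' @param windows An [observation_windows()].
#' @param tox_weighting Logical; fractional weighting of toxicity follow-up.
#' @return List with `x_eff`, `m_eff` (weighted), `x_tox`, `m_tox`
#'   (integer unless `tox_weighting`), and `n_enrolled`.
#' @export
effective_counts <- function(patients, analysis_day, windows,
                             tox_weighting = FALSE) {
  stopifnot(inherits(windows, "observation_windows"))
  if (analysis_day < 0) stop("negative follow-up: analysis_day must be >= 0")
  enr <- patients[patients$arrival <= analysis_day, , drop = FALSE]
  eff <- endpoint_counts(enr$arrival, enr$eff, enr$t_eff, analysis_day,
                         windows$t_eff, weighted = TRUE)
  tox <- endpoint_counts(enr$arrival, enr$tox, enr$t_tox, analysis_day,
                         windows$t_tox, weighted = tox_weighting)
  list(x_eff = eff$x, m_eff = eff$m, x_tox = tox$x, m_tox = tox$m,
       n_enrolled = nrow(enr))
}

# Core counting rule shared by both endpoints.
# Weighted (time-to-event) mode: observed event -> (1, 1); complete window,
# no event -> (0, 1); pending -> (0, follow/window).
# Binary mode: complete windows only (event status is then fully known);
# events still pending in an open window are not counted until the window
# closes.
endpoint_counts <- function(arrival, event, t_event, day, window, weighted) {
  follow <- day - arrival
  complete <- follow >= window
  if (weighted) {
    observed <- event & !is.na(t_event) & (arrival + t_event <= day)
    w <- ifelse(observed | complete, 1, follow / window)
    list(x = sum(observed), m = sum(w))
  } else {
    list(x = sum(event & complete), m = sum(complete))
  }
}

#' Marginal posterior tails of a Dirichlet-multinomial joint model
#'
#' The joint monitoring designs model the four outcome cells
#' (Eff & Tox, Eff & !Tox, !Eff & Tox, !Eff & !Tox) as multinomial with a
#' Dirichlet prior. By the aggregation property, the marginal posterior of
#' the efficacy rate is Beta over the grouped cells (1 + 2 vs 3 + 4), and of
#' the toxicity rate Beta over (1 + 3 vs 2 + 4), so the decision rules
#' reduce to Beta tails on aggregated (possibly weighted) counts.
#'
#' @param alpha Length-4 positive Dirichlet concentration, cell order as above.
#' @param counts Length-4 non-negative (weighted) cell counts.
#' @param phi_eff Futility cutoff for efficacy.
#' @param phi_tox Toxicity cutoff.
#' @return Named vector `c(pr_eff_le = Pr(p_eff <= phi_eff | D),
#'   pr_tox_gt = Pr(p_tox > phi_tox | D))`.
#' @export
dirichlet_marginal_tails <- function(alpha, counts, phi_eff, phi_tox) {
  stopifnot(length(alpha) == 4, all(alpha > 0),
            length(counts) == 4, all(counts >= 0))
  a_eff <- alpha[1] + alpha[2] + counts[1] + counts[2]
  b_eff <- alpha[3] + alpha[4] + counts[3] + counts[4]
  a_tox <- alpha[1] + alpha[3] + counts[1] + counts[3]
  b_tox <- alpha[2] + alpha[4] + counts[2] + counts[4]
  c(pr_eff_le = stats::pbeta(phi_eff, a_eff, b_eff),
    pr_tox_gt = stats::pbeta(phi_tox, a_tox, b_tox, lower.tail = FALSE))
}
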