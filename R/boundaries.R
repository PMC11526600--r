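#' Adaptive probability threshold C_n
#'
#' The look-specific stopping threshold of the BOP2/TOP family,
#' \deqn{C_n = 1 - \lambda (n / N)^{\gamma},}
#' with `n` patients analysed of a maximum `N`. Larger `lambda` lowers the
#' final bar (more positive conclusions); `gamma` shapes how quickly the
#' threshold tightens across looks.
#'
#' @param n Patients at the look, `0 < n <= N`.
#' @param N Maximum number of patients for the rule.
#' @param lambda Scale hyperparameter in (0, 1\].
#' @param gamma Shape hyperparameter > 0.
#' @return Threshold value(s) in \[0, 1).
#' @export
cn_threshold <- function(n, N, lambda, gamma) {
  stopifnot(lambda > 0, lambda <= 1, gamma > 0, N >= 1)
  if (any(n <= 0) || any(n > N)) stop("require 0 < n <= N")
  1 - lambda * (n / N)^gamma
}

#' Toxicity stopping boundaries for posterior-probability monitoring
#'
#' For each look size `n`, the smallest integer toxicity count `x` with
#' \eqn{Pr(p_{tox} > cutoff \mid x, n) > threshold} under the Beta prior is
#' the stopping count; one less is the maximal count of toxicities allowing
#' the trial to continue.
#'
#' @param looks Ordered patient counts at the toxicity looks.
#' @param prior Beta prior `c(a, b)`, default uniform.
#' @param cutoff Unacceptable-toxicity rate cutoff (default 0.25).
#' @param threshold Posterior probability threshold (default 0.95).
#' @return Data.frame with columns `n`, `stop_if_ge` (NA when no count at
#'   that look can trigger a stop) and `max_tox_to_continue`.
#' @examples
#' pp_tox_boundaries(c(5, 10))  # stop at >= 3/5 and >= 5/10
#' @export
pp_tox_boundaries <- function(looks, prior = c(1, 1), cutoff = 0.25,
                              threshold = 0.95) {
  stopifnot(all(diff(looks) > 0), all(looks >= 1))
  stop_at <- vapply(looks, function(n) {
    min_stop_count(n, prior, cutoff, threshold)
  }, numeric(1))
  data.frame(n = looks,
             stop_if_ge = ifelse(is.finite(stop_at), stop_at, NA),
             max_tox_to_continue = ifelse(is.finite(stop_at), stop_at - 1,
                                          looks))
}

# smallest x in 0..m with Pr(p > cutoff | x, m) > threshold, Inf if none
min_stop_count <- function(m, prior, cutoff, threshold) {
  x <- 0:m
  hit <- beta_tail(x, m, cutoff, prior) > threshold
  if (any(hit)) x[which(hit)[1]] else Inf
}

# stop counts for every m = 0..m_max (vector indexed m + 1)
pp_stop_counts <- function(m_max, prior, cutoff, threshold) {
  vapply(0:m_max, min_stop_count, numeric(1),
         prior = prior, cutoff = cutoff, threshold = threshold)
}

#' Futility boundaries for complete-data BOP2-style looks
#'
#' At an efficacy look with `n` complete observations the trial stops when
#' \eqn{Pr(p_{eff} \le \phi \mid D_n) > C_n}. Since the posterior tail is
#' decreasing in the responder count, the rule is equivalent to a minimal
#' integer number of responders required to continue.
#'
#' @param looks Ordered efficacy look sizes; the last is the final analysis.
#' @param N Maximum patients entering the threshold (defaults to the last
#'   look).
#' @param prior Beta prior `c(a, b)` for the efficacy rate.
#' @param phi Futility cutoff (null response rate).
#' @param lambda,gamma Threshold hyperparameters, see [cn_threshold()].
#' @return Data.frame with columns `n`, `cn`, `min_resp_to_continue`.
#' @export
bop_futility_boundaries <- function(looks, N = max(looks),
                                    prior = c(0.15, 0.85), phi = 0.15,
                                    lambda = 0.865, gamma = 0.91) {
  stopifnot(all(diff(looks) > 0), all(looks >= 1), max(looks) <= N)
  cn <- cn_threshold(looks, N, lambda, gamma)
  min_resp <- mapply(function(n, thr) {
    x <- 0:n
    stop_x <- stats::pbeta(phi, prior[1] + x, prior[2] + n - x) > thr
    if (!any(stop_x)) 0 else max(x[stop_x]) + 1
  }, looks, cn)
  data.frame(n = looks, cn = cn, min_resp_to_continue = min_resp)
}

#' Simon's two-stage design with fixed stage sizes
#'
#' Exhaustive search over the stage-1 and final responder boundaries
#' `(r1, r)` with the stage sizes held fixed: stop for futility after stage 1
#' when `X1 <= r1`; conclude efficacy when `X1 > r1` and the total responder
#' count exceeds `r`. Among pairs with exact binomial type I error at most
#' `alpha_max` and power at least `power_min`, the design minimising the
#' expected sample size under `p0`,
#' `EN(p0) = n1 + (1 - PET(p0)) (n - n1)`, is returned (ties: smaller alpha,
#' then larger power).
#'
#' @param p0 Null response rate.
#' @param p1 Alternative response rate (`p1 > p0`).
#' @param alpha_max Maximum exact type I error.
#' @param power_min Minimum exact power.
#' @param n1 Stage-1 sample size.
#' @param n Total sample size.
#' @return Object of class `simon_design`: list with `n1`, `r1`, `n`, `r`,
#'   `alpha`, `power`, `pet_p0`, `en_p0`.
#' @export
simon_two_stage <- function(p0 = 0.15, p1 = 0.30, alpha_max = 0.05,
                            power_min = 0.90, n1 = 30, n = 81) {
  stopifnot(p0 < p1, n1 >= 1, n > n1)
  best <- NULL
  best_attainable <- c(alpha = Inf, power = 0)
  for (r1 in 0:n1) {
    pet0 <- stats::pbinom(r1, n1, p0)
    en0 <- n1 + (1 - pet0) * (n - n1)
    x1 <- seq(r1 + 1, n1)
    if (r1 == n1) next  # always stops: power 0
    d0 <- stats::dbinom(x1, n1, p0)
    d1 <- stats::dbinom(x1, n1, p1)
    for (r in r1:(n - 1)) {
      # reject iff X1 > r1 and X1 + X2 > r
      tail0 <- stats::pbinom(r - x1, n - n1, p0, lower.tail = FALSE)
      tail1 <- stats::pbinom(r - x1, n - n1, p1, lower.tail = FALSE)
      alpha <- sum(d0 * tail0)
      power <- sum(d1 * tail1)
      if (alpha <= alpha_max && power > best_attainable["power"])
        best_attainable <- c(alpha = alpha, power = power)
      if (alpha > alpha_max || power < power_min) next
      cand <- list(n1 = n1, r1 = r1, n = n, r = r, alpha = alpha,
                   power = power, pet_p0 = pet0, en_p0 = en0)
      if (is.null(best) ||
          en0 < best$en_p0 - 1e-12 ||
          (abs(en0 - best$en_p0) < 1e-12 &&
           (alpha < best$alpha - 1e-12 ||
            (abs(alpha - best$alpha) < 1e-12 && power > best$power))))
        best <- cand
    }
  }
  if (is.null(best))
    stop(sprintf(paste0("no (r1, r) pair meets alpha <= %.3f and power >= ",
                        "%.3f; best attainable power at that alpha: %.4f"),
                 alpha_max, power_min, best_attainable["power"]))
  structure(best, class = "simon_design")
}

#' @export
print.simon_design <- function(x, ...) {
  cat(sprintf(paste0("Simon two-stage design (fixed stages %d / %d)\n",
                     "  stop stage 1 if responders <= %d; positive if total > %d\n",
                     "  exact alpha = %.4f, power = %.4f, PET(p0) = %.4f, EN(p0) = %.1f\n"),
              x$n1, x$n, x$r1, x$r, x$alpha, x$power, x$pet_p0, x$en_p0))
  invisible(x)
}

#' Informative toxicity prior from concomitant patients
#'
#' Toxicity data observed in the biomarker-positive subgroup (whose efficacy
#' is analysed separately) update the toxicity prior under the assumed
#' homogeneity of toxicity across biomarker status: the Beta pseudo-counts
#' gain `x_pos` events and `n_pos - x_pos` non-events. The efficacy prior is
#' untouched.
#'
#' @param prior Base toxicity Beta prior `c(a, b)`.
#' @param x_pos Toxicity events among concomitant patients with complete
#'   (or event-ascertained) windows.
#' @param n_pos Number of such patients.
#' @return Updated `c(a, b)`.
#' @examples
#' informative_tox_prior(c(1, 1), 2, 5)  # Beta(3, 4)
#' @export
informative_tox_prior <- function(prior, x_pos, n_pos) {
  stopifnot(length(prior) == 2, all(prior > 0), x_pos >= 0, n_pos >= x_pos)
  c(prior[1] + x_pos, prior[2] + n_pos - x_pos)
}
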