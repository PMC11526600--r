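# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: tails by quadrature, designs by brute-force
# enumeration.

# Beta posterior upper tail by quadrature (oracle for beta_tail / pbeta).
quad_beta_tail <- function(x, m, cutoff, prior = c(1, 1)) {
  a <- prior[1] + x
  b <- prior[2] + m - x
  stats::integrate(function(p) stats::dbeta(p, a, b), cutoff, 1,
                   rel.tol = 1e-10)$value
}

# Smallest toxicity count that triggers Pr(p > cutoff | x, m) > threshold,
# found by enumeration over the quadrature tail.
quad_min_stop <- function(m, prior = c(1, 1), cutoff = 0.25,
                          threshold = 0.95) {
  for (x in 0:m)
    if (quad_beta_tail(x, m, cutoff, prior) > threshold) return(x)
  Inf
}

# Brute-force Simon two-stage search: double loop over (r1, r) with the
# joint stage pmf summed term by term (no pbinom shortcuts).
brute_simon <- function(p0, p1, alpha_max, power_min, n1, n) {
  reject_prob <- function(r1, r, p) {
    total <- 0
    for (x1 in (r1 + 1):n1) {
      if (x1 > n1) break
      tail2 <- sum(stats::dbinom(max(0, r - x1 + 1):(n - n1), n - n1, p))
      total <- total + stats::dbinom(x1, n1, p) * tail2
    }
    total
  }
  best <- NULL
  for (r1 in 0:(n1 - 1)) {
    pet0 <- sum(stats::dbinom(0:r1, n1, p0))
    en0 <- n1 + (1 - pet0) * (n - n1)
    for (r in r1:(n - 1)) {
      a <- reject_prob(r1, r, p0)
      pw <- reject_prob(r1, r, p1)
      if (a > alpha_max || pw < power_min) next
      if (is.null(best) || en0 < best$en0 - 1e-12 ||
          (abs(en0 - best$en0) < 1e-12 && a < best$alpha - 1e-12))
        best <- list(r1 = r1, r = r, alpha = a, power = pw, en0 = en0)
    }
  }
  best
}

# Deterministic toy trial for exact enumeration: 6 patients, fixed 50-day
# gaps, efficacy window 10 d / toxicity window 5 d, complete-data (BOP2)
# futility looks at 3 and 6 plus PP toxicity looks at 3 and 6. With gaps far
# exceeding both windows, every analysis depends only on the latent outcome
# pair of each patient, so the positive probability is an exact sum over the
# 4^6 outcome sequences.
toy_design <- function() {
  make_design("bop_pp", lambda = 0.9, gamma = 1, eff_looks = c(3, 6),
              tox_looks = c(3, 6), phi_eff = 0.3, phi_tox = 0.3,
              pp_threshold = 0.9, eff_prior = c(1, 1), tox_prior = c(1, 1),
              n_max = 6, p_met_positive = 0)
}

toy_windows <- function() observation_windows(t_eff = 10, t_tox = 5)
toy_accrual <- function() accrual_model(50, "fixed")

# Independent decision function for one outcome sequence of the toy trial.
# Toxicity look at n uses the first n - 1 patients (the trigger patient's
# window is still open at its own enrollment); efficacy looks are analysed
# on complete data under accrual suspension.
toy_decision <- function(eff, tox) {
  cn <- function(n) 1 - 0.9 * (n / 6)
  stop_tox <- function(x, m) (1 - stats::pbeta(0.3, 1 + x, 1 + m - x)) > 0.9
  stop_fut <- function(x, n) stats::pbeta(0.3, 1 + x, 1 + n - x) > cn(n)
  if (stop_tox(sum(tox[1:2]), 2)) return("stopped_toxicity")
  if (stop_fut(sum(eff[1:3]), 3)) return("stopped_futility")
  if (stop_tox(sum(tox[1:5]), 5)) return("stopped_toxicity")
  if (stop_fut(sum(eff[1:6]), 6)) return("negative_final")
  "positive"
}

# Exact positive probability of the toy trial by 4^6 enumeration.
toy_exact_positive <- function(cells) {
  grid <- as.matrix(expand.grid(rep(list(1:4), 6)))
  pos <- 0
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    prob <- prod(cells[cell])
    if (prob == 0) next
    eff <- cell <= 2
    tox <- cell == 1 | cell == 3
    if (toy_decision(eff, tox) == "positive") pos <- pos + prob
  }
  pos
}

# Monte Carlo tolerance (percentage points) for comparing a simulated
# probability with a reference value that itself carries 10,000-replicate
# noise.
mc_tol_pp <- function(p, reps, ref_reps = 10000) {
  max(3 * sqrt(p * (1 - p) * (1 / reps + 1 / ref_reps)) * 100, 1.5)
}
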