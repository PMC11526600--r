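test_that("beta_tail matches quadrature and behaves monotonically", {
  expect_equal(beta_tail(0, 0, 0.25), 0.75)
  expect_equal(beta_tail(3, 10, 0), 1)
  expect_equal(beta_tail(3, 10, 0.25), quad_beta_tail(3, 10, 0.25),
               tolerance = 1e-8)
  # weighted counts are allowed
  expect_equal(beta_tail(1.5, 4.25, 0.3, c(2, 3)),
               quad_beta_tail(1.5, 4.25, 0.3, c(2, 3)), tolerance = 1e-8)

  cutoffs <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(diff(beta_tail(3, 10, cutoffs)) < 0))
  xs <- 0:10
  expect_true(all(diff(beta_tail(xs, 10, 0.25)) > 0))

  expect_error(beta_tail(3, 10, 1.2), "cutoff")
  expect_error(beta_tail(5, 3, 0.2), "x <= m")
})

test_that("effective counts weight pending efficacy follow-up", {
  w <- observation_windows()
  pts <- data.frame(arrival = 0, met_positive = FALSE, eff = FALSE,
                    tox = FALSE, t_eff = NA_real_, t_tox = NA_real_)
  # halfway through the efficacy window, no response: (0, 0.5)
  ec <- effective_counts(pts, 90, w)
  expect_equal(c(ec$x_eff, ec$m_eff), c(0, 0.5))

  # response observed on day 30 counts fully, regardless of the open window
  pts$eff <- TRUE; pts$t_eff <- 30
  ec <- effective_counts(pts, 30, w)
  expect_equal(c(ec$x_eff, ec$m_eff), c(1, 1))

  # all windows complete: weighted counts equal raw counts
  pts3 <- data.frame(arrival = c(0, 10, 20), met_positive = FALSE,
                     eff = c(TRUE, FALSE, TRUE), tox = c(TRUE, FALSE, FALSE),
                     t_eff = c(100, NA, 150), t_tox = c(30, NA, NA))
  ec <- effective_counts(pts3, 500, w)
  expect_equal(c(ec$x_eff, ec$m_eff, ec$x_tox, ec$m_tox), c(2, 3, 1, 3))

  # binary toxicity convention: an open window contributes nothing yet
  ec <- effective_counts(pts3, 45, w)
  expect_equal(c(ec$x_tox, ec$m_tox), c(1, 1))
  ec <- effective_counts(pts3, 45, w, tox_weighting = TRUE)
  expect_equal(ec$x_tox, 1)
  expect_equal(ec$m_tox, 1 + 35 / 42 + 25 / 42)

  # patients not yet enrolled are ignored; m_eff never exceeds enrollment
  ec <- effective_counts(pts3, 15, w)
  expect_equal(ec$n_enrolled, 2)
  expect_lte(ec$m_eff, 2)
  expect_error(effective_counts(pts3, -1, w), "negative")
})

test_that("Dirichlet marginals reduce to aggregated Beta tails", {
  tails <- dirichlet_marginal_tails(rep(1, 4), rep(0, 4), 0.5, 0.5)
  expect_equal(tails[["pr_eff_le"]], pbeta(0.5, 2, 2))

  set.seed(5)
  for (i in 1:20) {
    alpha <- runif(4, 0.1, 2)
    counts <- runif(4, 0, 20)
    t2 <- dirichlet_marginal_tails(alpha, counts, 0.15, 0.30)
    expect_lt(abs(t2[["pr_eff_le"]] -
                  (1 - beta_tail(counts[1] + counts[2], sum(counts), 0.15,
                                 c(alpha[1] + alpha[2],
                                   alpha[3] + alpha[4])))), 1e-12)
    expect_lt(abs(t2[["pr_tox_gt"]] -
                  beta_tail(counts[1] + counts[3], sum(counts), 0.30,
                            c(alpha[1] + alpha[3],
                              alpha[2] + alpha[4]))), 1e-12)
  }

  # zero toxicity cells with large non-toxic counts drive the tail to 0
  expect_lt(dirichlet_marginal_tails(rep(1, 4), c(0, 500, 0, 500),
                                     0.15, 0.30)[["pr_tox_gt"]], 1e-6)
})

test_that("Dirichlet marginal tails agree with Monte Carlo sampling", {
  alpha <- c(0.08, 0.07, 0.22, 0.63)
  counts <- c(3, 2, 5, 10)
  post <- alpha + counts
  set.seed(31)
  n <- 1e5
  g <- matrix(rgamma(4 * n, shape = rep(post, each = n)), nrow = n)
  p_eff <- (g[, 1] + g[, 2]) / rowSums(g)
  p_tox <- (g[, 1] + g[, 3]) / rowSums(g)
  tails <- dirichlet_marginal_tails(alpha, counts, 0.15, 0.30)
  mc_eff <- mean(p_eff <= 0.15)
  mc_tox <- mean(p_tox > 0.30)
  expect_lt(abs(tails[["pr_eff_le"]] - mc_eff),
            3 * sqrt(mc_eff * (1 - mc_eff) / n) + 1e-6)
  expect_lt(abs(tails[["pr_tox_gt"]] - mc_tox),
            3 * sqrt(mc_tox * (1 - mc_tox) / n))
})
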