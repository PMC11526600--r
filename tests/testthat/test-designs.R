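test_that("the adaptive threshold follows its power-function form", {
  expect_equal(cn_threshold(81, 81, 0.92, 0.97), 1 - 0.92)
  expect_equal(cn_threshold(81, 81, 1, 2), 0)
  expect_equal(cn_threshold(30, 81, 0.865, 0.91), 0.6496718,
               tolerance = 1e-7)
  # strictly decreasing across looks
  cn <- cn_threshold(c(5, 10, 30, 50, 81), 81, 0.69, 0.98)
  expect_true(all(diff(cn) < 0))
  expect_error(cn_threshold(90, 81, 0.9, 1), "n <= N")
})

test_that("toxicity boundaries equal exhaustive posterior-rule enumeration", {
  bt <- pp_tox_boundaries(c(5, 10))
  expect_equal(bt$stop_if_ge, c(3, 5))

  looks <- c(5, 10, 15, 20, seq(30, 90, 10))
  bt <- pp_tox_boundaries(looks)
  for (i in seq_along(looks)) {
    expect_equal(bt$stop_if_ge[i], quad_min_stop(looks[i]),
                 info = paste("look", looks[i]))
    # the integer boundary reproduces the posterior rule for every count
    x <- 0:looks[i]
    rule <- beta_tail(x, looks[i], 0.25) > 0.95
    expect_equal(x >= bt$stop_if_ge[i], rule)
  }

  # an unattainable threshold never stops
  never <- pp_tox_boundaries(c(5, 10), threshold = 1)
  expect_true(all(is.na(never$stop_if_ge)))
})

test_that("futility boundaries invert the posterior rule exactly", {
  # phi = 0 cannot trigger futility
  b0 <- bop_futility_boundaries(c(10, 20), N = 20, phi = 0)
  expect_true(all(b0$min_resp_to_continue == 0))

  b <- bop_futility_boundaries(c(30, 81), 81, c(0.15, 0.85), 0.15,
                               0.865, 0.91)
  expect_true(all(diff(b$min_resp_to_continue) >= 0))
  for (i in seq_len(nrow(b))) {
    n <- b$n[i]
    x <- 0:n
    rule <- pbeta(0.15, 0.15 + x, 0.85 + n - x) > b$cn[i]
    expect_equal(x < b$min_resp_to_continue[i], rule)
  }

  # single-look toy against direct search
  toy <- bop_futility_boundaries(10, 10, c(1, 1), 0.15, 0.9, 1)
  brute <- 0
  for (x in 0:10)
    if (quad_beta_tail(x, 10, 0.15, c(1, 1)) < 1 - (1 - 0.9)) brute <- x + 1
  expect_equal(toy$min_resp_to_continue, brute)
})

test_that("Simon search agrees with an independent brute-force double loop", {
  s <- simon_two_stage(p0 = 0.15, p1 = 0.30, alpha_max = 0.05,
                       power_min = 0.90, n1 = 30, n = 81)
  b <- brute_simon(0.15, 0.30, 0.05, 0.90, 30, 81)
  expect_equal(s$r1, b$r1)
  expect_equal(s$r, b$r)
  expect_equal(s$alpha, b$alpha, tolerance = 1e-10)
  expect_equal(s$power, b$power, tolerance = 1e-10)
  expect_lte(s$alpha, 0.05)
  expect_gte(s$power, 0.90)

  # PET(p0) is the cumulative stage-1 binomial
  expect_equal(s$pet_p0, pbinom(s$r1, 30, 0.15))
  expect_equal(s$en_p0, 30 + (1 - s$pet_p0) * 51)

  # exact alpha matches a Monte Carlo of the two-stage rule
  set.seed(13)
  x1 <- rbinom(1e5, 30, 0.15)
  x2 <- rbinom(1e5, 51, 0.15)
  mc <- mean(x1 > s$r1 & x1 + x2 > s$r)
  expect_lt(abs(mc - s$alpha), 3 * sqrt(s$alpha * (1 - s$alpha) / 1e5))

  expect_error(simon_two_stage(0.15, 0.18, 0.05, 0.90, 30, 81),
               "no \\(r1, r\\) pair")
})

test_that("informative toxicity prior updates and tightens boundaries", {
  expect_equal(informative_tox_prior(c(1, 1), 2, 5), c(3, 4))
  expect_equal(informative_tox_prior(c(0.3, 0.7), 0, 0), c(0.3, 0.7))

  # more concomitant toxicity never loosens the stopping boundary
  looks <- c(5, 10, 20, 40)
  prev <- NULL
  for (x_pos in 0:5) {
    pr <- informative_tox_prior(c(0.3, 0.7), x_pos, 5)
    b <- pp_tox_boundaries(looks, pr, 0.30, 0.90)$stop_if_ge
    b[is.na(b)] <- Inf
    if (!is.null(prev)) expect_true(all(b <= prev))
    prev <- b
  }
})

test_that("design constructor assembles the published defaults", {
  d <- make_design("top_pp")
  expect_equal(c(d$eff$lambda, d$eff$gamma), c(0.865, 0.91))
  expect_equal(d$eff$looks, c(30, 81))
  expect_equal(d$tox$looks, c(5, 10, 15, 20, 30, 40, 50, 60, 70, 80, 90))
  expect_equal(d$tox$cutoff, 0.25)
  expect_equal(d$tox$prior, c(1, 1))
  expect_equal(d$eff$prior, c(0.15, 0.85))
  expect_false(d$suspend_accrual)

  d0 <- make_design("top_eff")
  expect_equal(c(d0$eff$lambda, d0$eff$gamma), c(0.92, 0.97))
  expect_null(d0$tox)

  dj <- make_design("top_joint")
  expect_equal(c(dj$eff$lambda, dj$eff$gamma), c(0.69, 0.98))
  expect_equal(dj$tox$looks, c(5, 10, 15, 20, 30, 40, 50, 60, 70, 81))
  expect_equal(dj$tox$cutoff, 0.30)
  expect_equal(dj$n_max, 81)
  expect_equal(dj$p_met_positive, 0)
  expect_equal(dj$tox$prior, c(0.3, 0.7), tolerance = 1e-12)

  di <- make_design("itop_joint")
  expect_true(di$tox$informative)
  expect_equal(di$n_max, 90)

  ds <- make_design("simon_pp")
  expect_true(ds$suspend_accrual)
  expect_equal(ds$eff$looks, c(30, 81))

  expect_error(make_design("nonsense"))
})

test_that("boundary tables restate each design's decision rules", {
  bt <- boundary_table(make_design("bop_pp"))
  expect_equal(bt$efficacy$min_resp_to_continue, c(4, 17))
  expect_equal(bt$toxicity$stop_if_ge[bt$toxicity$n == 5], 3)

  bs <- boundary_table(make_design("simon_pp"))
  s <- simon_two_stage()
  expect_equal(bs$efficacy$min_resp_to_continue, c(s$r1 + 1, s$r + 1))

  bj <- boundary_table(make_design("top_joint"))
  expect_true(all(diff(bj$toxicity$cn) < 0))
  expect_true(all(bj$toxicity$stop_if_ge <= bj$toxicity$n, na.rm = TRUE))
})
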