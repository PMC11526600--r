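test_that("a perfect drug is always concluded positive at full enrollment", {
  d <- make_design("top_pp")
  co <- generate_cohort(90, outcome_scenario(1, 0), seed = 2)
  res <- run_trial(d, co)
  expect_equal(res$decision, "positive")
  expect_equal(res$n_enrolled, 90)
  expect_false(res$early)

  oc <- operating_characteristics(d, outcome_scenario(1, 0), reps = 30,
                                  seed = 3)
  expect_equal(oc$prob_positive, 1)
  expect_equal(oc$prob_early_stop, 0)
})

test_that("certain toxicity triggers the first decidable toxicity look", {
  # slow accrual: every earlier window is complete at each look
  d <- make_design("top_pp")
  co <- generate_cohort(90, outcome_scenario(0.3, 1),
                        accrual = accrual_model(50, "fixed"), seed = 4)
  res <- run_trial(d, co)
  expect_equal(res$decision, "stopped_toxicity")
  expect_equal(res$stop_look, "tox@5")   # 4 events of 4 complete windows
  expect_equal(res$n_enrolled, 5)
  expect_true(res$early)
})

test_that("the same design and cohort always reproduce the same result", {
  d <- make_design("itop_joint")
  co <- generate_cohort(90, outcome_scenario(0.25, 0.25, 0.1), seed = 8)
  r1 <- run_trial(d, co)
  r2 <- run_trial(d, co)
  expect_identical(r1, r2)

  sc <- outcome_scenario(0.30, 0.20, "pos1")
  oc1 <- operating_characteristics(make_design("top_pp"), sc, reps = 50,
                                   seed = 99)
  oc2 <- operating_characteristics(make_design("top_pp"), sc, reps = 50,
                                   seed = 99)
  expect_equal(oc1$prob_positive, oc2$prob_positive)
  expect_equal(oc1$mean_duration, oc2$mean_duration)
})

test_that("engine refuses cohorts smaller than the design maximum", {
  d <- make_design("top_pp")
  co <- generate_cohort(40, outcome_scenario(0.3, 0.2, 0), seed = 1)
  expect_error(run_trial(d, co), "design needs")
})

test_that("toy-trial positive probability matches 4^6 exact enumeration", {
  d <- toy_design()
  sc <- outcome_scenario(0.45, 0.25, 0.1)
  exact <- toy_exact_positive(joint_cell_probs(sc))
  reps <- 20000
  oc <- operating_characteristics(d, sc, reps = reps, seed = 17,
                                  accrual = toy_accrual(),
                                  windows = toy_windows())
  expect_lt(abs(oc$prob_positive - exact),
            3 * sqrt(exact * (1 - exact) / reps))
})

test_that("sample size, duration and stop accounting are coherent", {
  sc <- outcome_scenario(0.20, 0.30, "pos1")
  for (kind in c("top_pp", "simon_pp", "top_joint")) {
    d <- make_design(kind)
    oc <- operating_characteristics(d, sc, reps = 300, seed = 23)
    expect_lte(oc$mean_n, d$n_max)
    expect_equal(oc$prob_early_stop,
                 oc$prob_stopped_futility + oc$prob_stopped_toxicity)
    expect_gt(oc$mean_duration, 0)
  }
})

test_that("accrual suspension makes complete-data designs slower than TOP", {
  top <- make_design("top_pp")
  bop <- make_design("bop_pp")
  for (sc in list(outcome_scenario(0.30, 0.20, "pos1"),
                  outcome_scenario(0.15, 0.30, "pos1"))) {
    oc_top <- operating_characteristics(top, sc, reps = 300, seed = 31)
    oc_bop <- operating_characteristics(bop, sc, reps = 300, seed = 31)
    expect_gt(oc_bop$mean_duration, oc_top$mean_duration)
  }
})

test_that("positive conclusions do not increase with the toxicity rate", {
  d <- make_design("top_pp")
  oc7 <- operating_characteristics(
    d, outcome_scenario(0.20, 0.20, "pos1"), reps = 600, seed = 37)
  oc8 <- operating_characteristics(
    d, outcome_scenario(0.20, 0.30, "pos1"), reps = 600, seed = 37)
  expect_gte(oc7$prob_positive, oc8$prob_positive)
})

test_that("scenario sweeps assemble a coherent long-format table", {
  tab <- scenario_table()[1:2, ]
  sw <- scenario_sweep(list("top_pp", make_design("top_joint")), tab,
                       r = "pos1", reps = 40, seed = 5)
  expect_equal(nrow(sw), 4)
  expect_setequal(unique(sw$design), c("top_pp", "top_joint"))
  expect_true(all(sw$prob_positive >= 0 & sw$prob_positive <= 1))
  expect_true(all(sw$se_positive <=
                    sqrt(0.25 / 40) + 1e-12))

  # a one-cell sweep equals a direct engine call under the same seed
  one <- scenario_sweep("top_pp", tab[1, ], r = 0, reps = 40, seed = 9)
  oc <- operating_characteristics(make_design("top_pp"),
                                  outcome_scenario(0.15, 0.30, 0),
                                  reps = 40, seed = 9 + 1000L)
  expect_equal(one$prob_positive, oc$prob_positive)
  expect_equal(one$mean_duration, oc$mean_duration)
})
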