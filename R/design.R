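#' Construct a sequential monitoring design
#'
#' Assembles one of the six monitoring strategies compared by the package:
#'
#' * `"top_eff"` — time-to-event TOP futility monitoring of efficacy only
#'   (weighted likelihood for pending patients), interim at 30 and final at
#'   81 biomarker-negative patients; defaults `lambda = 0.92`,
#'   `gamma = 0.97` (the initially planned efficacy rule).
#' * `"top_pp"` — TOP efficacy monitoring (`lambda = 0.865`, `gamma = 0.91`)
#'   plus an independent posterior-probability toxicity rule
#'   `Pr(p_tox > 0.25 | D) > 0.95` at 5, 10, 15, 20, 30, ..., 90 patients
#'   over the whole population.
#' * `"simon_pp"` — Simon's two-stage design with fixed stages 30/81
#'   (boundaries from [simon_two_stage()]) plus the same toxicity rule;
#'   accrual is suspended at the interim until all efficacy windows complete.
#' * `"bop_pp"` — BOP2 complete-data futility boundaries (`lambda = 0.865`,
#'   `gamma = 0.91`) with accrual suspension, plus the same toxicity rule.
#' * `"top_joint"` — joint TOP monitoring of efficacy and toxicity through a
#'   Dirichlet-multinomial model (`lambda = 0.69`, `gamma = 0.98`), efficacy
#'   looks at 30/81 and toxicity looks at 5, ..., 70, 81 patients, in a
#'   homogeneous biomarker-negative population; stop when
#'   `Pr(p_eff <= 0.15 | D) > C_n` or `Pr(p_tox > 0.30 | D) > C_n`.
#' * `"itop_joint"` — as `"top_joint"` but monitoring the biomarker-negative
#'   patients of a mixed 90-patient cohort, with the toxicity prior refreshed
#'   at every look from completed toxicity observations in biomarker-positive
#'   patients ([informative_tox_prior()]).
#'
#' Priors follow the BOP2 convention: Dirichlet concentration equal to the
#' null-scenario cell probabilities with total effective sample size 1, so
#' the marginal efficacy prior is Beta(`p0_eff`, 1 - `p0_eff`) and the
#' toxicity margin Beta(`p0_tox`, 1 - `p0_tox`). The stand-alone
#' posterior-probability toxicity rule uses a uniform Beta(1, 1) prior. All
#' defaults can be overridden.
#'
#' @param kind Design kind, see above.
#' @param lambda,gamma Threshold hyperparameters for [cn_threshold()];
#'   defaults depend on `kind`.
#' @param eff_looks Efficacy look sizes (counts of biomarker-negative
#'   patients); the last is the final analysis.
#' @param tox_looks Toxicity look sizes; population depends on `kind`.
#' @param phi_eff Efficacy futility cutoff.
#' @param phi_tox Toxicity cutoff (0.25 for the stand-alone rule, 0.30 for
#'   joint designs).
#' @param pp_threshold Posterior threshold of the stand-alone toxicity rule.
#' @param eff_prior,tox_prior Beta priors `c(a, b)`; `NULL` for the
#'   kind-specific defaults above.
#' @param n_max Total enrollment cap.
#' @param p_met_positive Biomarker-positive prevalence assumed when the
#'   engine generates cohorts for this design.
#' @param simon A [simon_two_stage()] object for `"simon_pp"`; `NULL`
#'   calibrates the default (p0 = 0.15, p1 = 0.30, alpha 0.05, power 0.90).
#' @param hypotheses A [hypothesis_pair()]; its null scenario seeds the
#'   default priors.
#' @return An object of class `trial_design`.
#' @export
make_design <- function(kind = c("top_pp", "top_eff", "simon_pp", "bop_pp",
                                 "top_joint", "itop_joint"),
                        lambda = NULL, gamma = NULL,
                        eff_looks = c(30, 81),
                        tox_looks = NULL,
                        phi_eff = 0.15, phi_tox = NULL,
                        pp_threshold = 0.95,
                        eff_prior = NULL, tox_prior = NULL,
                        n_max = NULL, p_met_positive = NULL,
                        simon = NULL,
                        hypotheses = hypothesis_pair()) {
  kind <- match.arg(kind)
  stopifnot(all(diff(eff_looks) > 0))
  h0 <- hypotheses$h0
  joint <- kind %in% c("top_joint", "itop_joint")
  alpha0 <- joint_cell_probs(h0)  # Dirichlet prior, ess 1
  if (is.null(eff_prior))
    eff_prior <- c(alpha0[1] + alpha0[2], alpha0[3] + alpha0[4])
  if (is.null(tox_prior))
    tox_prior <- if (joint) c(alpha0[1] + alpha0[3], alpha0[2] + alpha0[4])
                 else c(1, 1)
  eff_prior <- unname(eff_prior); tox_prior <- unname(tox_prior)
  N_eff <- max(eff_looks)

  default_lg <- switch(kind,
    top_eff = c(0.92, 0.97),
    top_pp = , bop_pp = c(0.865, 0.91),
    simon_pp = c(NA, NA),
    top_joint = , itop_joint = c(0.69, 0.98))
  if (is.null(lambda)) lambda <- default_lg[1]
  if (is.null(gamma)) gamma <- default_lg[2]

  if (is.null(tox_looks))
    tox_looks <- if (joint) c(5, 10, 15, 20, seq(30, 70, 10), max(eff_looks))
                 else c(5, 10, 15, 20, seq(30, 90, 10))
  if (is.null(phi_tox)) phi_tox <- if (joint) 0.30 else 0.25
  if (is.null(p_met_positive))
    p_met_positive <- if (kind == "top_joint") 0 else 0.10
  if (is.null(n_max)) {
    # homogeneous joint design enrolls exactly the efficacy maximum;
    # mixed-population designs enroll 90 (81 biomarker-negative expected)
    n_max <- if (p_met_positive == 0 && kind != "itop_joint") max(eff_looks)
             else max(90, if (joint) 0 else max(tox_looks))
  }

  eff <- switch(kind,
    simon_pp = {
      if (is.null(simon))
        simon <- simon_two_stage(p0 = phi_eff, p1 = hypotheses$h1$p_eff,
                                 n1 = eff_looks[1], n = max(eff_looks))
      stopifnot(inherits(simon, "simon_design"))
      list(rule = "simon", looks = c(simon$n1, simon$n), N = simon$n,
           phi = phi_eff, prior = eff_prior, r1 = simon$r1, r = simon$r,
           simon = simon)
    },
    bop_pp = list(rule = "bop", looks = eff_looks, N = N_eff, phi = phi_eff,
                  prior = eff_prior, lambda = lambda, gamma = gamma),
    list(rule = "top", looks = eff_looks, N = N_eff, phi = phi_eff,
         prior = eff_prior, lambda = lambda, gamma = gamma))

  tox <- if (kind == "top_eff") NULL else if (joint) {
    list(rule = "top", looks = tox_looks, population = "met_neg",
         cutoff = phi_tox, prior = tox_prior, lambda = lambda, gamma = gamma,
         N = max(tox_looks), weighting = "fractional",
         informative = kind == "itop_joint")
  } else {
    list(rule = "pp", looks = tox_looks, population = "all",
         cutoff = phi_tox, threshold = pp_threshold, prior = tox_prior,
         weighting = "complete", informative = FALSE)
  }

  labels <- c(top_eff = "TOP efficacy only", top_pp = "TOP_eff + PP_tox",
              simon_pp = "Simon + PP_tox", bop_pp = "BOP_eff + PP_tox",
              top_joint = "TOP_eff/tox", itop_joint = "iTOP_eff/tox")
  structure(list(kind = kind, label = unname(labels[kind]), n_max = n_max,
                 p_met_positive = p_met_positive,
                 suspend_accrual = kind %in% c("simon_pp", "bop_pp"),
                 eff = eff, tox = tox, dirichlet_alpha = unname(alpha0)),
            class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("Sequential phase II design: %s\n", x$label))
  cat(sprintf("  enrollment cap %d, biomarker-positive prevalence %.2f%s\n",
              x$n_max, x$p_met_positive,
              if (x$suspend_accrual) ", accrual suspended at efficacy looks"
              else ""))
  if (x$eff$rule == "simon") {
    cat(sprintf("  efficacy: Simon r1 = %d / %d, r = %d / %d\n",
                x$eff$r1, x$eff$looks[1], x$eff$r, x$eff$N))
  } else {
    cat(sprintf("  efficacy (%s): looks %s of N = %d, phi = %.2f, lambda = %.3f, gamma = %.2f\n",
                x$eff$rule, paste(x$eff$looks, collapse = "/"), x$eff$N,
                x$eff$phi, x$eff$lambda, x$eff$gamma))
  }
  if (!is.null(x$tox)) {
    if (x$tox$rule == "pp")
      cat(sprintf("  toxicity: Pr(p_tox > %.2f | D) > %.2f at %s patients (%s)\n",
                  x$tox$cutoff, x$tox$threshold,
                  paste(range(x$tox$looks), collapse = ".."),
                  x$tox$population))
    else
      cat(sprintf("  toxicity: Pr(p_tox > %.2f | D) > C_n at %s patients (%s%s)\n",
                  x$tox$cutoff, paste(range(x$tox$looks), collapse = ".."),
                  x$tox$population,
                  if (x$tox$informative) ", informative prior" else ""))
  }
  invisible(x)
}

#' Integer decision boundaries of a design
#'
#' Tabulates the per-look integer boundaries implied by the posterior rules
#' on complete data: the maximal toxicity count allowing continuation and
#' (for complete-data efficacy rules) the minimal responder count. For
#' weighted (TOP) interim analyses the table gives the complete-data
#' equivalent at each look size.
#'
#' @param design A [make_design()] object.
#' @return List of data.frames `efficacy` and `toxicity` (either may be
#'   `NULL`).
#' @export
boundary_table <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  e <- design$eff
  efficacy <- switch(e$rule,
    simon = data.frame(n = e$looks, cn = NA,
                       min_resp_to_continue = c(e$r1 + 1, e$r + 1)),
    bop_futility_boundaries(e$looks, e$N, e$prior, e$phi, e$lambda, e$gamma))
  toxicity <- NULL
  if (!is.null(design$tox)) {
    t <- design$tox
    if (t$rule == "pp") {
      toxicity <- pp_tox_boundaries(t$looks, t$prior, t$cutoff, t$threshold)
    } else {
      cn <- cn_threshold(t$looks, t$N, t$lambda, t$gamma)
      stop_at <- mapply(function(n, thr)
        min_stop_count(n, t$prior, t$cutoff, thr), t$looks, cn)
      toxicity <- data.frame(n = t$looks, cn = cn,
                             stop_if_ge = ifelse(is.finite(stop_at), stop_at, NA),
                             max_tox_to_continue =
                               ifelse(is.finite(stop_at), stop_at - 1, t$looks))
    }
  }
  list(efficacy = efficacy, toxicity = toxicity)
}
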