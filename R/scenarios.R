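#' Feasible correlation range for two Bernoulli outcomes
#'
#' Two Bernoulli variables with success probabilities `p_eff` and `p_tox`
#' cannot attain every correlation in \[-1, 1\]: the joint probability
#' \eqn{\pi_{11} = Pr(Eff \cap Tox)} is constrained by the Frechet bounds
#' \eqn{\max(0, p_{eff}+p_{tox}-1) \le \pi_{11} \le \min(p_{eff}, p_{tox})}.
#' Converting each extreme to a Pearson correlation via
#' \deqn{R = \frac{\pi_{11} - p_{eff} p_{tox}}
#'                {\sqrt{p_{eff}(1-p_{eff}) p_{tox}(1-p_{tox})}}}
#' gives the attainable range.
#'
#' @param p_eff True probability of efficacy (response), strictly in (0, 1).
#' @param p_tox True probability of unacceptable toxicity, strictly in (0, 1).
#' @return Named numeric vector `c(r_min = ..., r_max = ...)`, at full
#'   precision (round for display).
#' @examples
#' correlation_bounds(0.30, 0.20)  # about (-0.33, 0.76)
#' correlation_bounds(0.25, 0.25)  # r_max = 1
#' @export
correlation_bounds <- function(p_eff, p_tox) {
  check_prob(p_eff, "p_eff", open = TRUE)
  check_prob(p_tox, "p_tox", open = TRUE)
  s <- sqrt(p_eff * (1 - p_eff) * p_tox * (1 - p_tox))
  lo <- max(0, p_eff + p_tox - 1)
  hi <- min(p_eff, p_tox)
  c(r_min = (lo - p_eff * p_tox) / s, r_max = (hi - p_eff * p_tox) / s)
}

#' Named correlation presets for a pair of marginals
#'
#' Returns an evenly spaced grid of `n_grid` correlations spanning the
#' feasible range together with the named preset `pos1 = r_max / 3`, the
#' "slight positive correlation" used throughout the simulation study, and
#' `indep = 0`. Only `pos1` is anchored in the published design calibration;
#' the grid points are a convenience for sensitivity sweeps.
#'
#' @inheritParams correlation_bounds
#' @param n_grid Number of evenly spaced grid points from `r_min` to `r_max`.
#' @return Named numeric vector of correlations.
#' @export
correlation_presets <- function(p_eff, p_tox, n_grid = 6) {
  b <- correlation_bounds(p_eff, p_tox)
  grid <- seq(b[["r_min"]], b[["r_max"]], length.out = n_grid)
  names(grid) <- paste0("grid", seq_len(n_grid))
  c(grid, pos1 = b[["r_max"]] / 3, indep = 0,
    min = b[["r_min"]], max = b[["r_max"]])
}

#' Define a true-outcome scenario
#'
#' An outcome scenario fixes the joint distribution of the two binary
#' endpoints: marginal efficacy rate, marginal toxicity rate, and their
#' Pearson correlation `r`. Construction fails when `r` is outside the
#' feasible range for the marginals (see [correlation_bounds()]).
#'
#' @inheritParams correlation_bounds
#' @param r Correlation between efficacy and toxicity, or one of the preset
#'   names from [correlation_presets()] (e.g. `"pos1"` for one third of the
#'   maximum feasible correlation). Degenerate marginals (0 or 1) force 0.
#' @param label Optional scenario label.
#' @return An object of class `outcome_scenario`.
#' @examples
#' outcome_scenario(0.30, 0.20, "pos1")
#' @export
outcome_scenario <- function(p_eff, p_tox, r = 0, label = NULL) {
  check_prob(p_eff, "p_eff")
  check_prob(p_tox, "p_tox")
  degenerate <- p_eff %in% c(0, 1) || p_tox %in% c(0, 1)
  if (is.character(r)) {
    if (degenerate)
      stop("correlation presets are undefined for degenerate marginals")
    presets <- correlation_presets(p_eff, p_tox)
    if (!r %in% names(presets))
      stop("unknown correlation preset: ", r)
    r <- unname(presets[r])
  }
  stopifnot(is.numeric(r), length(r) == 1, is.finite(r))
  if (degenerate) {
    if (abs(r) > 1e-12)
      stop("degenerate marginals (0 or 1) force r = 0")
    r <- 0
  } else {
    b <- correlation_bounds(p_eff, p_tox)
    if (r < b[["r_min"]] - 1e-9 || r > b[["r_max"]] + 1e-9)
      stop(sprintf("r = %.4f outside feasible range [%.4f, %.4f]",
                   r, b[["r_min"]], b[["r_max"]]))
    r <- min(max(r, b[["r_min"]]), b[["r_max"]])
  }
  structure(list(p_eff = p_eff, p_tox = p_tox, r = r, label = label),
            class = "outcome_scenario")
}

#' @export
print.outcome_scenario <- function(x, ...) {
  cat("Outcome scenario", if (!is.null(x$label)) paste0("'", x$label, "'"),
      sprintf("\n  p_eff = %.3f, p_tox = %.3f, r = %.3f\n",
              x$p_eff, x$p_tox, x$r))
  cells <- joint_cell_probs(x)
  cat(sprintf("  joint cells: pi11 = %.4f, pi10 = %.4f, pi01 = %.4f, pi00 = %.4f\n",
              cells[1], cells[2], cells[3], cells[4]))
  invisible(x)
}

#' Joint cell probabilities of a correlated bivariate binary outcome
#'
#' Inverts the Bernoulli-correlation relation:
#' \eqn{\pi_{11} = p_{eff} p_{tox} + R \sqrt{p_{eff}(1-p_{eff})
#' p_{tox}(1-p_{tox})}}, with the remaining cells obtained by marginal
#' subtraction. Cells are ordered (Eff & Tox, Eff & !Tox, !Eff & Tox,
#' !Eff & !Tox).
#'
#' @param scenario An [outcome_scenario()], or a numeric `p_eff` when
#'   `p_tox`/`r` are supplied directly.
#' @param p_tox,r Marginal toxicity rate and correlation, used only when
#'   `scenario` is numeric.
#' @return Named numeric vector `c(pi11, pi10, pi01, pi00)` summing to 1.
#' @examples
#' joint_cell_probs(outcome_scenario(0.15, 0.30, "pos1"))  # 0.08 0.07 0.22 0.63
#' @export
joint_cell_probs <- function(scenario, p_tox = NULL, r = 0) {
  if (is.numeric(scenario)) {
    scenario <- outcome_scenario(scenario, p_tox, r)
  }
  stopifnot(inherits(scenario, "outcome_scenario"))
  pe <- scenario$p_eff
  pt <- scenario$p_tox
  s <- sqrt(pe * (1 - pe) * pt * (1 - pt))
  pi11 <- pe * pt + scenario$r * s
  cells <- c(pi11 = pi11, pi10 = pe - pi11, pi01 = pt - pi11,
             pi00 = 1 - pe - pt + pi11)
  if (any(cells < -1e-9) || any(cells > 1 + 1e-9))
    stop("correlation infeasible for these marginals: cell outside [0, 1]")
  cells <- pmin(pmax(cells, 0), 1)
  cells / sum(cells)
}

#' The ten simulation scenarios of the comparative study
#'
#' True (efficacy, toxicity) marginal pairs spanning the null, the
#' alternative, intermediate, inefficacious and toxic profiles, with their
#' feasible correlation range. The correlation is left to the caller (most
#' often the `"pos1"` preset, one third of the maximum).
#'
#' @return A data.frame with columns `scenario`, `label`, `p_eff`, `p_tox`,
#'   `r_min`, `r_max`.
#' @export
scenario_table <- function() {
  tab <- data.frame(
    scenario = 1:10,
    label = c("Null", "Alternative", "Intermediate", "Intermediate (2)",
              "Inefficacious", "Inefficacious (2)", "Intermediate efficacy",
              "Intermediate efficacy (2)", "Toxic", "Toxic (2)"),
    p_eff = c(0.15, 0.30, 0.20, 0.25, 0.15, 0.10, 0.20, 0.20, 0.30, 0.40),
    p_tox = c(0.30, 0.20, 0.25, 0.25, 0.20, 0.15, 0.20, 0.30, 0.30, 0.35),
    stringsAsFactors = FALSE
  )
  bounds <- t(mapply(correlation_bounds, tab$p_eff, tab$p_tox))
  tab$r_min <- bounds[, "r_min"]
  tab$r_max <- bounds[, "r_max"]
  tab
}

#' Working null and alternative hypothesis pair
#'
#' The design-calibration hypotheses: a null of modest efficacy with
#' borderline toxicity and an alternative of doubled efficacy with acceptable
#' toxicity, each with a slight positive efficacy-toxicity correlation.
#'
#' @param h0,h1 [outcome_scenario()] objects; defaults are
#'   \{0.15, 0.30, R = 0.21\} and \{0.30, 0.20, R = 0.26\}.
#' @return An object of class `hypothesis_pair`.
#' @export
hypothesis_pair <- function(h0 = outcome_scenario(0.15, 0.30, 0.21, "H0"),
                            h1 = outcome_scenario(0.30, 0.20, 0.26, "H1")) {
  stopifnot(inherits(h0, "outcome_scenario"), inherits(h1, "outcome_scenario"))
  if (h1$p_eff <= h0$p_eff)
    stop("alternative efficacy must exceed null efficacy")
  structure(list(h0 = h0, h1 = h1), class = "hypothesis_pair")
}

# shared input check
check_prob <- function(x, name, open = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(name, " must be a single finite number")
  if (open && (x <= 0 || x >= 1))
    stop(name, " must be strictly inside (0, 1)")
  if (x < 0 || x > 1)
    stop(name, " must be a probability in [0, 1]")
  invisible(x)
}
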