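## Synthetic data generator for the simulation study: a four-class latent
## exposure (conduct-problem trajectory classes EOP / AO / CL / Low at
## 8/10/12/70%), five binary indicators whose separation is calibrated to a
## target relative entropy, and a binary mediator ("deviant peers") and
## outcome ("hazardous alcohol use") drawn from the conditional
## probabilities of the simulation cross-tabulation.

## Cross-tabulation defining the structural model: cell counts for a
## population of 5,000 (class x mediator x outcome).
.sim_population <- list(
  classes = c("EOP", "AO", "CL", "Low"),
  n_m0 = c(270, 325, 475, 2930),     # cell totals with M = 0
  y1_m0 = c(120, 125, 180, 980),     # of which Y = 1
  n_m1 = c(130, 175, 125, 570),      # cell totals with M = 1
  y1_m1 = c(80, 100, 60, 245))

#' The simulation cross-tabulation as a frequency table
#'
#' The class x mediator x outcome population (n = 5,000) whose conditional
#' probabilities define the structural model of the simulation study.
#' Useful for saturated fits and for closed-form truth computations.
#'
#' @return a data frame with columns `class` (1..4, reference class 4 =
#'   "Low"), `m`, `y`, and the cell count `n`.
#' @export
population_crosstab <- function() {
  t1 <- .sim_population
  data.frame(
    class = rep(1:4, 4L),
    m = rep(c(0L, 0L, 1L, 1L), each = 4L),
    y = rep(c(0L, 1L, 0L, 1L), each = 4L),
    n = c(t1$n_m0 - t1$y1_m0, t1$y1_m0, t1$n_m1 - t1$y1_m1, t1$y1_m1))
}

default_p_m_given_x <- function() .sim_population$n_m1 / (.sim_population$n_m0 + .sim_population$n_m1)

default_p_y_given_x_m <- function() {
  cbind(m0 = .sim_population$y1_m0 / .sim_population$n_m0, m1 = .sim_population$y1_m1 / .sim_population$n_m1)
}

## Canonical trajectory shapes for the five indicators: "Low" flat and rare,
## "Childhood Limited" decreasing, "Adolescent Onset" increasing,
## "Early-Onset Persistent" persistently high.
default_base_profiles <- function() {
  rbind(EOP = c(0.8, 0.8, 0.8, 0.8, 0.8),
        AO  = c(0.1, 0.2, 0.4, 0.6, 0.8),
        CL  = c(0.8, 0.6, 0.4, 0.2, 0.1),
        Low = c(0.1, 0.1, 0.1, 0.1, 0.1))
}

## Exact population relative entropy of a binary-indicator latent class
## model: enumerate all 2^p complete response patterns, weight each
## pattern's posterior entropy by its marginal probability.
population_entropy <- function(class_props, item_probs) {
  p <- ncol(item_probs)
  pats <- as.matrix(expand.grid(rep(list(c(0, 1)), p)))
  L <- sweep(measurement_loglik(pats, item_probs), 2L, log(class_props), `+`)
  lse <- log_sum_exp_rows(L)
  relative_entropy(exp(L - lse), weights = exp(lse))
}

scale_profiles <- function(base_profiles, s) {
  lp <- logit(base_profiles)
  mid <- colMeans(lp)
  expit(sweep(sweep(lp, 2L, mid, `-`) * s, 2L, mid, `+`))
}

#' Calibrate indicator profiles to a target relative entropy
#'
#' Scales the separation of the base item-probability profiles around their
#' per-item logit midpoints by a single factor, chosen by bisection so that
#' the population relative entropy of the implied model equals
#' `entropy_target`. The population entropy is computed exactly by
#' enumerating all 2^p response patterns, so the calibration is
#' deterministic; pass `n_probe` to evaluate on a sampled probe instead.
#'
#' @param class_props class mixing proportions.
#' @param base_profiles k x p matrix of item probabilities encoding the
#'   trajectory shapes.
#' @param entropy_target target relative entropy in (0, 1).
#' @param n_probe optional probe-sample size; `NULL` (default) uses exact
#'   enumeration.
#' @param seed seed for the probe sample when `n_probe` is given.
#' @param tol bisection tolerance on the achieved entropy.
#' @return the calibrated k x p item-probability matrix, with attributes
#'   `scale_factor` and `achieved_entropy`.
#' @export
calibrate_profiles <- function(class_props, base_profiles, entropy_target,
                               n_probe = NULL, seed = 1L, tol = 1e-4) {
  stopifnot(entropy_target > 0, entropy_target < 1)
  eval_entropy <- function(s) {
    P <- scale_profiles(base_profiles, s)
    if (is.null(n_probe)) return(population_entropy(class_props, P))
    set.seed(as.integer(seed) %% .Machine$integer.max)
    d <- draw_indicators(class_props, P, n_probe)
    relative_entropy(softmax_rows(
      sweep(measurement_loglik(d$U, P), 2L, log(class_props), `+`)))
  }
  lo <- 0; hi <- 1
  e_hi <- eval_entropy(hi)
  while (e_hi < entropy_target) {
    lo <- hi; hi <- hi * 2
    if (hi > 64) {
      cond <- simpleCondition(sprintf(
        "calibration failure: entropy target %.3f unreachable (achieved %.3f at scale %.1f)",
        entropy_target, e_hi, lo))
      class(cond) <- c("lcmediate_calibration_failure", "error", "condition")
      stop(cond)
    }
    e_hi <- eval_entropy(hi)
  }
  for (i in seq_len(60L)) {
    mid <- (lo + hi) / 2
    e <- eval_entropy(mid)
    if (abs(e - entropy_target) < tol) break
    if (e < entropy_target) lo <- mid else hi <- mid
  }
  out <- scale_profiles(base_profiles, mid)
  attr(out, "scale_factor") <- mid
  attr(out, "achieved_entropy") <- e
  out
}

draw_indicators <- function(class_props, item_probs, n, X = NULL) {
  k <- length(class_props); p <- ncol(item_probs)
  if (is.null(X))
    X <- draw_classes(matrix(class_props, n, k, byrow = TRUE))
  U <- matrix(0L, n, p)
  for (j in seq_len(p))
    U[, j] <- stats::rbinom(n, 1L, item_probs[X, j])
  colnames(U) <- paste0("u", seq_len(p))
  list(X = X, U = U)
}

#' Define a simulation scenario
#'
#' Bundles the generating parameters of one data-generating mechanism: the
#' class proportions, the entropy-calibrated indicator profiles, and the
#' mediator/outcome conditional probabilities taken from the simulation
#' cross-tabulation ([population_crosstab()]). The three named presets differ
#' only in class separation (relative entropy approximately 0.90 / 0.80 /
#' 0.70).
#'
#' @param entropy `"good"`, `"medium"` or `"poor"` (targets 0.90, 0.80,
#'   0.70), or a numeric target in (0, 1).
#' @param n default sample size for datasets generated from the scenario.
#' @param class_props class proportions (EOP, AO, CL, Low).
#' @param base_profiles trajectory shapes passed to [calibrate_profiles()].
#' @param p_m_given_x `P(M = 1 | X = x)` per class.
#' @param p_y_given_x_m k x 2 matrix `P(Y = 1 | X = x, M = m)`, columns m =
#'   0, 1.
#' @return an object of class `"lcm_scenario"`.
#' @export
lcm_scenario <- function(entropy = c("good", "medium", "poor"), n = 5000L,
                         class_props = c(0.08, 0.10, 0.12, 0.70),
                         base_profiles = default_base_profiles(),
                         p_m_given_x = default_p_m_given_x(),
                         p_y_given_x_m = default_p_y_given_x_m()) {
  if (is.character(entropy)) {
    entropy <- match.arg(entropy)
    target <- c(good = 0.90, medium = 0.80, poor = 0.70)[[entropy]]
    label <- entropy
  } else {
    target <- entropy
    label <- sprintf("custom(%.2f)", target)
  }
  stopifnot(abs(sum(class_props) - 1) < 1e-8,
            all(p_m_given_x > 0 & p_m_given_x < 1),
            all(p_y_given_x_m > 0 & p_y_given_x_m < 1))
  profiles <- calibrate_profiles(class_props, base_profiles, target)
  structure(list(class_props = class_props,
                 item_profiles = profiles,
                 entropy_label = label,
                 entropy_target = target,
                 achieved_entropy = attr(profiles, "achieved_entropy"),
                 p_m_given_x = p_m_given_x,
                 p_y_given_x_m = p_y_given_x_m,
                 n_obs = n),
            class = "lcm_scenario")
}

#' @export
print.lcm_scenario <- function(x, ...) {
  cat(sprintf("Simulation scenario: %s entropy (target %.2f, population value %.3f), n = %d\n",
              x$entropy_label, x$entropy_target, x$achieved_entropy, x$n_obs))
  cat("class proportions:", paste(x$class_props, collapse = " / "), "\n")
  cat("item profiles:\n"); print(round(x$item_profiles, 3))
  invisible(x)
}

#' Generate one dataset from a scenario
#'
#' Draws the latent class, the conditionally independent binary indicators,
#' and the mediator and outcome from the scenario's conditional
#' probabilities, each from its own deterministic child stream of `seed`.
#'
#' @param scenario an `"lcm_scenario"`.
#' @param n sample size (defaults to the scenario's `n_obs`).
#' @param seed integer seed.
#' @return a data frame with columns `true_class`, `u1..u_p`, `m`, `y`.
#' @export
lcm_simulate <- function(scenario, n = scenario$n_obs, seed = 1L) {
  seeds <- derive_seeds(seed, 4L)
  k <- length(scenario$class_props)
  set.seed(seeds[1L])
  X <- draw_classes(matrix(scenario$class_props, n, k, byrow = TRUE))
  set.seed(seeds[2L])
  U <- draw_indicators(scenario$class_props, scenario$item_profiles, n, X = X)$U
  set.seed(seeds[3L])
  M <- stats::rbinom(n, 1L, scenario$p_m_given_x[X])
  set.seed(seeds[4L])
  Y <- stats::rbinom(n, 1L, scenario$p_y_given_x_m[cbind(X, M + 1L)])
  out <- data.frame(true_class = X, U, m = M, y = Y)
  attr(out, "scenario") <- scenario$entropy_label
  attr(out, "seed") <- seed
  out
}

#' Closed-form true mediation effects of a scenario
#'
#' Evaluates the mediation formula directly on the scenario's conditional
#' probabilities (no sampling, no model fitting); this is the truth the
#' simulation harness measures performance against.
#'
#' @param scenario an `"lcm_scenario"`.
#' @return a `"mediation_effects"` data frame (standard errors `NA`).
#' @export
true_effects <- function(scenario) {
  pm <- scenario$p_m_given_x
  py <- scenario$p_y_given_x_m
  k <- length(pm)
  a0 <- logit(pm[k])
  alpha <- c(a0, logit(pm[-k]) - a0)
  b0 <- logit(py[k, 1L]); b1 <- logit(py[k, 2L]) - b0
  bx <- logit(py[-k, 1L]) - b0
  bxm <- logit(py[-k, 2L]) - b0 - b1 - bx
  sp <- structure(list(alpha = alpha, beta = c(b0, b1, bx, bxm),
                       cov_alpha = NULL, cov_beta = NULL, k = k,
                       n_confounders = 0L, fit_method = "closed form"),
                  class = "lcm_struct")
  mediation_effects(sp, se = FALSE)
}
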