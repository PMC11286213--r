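## Monte Carlo simulation harness: replicate datasets, all requested
## estimators, the non-convergence exclusion rule, and Morris-style
## performance measures with Monte Carlo standard errors.

#' Run a simulation study
#'
#' Generates `n_sim` replicate datasets from a scenario, runs each
#' requested linking method on every replicate, and records the estimated
#' mediation effects and model standard errors. Replicates are
#' independently seeded from the root seed, so results do not depend on
#' execution order, and a method failing on one replicate is recorded as
#' excluded rather than aborting the run. The unconditional latent class
#' fit (and its parameter covariance, whose largest within-class threshold
#' SE feeds the exclusion rule) is shared across the methods that start
#' from it.
#'
#' @param scenario an [lcm_scenario()].
#' @param n_sim number of replicate datasets.
#' @param methods subset of `c("onestep", "bch", "modal", "npcd",
#'   "incpcd", "upcd")`.
#' @param seed root seed.
#' @param n per-replicate sample size (default: the scenario's).
#' @param m_pcd imputations for nPCD / incPCD.
#' @param upcd an [upcd_control()] list (also sets the uPCD imputation
#'   count).
#' @param n_restarts EM restarts for class-derivation models.
#' @param progress print a dot per replicate.
#' @return an object of class `"lcm_study"` with the estimates table
#'   (`$estimates`: replicate, method, comparison, estimand, estimate, se,
#'   excluded_flag, exclusion_reason) and per-replicate statistics
#'   (`$rep_stats`) used by [apply_exclusions()].
#' @export
lcm_study <- function(scenario, n_sim, methods = c("modal", "npcd"),
                      seed = 1L, n = scenario$n_obs, m_pcd = 40L,
                      upcd = upcd_control(), n_restarts = 20L,
                      onestep_restarts = 4L, progress = FALSE) {
  methods <- match.arg(methods,
                       c("onestep", "bch", "modal", "npcd", "incpcd", "upcd"),
                       several.ok = TRUE)
  rep_seeds <- derive_seeds(seed, n_sim)
  est <- vector("list", n_sim)
  stats_l <- vector("list", n_sim)
  for (r in seq_len(n_sim)) {
    out <- simulate_and_fit(scenario, n, methods, rep_seeds[r], m_pcd,
                            upcd, n_restarts, onestep_restarts)
    out$estimates$replicate <- r
    out$rep_stats$replicate <- r
    est[[r]] <- out$estimates
    stats_l[[r]] <- out$rep_stats
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  structure(list(estimates = do.call(rbind, est),
                 rep_stats = do.call(rbind, stats_l),
                 scenario = scenario$entropy_label,
                 n = n, n_sim = n_sim, methods = methods, seed = seed),
            class = "lcm_study")
}

simulate_and_fit <- function(scenario, n, methods, rep_seed, m_pcd, upcd,
                             n_restarts, onestep_restarts = 4L) {
  d <- lcm_simulate(scenario, n = n, seed = rep_seed)
  k <- length(scenario$class_props)
  U <- as.matrix(d[, paste0("u", seq_len(ncol(scenario$item_profiles)))])
  M <- d$m; Y <- d$y
  mseeds <- derive_seeds(rep_seed, length(methods) + 1L)
  needs_uncond <- any(methods %in% c("modal", "bch", "npcd", "upcd"))
  lfit <- NULL
  lca_max_tau_se <- NA_real_
  if (needs_uncond) {
    lfit <- tryCatch({
      f <- lca(U, k, n_restarts = n_restarts, seed = mseeds[1L])
      f <- align_classes(f, ref = scenario$item_profiles)
      f$param_cov <- param_covariance(f, U)
      f
    }, error = function(e) NULL, warning = function(w) {
      f <- suppressWarnings(lca(U, k, n_restarts = n_restarts,
                                seed = mseeds[1L]))
      f <- align_classes(f, ref = scenario$item_profiles)
      f$param_cov <- param_covariance(f, U)
      f
    })
    if (!is.null(lfit)) lca_max_tau_se <- lfit$param_cov$max_tau_se
  }
  rows <- list()
  onestep_max_tau_se <- NA_real_
  upcd_empty <- FALSE
  for (i in seq_along(methods)) {
    me <- methods[i]
    fit <- tryCatch(suppressWarnings(
      lcmediate(U, M, Y, C = NULL, k = k, method = me,
                m = if (me == "upcd") upcd$m else m_pcd,
                seed = mseeds[i + 1L], n_restarts = n_restarts,
                ref_profiles = scenario$item_profiles,
                lca_fit = lfit, upcd = upcd,
                onestep_restarts = onestep_restarts)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[me]] <- data.frame(method = me,
                               comparison = NA_character_,
                               estimand = NA_character_,
                               estimate = NA_real_, se = NA_real_,
                               excluded_flag = TRUE,
                               exclusion_reason = conditionMessage(fit))
    } else {
      e <- fit$effects
      rows[[me]] <- data.frame(method = me, comparison = e$comparison,
                               estimand = e$estimand,
                               estimate = e$estimate, se = e$se,
                               excluded_flag = FALSE,
                               exclusion_reason = NA_character_)
      if (me == "onestep")
        onestep_max_tau_se <- fit$diagnostics$max_tau_se
      if (me == "upcd")
        upcd_empty <- isTRUE(fit$diagnostics$excluded_empty_class)
    }
  }
  list(estimates = do.call(rbind, rows),
       rep_stats = data.frame(lca_max_tau_se = lca_max_tau_se,
                              onestep_max_tau_se = onestep_max_tau_se,
                              upcd_empty_class = upcd_empty,
                              seed = rep_seed))
}

#' Apply the non-convergence exclusion rule
#'
#' A replicate is excluded for all methods when the largest within-class
#' threshold standard error of its unconditional latent class model — or of
#' its one-step model, when one was run — strictly exceeds twice the cohort
#' average of the corresponding per-replicate maxima. Replicates where the
#' uPCD chain hit an imputed class of zero prevalence are likewise
#' excluded. Exclusion reasons are recorded per source.
#'
#' @param study an `"lcm_study"`.
#' @return the study with `excluded_flag` / `exclusion_reason` updated.
#' @export
apply_exclusions <- function(study) {
  rs <- study$rep_stats
  excl <- rep(FALSE, nrow(rs))
  reason <- rep(NA_character_, nrow(rs))
  for (src in c("lca_max_tau_se", "onestep_max_tau_se")) {
    v <- rs[[src]]
    if (all(is.na(v))) next
    thr <- 2 * mean(v, na.rm = TRUE)
    hit <- !is.na(v) & v > thr
    reason[hit & !excl] <- paste0(src, " > 2 x cohort mean")
    excl <- excl | hit
  }
  hit <- rs$upcd_empty_class %in% TRUE
  reason[hit & !excl] <- "imputed latent class with zero prevalence"
  excl <- excl | hit
  idx <- match(study$estimates$replicate, rs$replicate)
  newly <- excl[idx] & !study$estimates$excluded_flag
  study$estimates$excluded_flag[newly] <- TRUE
  study$estimates$exclusion_reason[newly] <- reason[idx][newly]
  study$exclusion_thresholds <- c(
    lca = 2 * mean(rs$lca_max_tau_se, na.rm = TRUE),
    onestep = if (all(is.na(rs$onestep_max_tau_se))) NA_real_ else
      2 * mean(rs$onestep_max_tau_se, na.rm = TRUE))
  study
}

#' @export
print.lcm_study <- function(x, ...) {
  cat(sprintf("Simulation study: %s scenario, n = %d, %d replicates, methods: %s\n",
              x$scenario, x$n, x$n_sim, paste(x$methods, collapse = ", ")))
  cat(sprintf("%d of %d estimate rows flagged excluded\n",
              sum(x$estimates$excluded_flag), nrow(x$estimates)))
  invisible(x)
}

#' Morris performance measures with Monte Carlo standard errors
#'
#' For every method x comparison x estimand cell of an estimates table:
#' bias `mean(est) - theta`, percentage bias `100 bias / theta`, coverage
#' of the Wald 95% interval, bias-eliminated coverage (intervals evaluated
#' against the mean estimate instead of the truth), empirical SE
#' `sd(est)`, and average model SE, each with its Monte Carlo SE (bias:
#' `emp_se / sqrt(R)`; coverage: `sqrt(c (1 - c) / R)`; empirical SE:
#' `emp_se / sqrt(2 (R - 1))`; model SE: `sd(model_se) / sqrt(R)`).
#' Percentage bias is flagged unstable when `|theta| < 0.02`.
#'
#' @param estimates an estimates data frame (from an `"lcm_study"` or its
#'   `$estimates`); excluded rows are dropped.
#' @param truth a `"mediation_effects"` table of true values (see
#'   [true_effects()]).
#' @return a `"PerformanceTable"` data frame.
#' @export
lcm_performance <- function(estimates, truth) {
  if (inherits(estimates, "lcm_study")) estimates <- estimates$estimates
  est <- estimates[!estimates$excluded_flag & !is.na(estimates$estimate), ]
  key <- unique(est[c("method", "comparison", "estimand")])
  out <- vector("list", nrow(key))
  for (i in seq_len(nrow(key))) {
    sel <- est$method == key$method[i] &
      est$comparison == key$comparison[i] & est$estimand == key$estimand[i]
    th <- truth$estimate[truth$comparison == key$comparison[i] &
                           truth$estimand == key$estimand[i]]
    e <- est$estimate[sel]; s <- est$se[sel]
    R <- length(e)
    emp_se <- stats::sd(e)
    cov <- mean(abs(e - th) <= 1.96 * s)
    bec <- mean(abs(e - mean(e)) <= 1.96 * s)
    out[[i]] <- data.frame(
      method = key$method[i], comparison = key$comparison[i],
      estimand = key$estimand[i], truth = th, n_included = R,
      bias = mean(e) - th,
      bias_mcse = emp_se / sqrt(R),
      pct_bias = 100 * (mean(e) - th) / th,
      pct_bias_mcse = 100 * emp_se / sqrt(R) / abs(th),
      pct_bias_unstable = abs(th) < 0.02,
      coverage = cov,
      coverage_mcse = sqrt(cov * (1 - cov) / R),
      bias_elim_coverage = bec,
      bias_elim_coverage_mcse = sqrt(bec * (1 - bec) / R),
      emp_se = emp_se,
      emp_se_mcse = emp_se / sqrt(2 * (R - 1)),
      model_se_avg = mean(s),
      model_se_mcse = stats::sd(s) / sqrt(R))
  }
  out <- do.call(rbind, out)
  class(out) <- c("PerformanceTable", "data.frame")
  out
}
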