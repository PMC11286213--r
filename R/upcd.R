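## Updated pseudo class draws (uPCD). Class-assignment probabilities
## P(X | U, M, Y) are re-derived at every iteration from the unconditional
## measurement parameters and the current structural estimates; all
## parameters are perturbed with Gaussian noise drawn from their estimated
## covariances so that classification uncertainty propagates into the
## pooled standard errors. After a burn-in the chain is thinned and the
## retained class draws form the multiple imputations, pooled by Rubin's
## rules.

#' Control parameters for the uPCD chain
#'
#' @param burn_in iterations discarded before any imputation is stored.
#' @param thin iterations between stored imputations.
#' @param m number of stored imputations.
#' @param perturb draw Gaussian noise around the measurement and structural
#'   estimates each cycle (disable only for diagnostics; without it the
#'   pooled SE ignores class-derivation uncertainty).
#' @param redraw_lca_each_iter perturb the measurement parameters afresh at
#'   every iteration (default) or once per stored-imputation cycle.
#' @param independent_restarts restart the chain (fresh burn-in) for every
#'   imputation instead of continuing one thinned chain.
#' @param firth_on_separation use Firth-penalised refits when a structural
#'   fit hits perfect prediction.
#' @export
upcd_control <- function(burn_in = 100L, thin = 20L, m = 80L,
                         perturb = TRUE, redraw_lca_each_iter = TRUE,
                         independent_restarts = FALSE,
                         firth_on_separation = TRUE) {
  stopifnot(burn_in >= 0L, thin >= 1L, m >= 1L)
  list(burn_in = as.integer(burn_in), thin = as.integer(thin),
       m = as.integer(m), perturb = isTRUE(perturb),
       redraw_lca_each_iter = isTRUE(redraw_lca_each_iter),
       independent_restarts = isTRUE(independent_restarts),
       firth_on_separation = isTRUE(firth_on_separation))
}

#' Perturb a parameter estimate with Gaussian noise
#'
#' Adds one draw from a zero-mean multivariate Gaussian with the given
#' covariance (eigenvalue-floored to positive semidefinite) to the
#' estimate. A zero covariance returns the estimate unchanged.
#'
#' @param estimate parameter vector.
#' @param cov its covariance matrix.
#' @return a perturbed parameter vector.
#' @export
perturb_params <- function(estimate, cov) {
  if (anyNA(cov) || any(!is.finite(cov))) return(estimate)
  if (all(cov == 0)) return(estimate)
  S <- (cov + t(cov)) / 2
  R <- tryCatch(chol(S + diag(1e-12, nrow(S))), error = function(e) NULL)
  if (is.null(R)) {
    e <- eigen(psd_repair(S), symmetric = TRUE)
    R <- t(e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors)))
  }
  estimate + drop(t(R) %*% stats::rnorm(length(estimate)))
}

#' Class-assignment probabilities conditional on mediator and outcome
#'
#' `P(X = x | U, M, Y) propto pi_x P(U | tau_x) P(M | x; alpha)
#' P(Y | x, M; beta)`, row-normalised on the log scale. With all structural
#' slopes at zero this reduces exactly to the unconditional posterior.
#'
#' @param gamma class logits (reference = last class).
#' @param tau k x p item-probability logits.
#' @param alpha,beta structural parameter vectors.
#' @param U indicator matrix; `M`, `Y` binary vectors.
#' @param C optional confounder matrix matching the structural fits.
#' @return an n x k posterior matrix.
#' @export
upcd_posterior <- function(gamma, tau, alpha, beta, U, M, Y, C = NULL) {
  U <- check_indicators(U)
  k <- nrow(tau)
  g0 <- c(gamma, 0)
  lpi <- g0 - (max(g0) + log(sum(exp(g0 - max(g0)))))
  L <- sweep(measurement_loglik(U, expit(tau)), 2L, lpi, `+`) +
    struct_loglik_rows(alpha, beta, k, M, Y, C)
  softmax_rows(L)
}

## One chain iteration on the compressed representation. Returns the new
## state (current perturbed alpha/beta, the fitted sp, the drawn W).
upcd_iterate <- function(state, chain) {
  k <- chain$k
  th <- if (chain$perturb && chain$redraw_lca_each_iter)
    state$lca_base + drop(chain$lca_chol %*% stats::rnorm(chain$d_lca))
  else state$lca_theta
  gamma <- th[seq_len(k - 1L)]
  tau <- matrix(th[k - 1L + seq_len(k * chain$p)], k, chain$p)
  ## cell-level posterior, expanded to persons through the pattern index
  g0 <- c(gamma, 0)
  lpi <- g0 - (max(g0) + log(sum(exp(g0 - max(g0)))))
  Lc <- meas_ll_fast(chain$Apat, chain$OmApat, expit(tau)) +
    rep(lpi, each = nrow(chain$Apat)) +
    struct_loglik_rows(state$alpha, state$beta, k, chain$Mpat, chain$Ypat,
                       chain$Cpat)
  probs <- softmax_rows(Lc)[chain$index, , drop = FALSE]
  W <- draw_classes(probs)
  sizes <- tabulate(W, k)
  if (any(sizes == 0L)) {          # redraw once from the continuing stream
    W <- draw_classes(probs)
    sizes <- tabulate(W, k)
  }
  empty <- any(sizes == 0L)
  if (!empty) {
    sp <- structural_fit(W, chain$M, chain$Y, chain$C, k,
                         firth_on_separation = chain$firth,
                         start = if (is.null(chain$C)) state$sp[c("alpha", "beta")])
    state$sp <- sp
    if (chain$perturb) {
      state$alpha <- perturb_params(sp$alpha, sp$cov_alpha)
      state$beta <- perturb_params(sp$beta, sp$cov_beta)
    } else if (!state$freeze) {
      state$alpha <- sp$alpha
      state$beta <- sp$beta
    }
  }
  state$lca_theta <- th
  state$W <- W
  state$sizes <- sizes
  state$empty <- empty
  state
}

run_upcd <- function(lca_fit, U, M, Y, C, k, m, control, seed, firth,
                     freeze_null_slopes = FALSE) {
  U <- check_indicators(U)
  n <- nrow(U); p <- ncol(U)
  nc <- if (is.null(C)) 0L else ncol(C)
  if (is.null(lca_fit$param_cov)) lca_fit$param_cov <- param_covariance(lca_fit, U)
  cp <- compress_patterns(U, extra = cbind(M, Y, C))
  theta0 <- lca_theta(lca_fit)
  Vl <- psd_repair(lca_fit$param_cov$cov)
  e <- eigen(Vl, symmetric = TRUE)
  lca_chol <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), length(theta0))
  Apat <- ifelse(is.na(cp$U), 0, cp$U)
  Opat <- (!is.na(cp$U)) * 1
  chain <- list(k = k, p = p, nc = nc,
                Apat = Apat, OmApat = Opat - Apat,
                Upat = cp$U, Mpat = cp$extra[, 1L], Ypat = cp$extra[, 2L],
                Cpat = if (nc) cp$extra[, 2L + seq_len(nc), drop = FALSE] else NULL,
                index = cp$index, M = M, Y = Y, C = C,
                lca_chol = lca_chol, d_lca = length(theta0),
                perturb = control$perturb, firth = control$firth_on_separation,
                redraw_lca_each_iter = control$redraw_lca_each_iter)
  ## Step 1: null structural fits -- Y on M only, M on intercept only
  fy <- logit_fit(cbind(1, M), Y)
  fm <- logit_fit(matrix(1, n, 1L), M)
  alpha0 <- c(fm$coef, rep(0, k - 1L + nc))
  beta0 <- c(fy$coef, rep(0, 2L * (k - 1L) + nc))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  if (control$perturb && !freeze_null_slopes) {
    alpha0[1L] <- perturb_params(fm$coef, fm$vcov)
    pb <- perturb_params(fy$coef, fy$vcov)
    beta0[1:2] <- pb
  }
  state <- list(alpha = alpha0, beta = beta0, lca_base = theta0,
                lca_theta = theta0, freeze = freeze_null_slopes, sp = NULL)
  total_iter <- if (control$independent_restarts)
    m * (control$burn_in + control$thin) else
    control$burn_in + m * control$thin
  store_at <- if (control$independent_restarts)
    seq_len(m) * (control$burn_in + control$thin) else
    control$burn_in + seq_len(m) * control$thin
  na <- k + nc; nb <- 2L * k + nc
  trace <- matrix(NA_real_, total_iter, na + nb + k + 4L * k)
  colnames(trace) <- c(paste0("alpha", seq_len(na) - 1L),
                       paste0("beta", seq_len(nb) - 1L),
                       paste0("size", seq_len(k)),
                       paste0("cell_x", rep(seq_len(k), 4L), "_m",
                              rep(rep(0:1, each = k), 2L), "_y",
                              rep(0:1, each = 2L * k)))
  effs <- vector("list", m)
  stored <- 0L
  empty_events <- 0L
  consecutive_empty <- 0L
  excluded <- FALSE
  for (it in seq_len(total_iter)) {
    if (control$independent_restarts &&
        it %% (control$burn_in + control$thin) == 1L) {
      state$alpha <- alpha0; state$beta <- beta0
    }
    state <- upcd_iterate(state, chain)
    if (state$empty) {
      empty_events <- empty_events + 1L
      consecutive_empty <- consecutive_empty + 1L
      if (consecutive_empty >= 2L) excluded <- TRUE
    } else consecutive_empty <- 0L
    cells <- tabulate(state$W + k * (chain$M + 2L * chain$Y), 4L * k)
    if (!is.null(state$sp))
      trace[it, ] <- c(state$sp$alpha, state$sp$beta, state$sizes, cells)
    if (it %in% store_at && !is.null(state$sp)) {
      stored <- stored + 1L
      effs[[stored]] <- mediation_effects(state$sp, C_rows = C)
    }
  }
  effs <- effs[seq_len(stored)]
  if (stored == 0L)
    stop("uPCD chain produced no usable imputations", call. = FALSE)
  pooled <- pool_effects(effs, effs[[1L]])
  mc_ratio <- max(pooled$mc_error / pooled$se)
  list(effects = pooled, lca = lca_fit,
       diagnostics = list(
         trace = as.data.frame(cbind(iteration = seq_len(total_iter), trace)),
         store_at = store_at, m = stored,
         burn_in = control$burn_in, thin = control$thin,
         empty_class_events = empty_events,
         excluded_empty_class = excluded,
         max_tau_se = lca_fit$param_cov$max_tau_se,
         mc_se_ratio_max = mc_ratio,
         perturb = control$perturb))
}

#' Convergence diagnostics for a uPCD fit
#'
#' Reports (a) the within-class threshold standard-error exclusion flag,
#' computed against the cohort distribution of per-dataset maxima when one
#' is supplied (the rule excludes a dataset whose largest threshold SE
#' exceeds twice the cohort average of such maxima); (b) empty-cell events
#' in the class x mediator x outcome cross-tabulation over the chain; and
#' (c) a Mann-Kendall stationarity verdict on the post-burn-in structural
#' parameter traces.
#'
#' @param fit an `"lcmed"` object fitted with `method = "upcd"`.
#' @param cohort_max_tau_se optional vector of per-dataset maxima of the
#'   within-class threshold SEs across a simulation cohort.
#' @param alpha significance level for the trend test.
#' @return a list with the flags, per-parameter trend p-values and a
#'   plot-ready trace table.
#' @export
diagnose_trace <- function(fit, cohort_max_tau_se = NULL, alpha = 0.05) {
  stopifnot(inherits(fit, "lcmed"), fit$method == "upcd")
  dg <- fit$diagnostics
  tr <- dg$trace
  post <- tr[tr$iteration > dg$burn_in & !is.na(tr[[2L]]), , drop = FALSE]
  par_cols <- grep("^(alpha|beta)", names(tr), value = TRUE)
  keep <- seq(1L, nrow(post),
              by = max(1L, floor(nrow(post) / 200L)))
  pvals <- vapply(par_cols, function(cn) {
    v <- post[[cn]][keep]
    if (stats::sd(v) == 0) return(1)
    suppressWarnings(stats::cor.test(seq_along(v), v,
                                     method = "kendall")$p.value)
  }, 0)
  stationary <- all(pvals >= alpha / length(pvals))
  cell_cols <- grep("^cell_", names(tr), value = TRUE)
  empty_cells <- sum(rowSums(tr[cell_cols] == 0, na.rm = TRUE) > 0 &
                       !is.na(tr[[2L]]))
  if (is.null(cohort_max_tau_se)) {
    se_rule <- "not evaluable (no cohort); absolute max threshold SE reported"
    se_excluded <- NA
  } else {
    se_excluded <- dg$max_tau_se > 2 * mean(cohort_max_tau_se)
    se_rule <- sprintf("max threshold SE %.3f vs 2 x cohort mean %.3f",
                       dg$max_tau_se, 2 * mean(cohort_max_tau_se))
  }
  list(threshold_se_excluded = se_excluded,
       threshold_se_rule = se_rule,
       max_tau_se = dg$max_tau_se,
       iterations_with_empty_cells = empty_cells,
       empty_class_events = dg$empty_class_events,
       excluded_empty_class = dg$excluded_empty_class,
       trend_p_values = pvals,
       stationary = stationary,
       pass = isTRUE(stationary) && !isTRUE(se_excluded) &&
         !isTRUE(dg$excluded_empty_class),
       trace = tr)
}

#' Trace plot for a uPCD fit
#'
#' @param x an `"lcmed"` object fitted with `method = "upcd"`.
#' @param pars trace columns to plot (default: the structural parameters).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.lcmed <- function(x, pars = NULL, ...) {
  if (x$method != "upcd" || is.null(x$diagnostics$trace)) {
    barplot(coef(x), las = 2, ylab = "log RR")
    return(invisible(x))
  }
  tr <- x$diagnostics$trace
  if (is.null(pars))
    pars <- grep("^(alpha|beta)", names(tr), value = TRUE)
  graphics::matplot(tr$iteration, tr[pars], type = "l", lty = 1,
                    xlab = "iteration", ylab = "parameter value", ...)
  graphics::abline(v = x$diagnostics$burn_in, lty = 2)
  invisible(x)
}
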