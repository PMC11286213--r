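## The six estimators linking a latent class exposure to the mediation
## model. `lcmediate()` is the single fitting entry point; the per-method
## workers live below and in onestep.R / upcd.R.

#' Counterfactual mediation with a latent class exposure
#'
#' Fits the latent class measurement model for the binary indicators `U`
#' and the structural mediation models for mediator `M` and outcome `Y`
#' (binary, complete), linking the two with one of six methods:
#'
#' * `"onestep"`: joint maximum likelihood of measurement and structural
#'   models; classification uncertainty propagates through the joint
#'   information matrix.
#' * `"bch"`: bias-adjusted three-step; modal assignment followed by a
#'   weighted multiple-group fit with inverse classification-error (BCH)
#'   weights, which may be negative.
#' * `"modal"`: modal class assignment with no correction.
#' * `"npcd"`: non-inclusive pseudo class draws; `m` multiple imputations
#'   of class membership from the unconditional posterior, pooled by
#'   Rubin's rules.
#' * `"incpcd"`: inclusive pseudo class draws; as `"npcd"` but the
#'   posterior comes from a conditional latent class model with `M`, `Y`
#'   (and confounders) as covariates.
#' * `"upcd"`: updated pseudo class draws; an iterative chain re-deriving
#'   `P(X | U, M, Y)` from the unconditional fit plus current structural
#'   estimates, with Gaussian perturbation of all parameters (see
#'   [upcd_control()]).
#'
#' Effects are reported on the log risk-ratio scale for each risk class
#' against the reference (last) class.
#'
#' @param U binary indicator matrix (0/1/`NA`).
#' @param M,Y binary mediator and outcome (complete).
#' @param C optional complete confounder matrix (main effects in both
#'   structural models; effects are standardised over its empirical rows).
#' @param k number of latent classes.
#' @param method linking method, see above.
#' @param m number of imputations for the pseudo-class-draw methods
#'   (default 40 for `"npcd"`/`"incpcd"`, 80 for `"upcd"`).
#' @param seed integer seed governing all randomness of the call.
#' @param n_restarts EM restarts for the class-derivation model (default
#'   20; the one-step model uses warm starts plus `onestep_restarts`).
#' @param ref_profiles optional k x p item-probability matrix to align the
#'   class labels against (e.g. generating profiles in a simulation);
#'   `NULL` orders classes by descending size.
#' @param lca_fit optionally, a pre-fitted aligned unconditional [lca()]
#'   object (with `$param_cov` attached) to reuse across methods.
#' @param upcd an [upcd_control()] list for `method = "upcd"`.
#' @param onestep_restarts random restarts added to the one-step warm start.
#' @param firth_on_separation fall back to Firth-penalised logistic fits
#'   when perfect prediction is detected.
#' @return an object of class `"lcmed"`: the effects table (`$effects`),
#'   the measurement fit (`$lca`), structural fit where applicable, and
#'   method-specific diagnostics.
#' @examples
#' sc <- lcm_scenario("good", n = 600)
#' d <- lcm_simulate(sc, seed = 7)
#' f <- lcmediate(d[paste0("u", 1:5)], d$m, d$y, k = 4, method = "modal",
#'                ref_profiles = sc$item_profiles, seed = 7)
#' print(f)
#' @export
lcmediate <- function(U, M, Y, C = NULL, k,
                      method = c("onestep", "bch", "modal", "npcd",
                                 "incpcd", "upcd"),
                      m = NULL, seed = 1L, n_restarts = 20L,
                      ref_profiles = NULL, lca_fit = NULL,
                      upcd = upcd_control(), onestep_restarts = 4L,
                      firth_on_separation = TRUE) {
  method <- match.arg(method)
  U <- check_indicators(U)
  if (!is.null(C)) {
    C <- as.matrix(C)
    if (anyNA(C)) stop("confounders must be complete", call. = FALSE)
  }
  if (anyNA(M) || anyNA(Y)) stop("M and Y must be complete", call. = FALSE)
  if (is.null(m)) m <- if (method == "upcd") 80L else 40L
  seeds <- derive_seeds(seed, 3L)
  if (method != "incpcd" && is.null(lca_fit) && method != "onestep") {
    lca_fit <- lca(U, k, n_restarts = n_restarts, seed = seeds[1L])
    lca_fit <- align_classes(lca_fit, ref = ref_profiles)
  }
  if (!is.null(lca_fit) && is.null(lca_fit$param_cov) &&
      method %in% c("upcd")) {
    lca_fit$param_cov <- param_covariance(lca_fit, U)
  }
  fit <- switch(method,
    modal = run_modal(lca_fit, U, M, Y, C, k, firth_on_separation),
    bch = run_bch(lca_fit, U, M, Y, C, k, firth_on_separation),
    npcd = run_npcd(lca_fit, U, M, Y, C, k, m, seeds[2L],
                    firth_on_separation),
    incpcd = run_incpcd(U, M, Y, C, k, m, n_restarts, seeds,
                        ref_profiles, lca_fit, firth_on_separation),
    onestep = run_onestep(U, M, Y, C, k, onestep_restarts, seeds[1L],
                          ref_profiles, firth_on_separation,
                          lca_fit = lca_fit),
    upcd = run_upcd(lca_fit, U, M, Y, C, k, m, upcd, seeds[2L],
                    firth_on_separation))
  fit$method <- method
  fit$k <- k
  fit$n <- nrow(U)
  fit$seed <- seed
  fit$call <- match.call()
  class(fit) <- "lcmed"
  fit
}

## ---- modal -----------------------------------------------------------------

run_modal <- function(lca_fit, U, M, Y, C, k, firth) {
  probs <- posterior(lca_fit, U)
  W <- modal_assignment(probs)
  sp <- structural_fit(W, M, Y, C, k, firth_on_separation = firth)
  list(effects = mediation_effects(sp, C_rows = C),
       structural = sp, lca = lca_fit,
       diagnostics = list(entropy = relative_entropy(probs)))
}

## ---- BCH -------------------------------------------------------------------

#' BCH inverse-classification-error weights
#'
#' Person `i` with modal class `w` receives weight `solve(D)[w, x]` for
#' pseudo-group `x`; the weights of each person sum to one and may be
#' negative. Feeding them to a weighted multiple-group fit undoes the
#' misclassification bias of modal assignment.
#'
#' @param D k x k classification matrix (see [classification_matrix()]).
#' @param W modal class labels.
#' @return an n x k weight matrix.
#' @export
bch_weights <- function(D, W) {
  if (kappa(D) > 1e8)
    warning("classification matrix is ill-conditioned; BCH weights are unreliable at this separation level",
            call. = FALSE)
  H <- solve(D)
  H[W, , drop = FALSE]
}

run_bch <- function(lca_fit, U, M, Y, C, k, firth) {
  probs <- posterior(lca_fit, U)
  W <- modal_assignment(probs)
  D <- classification_matrix(probs)
  Hw <- bch_weights(D, W)
  n <- length(W)
  ## expand to k weighted pseudo-rows per person with deterministic class x
  Wx <- rep(seq_len(k), each = n)
  sp <- structural_fit(Wx, rep(M, k), rep(Y, k),
                       C = if (is.null(C)) NULL else C[rep(seq_len(n), k), , drop = FALSE],
                       k = k, weights = as.vector(Hw),
                       firth_on_separation = FALSE)
  list(effects = mediation_effects(sp, C_rows = C),
       structural = sp, lca = lca_fit,
       diagnostics = list(D = D, condition_number = kappa(D)))
}

## ---- Rubin pooling ---------------------------------------------------------

#' Pool multiply-imputed estimates by Rubin's rules
#'
#' @param estimates per-imputation point estimates.
#' @param variances per-imputation (squared) standard errors.
#' @return a list with the pooled `estimate`, `within_var`, `between_var`,
#'   `total_se` (within + (1 + 1/m) between, square-rooted), the number of
#'   imputations `m`, and the Monte Carlo error of the pooled estimate
#'   `mc_error = sqrt(between_var / m)`.
#' @export
rubin_pool <- function(estimates, variances) {
  m <- length(estimates)
  stopifnot(m >= 1L, length(variances) == m)
  est <- mean(estimates)
  between <- if (m > 1L) stats::var(estimates) else 0
  within <- mean(variances)
  list(estimate = est, within_var = within, between_var = between,
       total_se = sqrt(within + (1 + 1 / m) * between),
       m = m, mc_error = sqrt(between / m))
}

## Pool a list of per-draw mediation_effects tables row-wise.
pool_effects <- function(effs, template) {
  E <- sapply(effs, `[[`, "estimate")
  V <- sapply(effs, function(e) e$se^2)
  out <- template
  pooled <- lapply(seq_len(nrow(out)), function(i)
    rubin_pool(E[i, ], V[i, ]))
  out$estimate <- vapply(pooled, `[[`, 0, "estimate")
  out$se <- vapply(pooled, `[[`, 0, "total_se")
  out$within_var <- vapply(pooled, `[[`, 0, "within_var")
  out$between_var <- vapply(pooled, `[[`, 0, "between_var")
  out$mc_error <- vapply(pooled, `[[`, 0, "mc_error")
  out$rr <- exp(out$estimate)
  out$ci_low <- out$estimate - 1.96 * out$se
  out$ci_high <- out$estimate + 1.96 * out$se
  attr(out, "m") <- length(effs)
  out
}

## Draw W repeatedly from a posterior matrix, refit, pool. A draw leaving a
## class empty is redrawn once from the continuing stream.
pcd_pool <- function(probs, M, Y, C, k, m, seed, firth) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  effs <- vector("list", m)
  redraws <- 0L
  for (d in seq_len(m)) {
    W <- draw_classes(probs)
    if (length(unique(W)) < k) {
      redraws <- redraws + 1L
      W <- draw_classes(probs)
      if (length(unique(W)) < k)
        stop("degenerate draw: imputed latent class with zero prevalence",
             call. = FALSE)
    }
    sp <- structural_fit(W, M, Y, C, k, firth_on_separation = firth)
    effs[[d]] <- mediation_effects(sp, C_rows = C)
  }
  list(effects = pool_effects(effs, effs[[1L]]), redraws = redraws)
}

run_npcd <- function(lca_fit, U, M, Y, C, k, m, seed, firth) {
  probs <- posterior(lca_fit, U)
  pooled <- pcd_pool(probs, M, Y, C, k, m, seed, firth)
  list(effects = pooled$effects, lca = lca_fit,
       diagnostics = list(m = m, redraws = pooled$redraws,
                          entropy = relative_entropy(probs)))
}

run_incpcd <- function(U, M, Y, C, k, m, n_restarts, seeds, ref_profiles,
                       lca_fit, firth) {
  Z <- cbind(m = M, y = Y)
  if (!is.null(C)) Z <- cbind(Z, C)
  if (is.null(lca_fit))
    lca_fit <- lca(U, k, n_restarts = max(n_restarts %/% 2L, 5L),
                   seed = seeds[3L])
  cfit <- lca_conditional(U, Z, k, n_restarts = n_restarts,
                          seed = seeds[1L], init = lca_fit)
  cfit <- align_classes(cfit, ref = ref_profiles)
  probs <- posterior(cfit, U, covariates = Z)
  pooled <- pcd_pool(probs, M, Y, C, k, m, seeds[2L], firth)
  list(effects = pooled$effects, lca = cfit,
       diagnostics = list(m = m, redraws = pooled$redraws,
                          entropy = relative_entropy(probs)))
}

## ---- lcmed methods ---------------------------------------------------------

#' @export
print.lcmed <- function(x, ...) {
  cat(sprintf("Latent class mediation fit: method = %s, k = %d, n = %d\n",
              x$method, x$k, x$n))
  print(x$effects)
  invisible(x)
}

#' @export
summary.lcmed <- function(object, ...) {
  out <- list(method = object$method, k = object$k, n = object$n,
              effects = object$effects,
              diagnostics = object$diagnostics)
  class(out) <- "summary.lcmed"
  out
}

#' @export
print.summary.lcmed <- function(x, ...) {
  cat(sprintf("Latent class mediation fit (method = %s, k = %d, n = %d)\n",
              x$method, x$k, x$n))
  print(x$effects)
  dg <- x$diagnostics
  if (!is.null(dg$entropy))
    cat(sprintf("\nrelative entropy of class assignment: %.3f\n", dg$entropy))
  if (!is.null(dg$m)) cat(sprintf("imputations pooled: %d\n", dg$m))
  if (!is.null(dg$mc_se_ratio_max))
    cat(sprintf("max Monte Carlo error / SE: %.1f%%\n",
                100 * dg$mc_se_ratio_max))
  invisible(x)
}

#' @export
coef.lcmed <- function(object, ...) {
  e <- object$effects
  stats::setNames(e$estimate, paste(e$comparison, e$estimand, sep = ":"))
}

#' @export
confint.lcmed <- function(object, parm, level = 0.95, ...) {
  e <- object$effects
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(e$estimate - z * e$se, e$estimate + z * e$se)
  rownames(out) <- paste(e$comparison, e$estimand, sep = ":")
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  out
}
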