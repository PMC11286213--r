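## Latent class analysis for binary indicators, fitted by EM with full
## information maximum likelihood over partially observed indicator vectors.
## The model: P(U | X = x) = prod_j p_xj^{u_j} (1 - p_xj)^{1 - u_j}, with
## mixing proportions pi_x. Parameters are stored on the logit scale:
## class logits gamma_x = log(pi_x / pi_k) (reference class = last class,
## gamma_k fixed at 0) and item thresholds tau_xj = logit P(U_j = 1 | X = x).
## Note this is the probability-logit convention; software that prints
## "thresholds" for the probability of the 0 category reports -tau.

P_CLAMP <- 1e-6  # item probabilities are kept in [P_CLAMP, 1 - P_CLAMP]

## ---- validation and pattern compression -----------------------------------

check_indicators <- function(U) {
  U <- as.matrix(U)
  storage.mode(U) <- "double"
  vals <- U[!is.na(U)]
  if (length(vals) && !all(vals %in% c(0, 1)))
    stop("indicator matrix must contain only 0, 1 or NA", call. = FALSE)
  if (any(rowSums(!is.na(U)) == 0L))
    stop("every row must have at least one non-missing indicator",
         call. = FALSE)
  if (is.null(colnames(U))) colnames(U) <- paste0("u", seq_len(ncol(U)))
  U
}

## Collapse rows to unique observed patterns (missingness pattern included),
## optionally jointly with extra columns. Returns the pattern matrix, counts
## and the row -> pattern index map.
compress_patterns <- function(U, extra = NULL) {
  M <- if (is.null(extra)) U else cbind(U, extra)
  key <- apply(M, 1L, paste, collapse = "\r")
  idx <- match(key, unique(key))
  first <- which(!duplicated(key))
  list(U = U[first, , drop = FALSE],
       extra = if (is.null(extra)) NULL else extra[first, , drop = FALSE],
       counts = as.vector(tabulate(idx, max(idx))),
       index = idx)
}

## Per-pattern measurement log-likelihood matrix (npat x k), FIML over
## missing cells: missing indicators simply contribute nothing.
measurement_loglik <- function(Upat, item_probs) {
  A <- ifelse(is.na(Upat), 0, Upat)          # observed 1s
  O <- (!is.na(Upat)) * 1                    # observed mask
  meas_ll_fast(A, O - A, item_probs)
}

## Fast path with precomputed masks: A = observed 1s, OmA = observed 0s.
meas_ll_fast <- function(A, OmA, item_probs) {
  P <- pmin(pmax(item_probs, P_CLAMP), 1 - P_CLAMP)
  A %*% t(log(P)) + OmA %*% t(log1p(-P))
}

## ---- unconditional fit -----------------------------------------------------

#' Fit a latent class model for binary indicators
#'
#' Maximum likelihood fit of a `k`-class mixture of independent Bernoulli
#' indicators by EM, with multiple random restarts and full-information
#' handling of missing indicator cells (missing at random). Rows are
#' collapsed to unique response patterns, so run time is driven by the
#' number of distinct patterns rather than the sample size.
#'
#' @param U matrix or data frame of binary indicators (0/1/`NA`); each row
#'   must have at least one observed indicator.
#' @param k number of latent classes.
#' @param n_restarts number of random-responsibility EM starts; the start
#'   with the highest observed-data log-likelihood is returned.
#' @param tol relative log-likelihood change declaring convergence.
#' @param max_iter maximum EM iterations per start.
#' @param seed integer seed controlling the random starts.
#' @return an object of class `"lca"` with mixing proportions `pi`, class
#'   logits `gamma` (reference = last class), item-probability logits `tau`,
#'   `item_probs`, the log-likelihood, the per-iteration log-likelihood
#'   `trace` of the best start, and boundary-clamp flags `clamped`.
#' @seealso [posterior()], [param_covariance()], [align_classes()]
#' @export
lca <- function(U, k, n_restarts = 20L, tol = 1e-8, max_iter = 5000L,
                seed = 1L) {
  U <- check_indicators(U)
  n <- nrow(U); p <- ncol(U)
  stopifnot(k >= 1L, n >= k, tol > 0)
  cp <- compress_patterns(U)
  if (k > nrow(cp$U)) {
    cond <- simpleCondition(
      sprintf("degenerate fit: k = %d exceeds the %d distinct response patterns",
              k, nrow(cp$U)))
    class(cond) <- c("lcmediate_degenerate_fit", "error", "condition")
    stop(cond)
  }
  if (k == 1L) {
    pbar <- colSums(cp$counts * ifelse(is.na(cp$U), 0, cp$U)) /
      colSums(cp$counts * !is.na(cp$U))
    pbar <- pmin(pmax(pbar, P_CLAMP), 1 - P_CLAMP)
    ip <- matrix(pbar, 1L, p, dimnames = list(NULL, colnames(U)))
    ll <- sum(cp$counts * measurement_loglik(cp$U, ip))
    return(new_lca(k, pi = 1, item_probs = ip, loglik = ll, n = n,
                   trace = ll, clamped = ip <= P_CLAMP | ip >= 1 - P_CLAMP,
                   converged = TRUE, item_names = colnames(U)))
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    R0 <- matrix(stats::runif(nrow(cp$U) * k), ncol = k)
    R0 <- R0 / rowSums(R0)
    fit <- em_lca(cp, k, R0, tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!best$converged) {
    cond <- simpleCondition("EM did not converge in any restart")
    class(cond) <- c("lcmediate_nonconvergence", "warning", "condition")
    cond$trace <- best$trace
    warning(cond)
  }
  new_lca(k, pi = best$pi, item_probs = best$item_probs, loglik = best$loglik,
          n = n, trace = best$trace, clamped = best$clamped,
          converged = best$converged, item_names = colnames(U))
}

em_lca <- function(cp, k, R, tol, max_iter) {
  counts <- cp$counts
  n <- sum(counts)
  A <- ifelse(is.na(cp$U), 0, cp$U)
  O <- (!is.na(cp$U)) * 1
  OmA <- O - A
  ll_prev <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Rw <- R * counts
    pi <- colSums(Rw) / n
    pi <- pmax(pi, 1e-12); pi <- pi / sum(pi)
    num <- crossprod(Rw, A)               # k x p expected 1s
    den <- crossprod(Rw, O)               # k x p expected observations
    P <- num / pmax(den, 1e-300)
    P <- pmin(pmax(P, P_CLAMP), 1 - P_CLAMP)
    L <- meas_ll_fast(A, OmA, P) + rep(log(pi), each = nrow(A))
    lse <- log_sum_exp_rows(L)
    ll <- sum(counts * lse)
    R <- exp(L - lse)
    trace <- c(trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * abs(ll_prev)) { converged <- TRUE; break }
    ll_prev <- ll
  }
  list(pi = pi, item_probs = P, loglik = ll, trace = trace,
       clamped = P <= P_CLAMP | P >= 1 - P_CLAMP, converged = converged)
}

new_lca <- function(k, pi, item_probs, loglik, n, trace, clamped, converged,
                    item_names, struct_coef = NULL, covariate_names = NULL) {
  p <- ncol(item_probs)
  dimnames(item_probs) <- list(paste0("class", seq_len(k)), item_names)
  obj <- list(k = k, p = p,
              pi = as.vector(pi),
              gamma = if (k > 1L) log(pi[-k] / pi[k]) else numeric(0),
              tau = logit(item_probs),
              item_probs = item_probs,
              loglik = loglik,
              n = n,
              n_params = (k - 1L) + k * p +
                if (is.null(struct_coef)) 0L else length(struct_coef) - (k - 1L),
              trace = trace,
              clamped = clamped,
              converged = converged)
  if (!is.null(struct_coef)) {
    obj$struct_coef <- struct_coef
    obj$covariate_names <- covariate_names
    class(obj) <- c("lca_cond", "lca")
  } else class(obj) <- "lca"
  obj
}

#' @export
print.lca <- function(x, ...) {
  cat(sprintf("%s latent class model: k = %d classes, %d binary indicators, n = %d\n",
              if (inherits(x, "lca_cond")) "Conditional" else "Unconditional",
              x$k, x$p, x$n))
  cat(sprintf("log-likelihood %.3f on %d parameters%s\n", x$loglik, x$n_params,
              if (x$converged) "" else " (EM not converged)"))
  cat("\nClass proportions:\n")
  print(round(x$pi, 4))
  cat("\nItem response probabilities P(U_j = 1 | class):\n")
  print(round(x$item_probs, 3))
  if (inherits(x, "lca_cond")) {
    cat("\nStructural multinomial-logit coefficients (reference = last class):\n")
    print(round(x$struct_coef, 4))
  }
  invisible(x)
}

#' @export
logLik.lca <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}

## ---- posteriors, entropy, classification ----------------------------------

#' Class-assignment probabilities
#'
#' Posterior probabilities `P(X = x | U)` for each row of `U` under a fitted
#' latent class model, computed on the log scale with log-sum-exp. For a
#' conditional model (see [lca_conditional()]) the prior term is
#' per-person, so the matching `covariates` must be supplied and the result
#' is `P(X = x | covariates, U)`.
#'
#' @param object a fitted `"lca"` object.
#' @param U indicator matrix (0/1/`NA`).
#' @param covariates covariate matrix for conditional models.
#' @param ... unused.
#' @return an n x k matrix whose rows sum to one.
#' @export
posterior <- function(object, ...) UseMethod("posterior")

#' @rdname posterior
#' @export
posterior.lca <- function(object, U, covariates = NULL, ...) {
  U <- check_indicators(U)
  stopifnot(ncol(U) == object$p)
  if (inherits(object, "lca_cond")) {
    if (is.null(covariates))
      stop("conditional model: supply the covariates the fit conditioned on")
    Z <- cbind(1, as.matrix(covariates))
    prior_logits <- cbind(Z %*% t(object$struct_coef), 0)
    cp <- compress_patterns(U, extra = cbind(prior_logits))
    L <- measurement_loglik(cp$U, object$item_probs) + cp$extra
  } else {
    cp <- compress_patterns(U)
    L <- sweep(measurement_loglik(cp$U, object$item_probs), 2L,
               log(object$pi), `+`)
  }
  probs <- softmax_rows(L)[cp$index, , drop = FALSE]
  colnames(probs) <- paste0("class", seq_len(object$k))
  probs
}

#' Relative entropy of a posterior matrix
#'
#' `1 - sum_i sum_x (-p_ix log p_ix) / (n log k)`: 1 means perfectly
#' separated classes, 0 means uniformly uncertain assignment. Rows may be
#' weighted, e.g. by pattern counts.
#'
#' @param probs n x k matrix of class-assignment probabilities.
#' @param weights optional row weights.
#' @return a scalar in `[0, 1]`.
#' @export
relative_entropy <- function(probs, weights = NULL) {
  k <- ncol(probs)
  stopifnot(k >= 2L)
  if (is.null(weights)) weights <- rep(1, nrow(probs))
  h <- -rowSums(ifelse(probs > 0, probs * log(probs), 0))
  1 - sum(weights * h) / (sum(weights) * log(k))
}

#' Modal class labels with deterministic tie-breaking
#'
#' Ties go to the lowest class index so repeated runs agree exactly.
#' @param probs n x k posterior matrix.
#' @export
modal_assignment <- function(probs) max.col(probs, ties.method = "first")

#' Classification matrix D\[x, w\] = P(assigned w | true class x)
#'
#' Estimated from posteriors as the posterior-mass-weighted distribution of
#' the modal assignment: `D[x, w] = sum_i p_ix 1(modal_i = w) / sum_i p_ix`.
#' Its inverse supplies the weights of the modified BCH correction.
#'
#' @param probs n x k posterior matrix.
#' @param assignment assignment rule; only `"modal"` is implemented.
#' @return a k x k matrix with unit row sums.
#' @export
classification_matrix <- function(probs, assignment = "modal") {
  assignment <- match.arg(assignment)
  k <- ncol(probs)
  stopifnot(nrow(probs) >= k)
  W <- modal_assignment(probs)
  D <- matrix(0, k, k)
  for (w in seq_len(k)) {
    sel <- W == w
    if (any(sel)) D[, w] <- colSums(probs[sel, , drop = FALSE])
  }
  tot <- rowSums(D)
  if (any(tot <= 0))
    stop("degenerate class: no posterior mass in class ",
         paste(which(tot <= 0), collapse = ", "), call. = FALSE)
  D / tot
}

## ---- parameter covariance --------------------------------------------------

## Observed-data log-likelihood as a function of theta = (gamma, tau)
## (and optionally the structural coefficients, for the one-step model --
## see onestep.R). Used for numerically differentiated information.
lca_theta <- function(fit) c(fit$gamma, as.vector(fit$tau))

lca_loglik_theta <- function(theta, k, p, cp) {
  gamma <- theta[seq_len(k - 1L)]
  tau <- matrix(theta[k - 1L + seq_len(k * p)], k, p)
  pi <- exp(c(gamma, 0)); pi <- pi / sum(pi)
  L <- sweep(measurement_loglik(cp$U, expit(tau)), 2L, log(pi), `+`)
  sum(cp$counts * log_sum_exp_rows(L))
}

#' Covariance of the latent class parameter estimates
#'
#' Inverse of the numerically differentiated observed-data information at
#' the estimate, for the stacked parameter `(gamma, tau)` on the logit
#' scale. Item probabilities that sit on the boundary clamp are flagged:
#' their information is unreliable and downstream exclusion rules key on
#' the largest within-class threshold standard error.
#'
#' @param fit an unconditional `"lca"` fit.
#' @param U the indicator matrix the model was fitted on.
#' @return a list with the full covariance `cov`, `se_gamma`, the k x p
#'   matrix `se_tau`, `max_tau_se`, and per-parameter `flagged` indicators.
#' @export
param_covariance <- function(fit, U) {
  U <- check_indicators(U)
  stopifnot(!inherits(fit, "lca_cond"))
  cp <- compress_patterns(U)
  k <- fit$k; p <- fit$p
  theta <- lca_theta(fit)
  H <- num_hessian(function(th) lca_loglik_theta(th, k, p, cp), theta)
  info <- -H
  V <- tryCatch(solve(info), error = function(e) NULL)
  singular <- is.null(V) || any(!is.finite(V)) || any(diag(V) < 0)
  if (singular) V <- MASS::ginv(psd_repair(info, floor = 1e-10))
  V <- psd_repair(V)
  se <- sqrt(pmax(diag(V), 0))
  se_tau <- matrix(se[k - 1L + seq_len(k * p)], k, p,
                   dimnames = dimnames(fit$tau))
  flagged <- c(rep(FALSE, k - 1L), as.vector(fit$clamped)) |
    !is.finite(se) | singular
  list(cov = V, se_gamma = se[seq_len(k - 1L)], se_tau = se_tau,
       max_tau_se = max(se_tau), flagged = flagged, singular = singular)
}

## ---- label alignment -------------------------------------------------------

#' Align class labels to a reference profile
#'
#' Mixture fits identify classes only up to permutation. This reorders the
#' classes of a fit to minimise the total absolute difference between the
#' fitted item-probability profiles and `ref` (exhaustive over all k!
#' permutations), or, when `ref` is `NULL`, sorts classes by descending
#' size. Needed before any cross-method or cross-replicate comparison.
#'
#' @param fit an `"lca"` fit.
#' @param ref optional k x p matrix of reference item probabilities (e.g.
#'   the generating profiles of a simulation).
#' @return the fit with classes permuted; `$perm` records the permutation
#'   applied (new order in terms of old indices).
#' @export
align_classes <- function(fit, ref = NULL) {
  k <- fit$k
  if (k == 1L) { fit$perm <- 1L; return(fit) }
  if (is.null(ref)) {
    perm <- order(fit$pi, decreasing = TRUE)
  } else {
    stopifnot(nrow(ref) == k, ncol(ref) == fit$p)
    perms <- permutations(k)
    cost <- apply(perms, 1L, function(pr)
      sum(abs(fit$item_probs[pr, , drop = FALSE] - ref)))
    perm <- perms[which.min(cost), ]
  }
  permute_lca(fit, perm)
}

permute_lca <- function(fit, perm) {
  fit$pi <- fit$pi[perm]
  fit$item_probs <- fit$item_probs[perm, , drop = FALSE]
  rownames(fit$item_probs) <- paste0("class", seq_len(fit$k))
  fit$tau <- logit(fit$item_probs)
  fit$clamped <- fit$clamped[perm, , drop = FALSE]
  fit$gamma <- log(fit$pi[-fit$k] / fit$pi[fit$k])
  if (!is.null(fit$struct_coef)) {
    ## re-reference the multinomial logits: with full logits eta_x (old ref
    ## last, eta_old_k = 0), new coefs are eta_perm[x] - eta_perm[k].
    full <- rbind(fit$struct_coef, 0)[perm, , drop = FALSE]
    fit$struct_coef <- sweep(full, 2L, full[fit$k, ], `-`)[-fit$k, , drop = FALSE]
  }
  fit$perm <- perm
  fit
}

## ---- conditional (covariate) LCA ------------------------------------------

#' Fit a latent class model with covariates predicting membership
#'
#' As [lca()], but class membership follows a multinomial-logit structural
#' model in the supplied covariates (reference = last class); the
#' measurement model is unchanged. This is the class-derivation model of
#' inclusive pseudo class draws, where the mediator and outcome enter as
#' covariates so that exported posteriors condition on them.
#'
#' @inheritParams lca
#' @param covariates complete numeric matrix (n x c); rows with missing
#'   covariate values are not allowed.
#' @param init optional unconditional [lca()] fit; its posterior seeds the
#'   first EM start (the remaining `n_restarts - 1` starts stay random),
#'   which speeds convergence markedly and anchors the class labels.
#' @return an object of classes `"lca_cond"` and `"lca"`; `struct_coef` is
#'   the (k-1) x (1+c) coefficient matrix (intercept first).
#' @export
lca_conditional <- function(U, covariates, k, n_restarts = 20L, tol = 1e-8,
                            max_iter = 5000L, seed = 1L, init = NULL) {
  U <- check_indicators(U)
  covariates <- as.matrix(covariates)
  if (anyNA(covariates))
    stop("covariates must be complete (complete-case upstream)", call. = FALSE)
  stopifnot(nrow(covariates) == nrow(U), k >= 2L)
  n <- nrow(U)
  Z <- cbind(`(Intercept)` = 1, covariates)
  cp <- compress_patterns(U, extra = Z)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  starts <- list()
  if (!is.null(init)) {
    stopifnot(inherits(init, "lca"), init$k == k)
    L0 <- sweep(measurement_loglik(cp$U, init$item_probs), 2L,
                log(init$pi), `+`)
    starts[[1L]] <- softmax_rows(L0)
    n_restarts <- n_restarts - 1L
  }
  for (r in seq_len(max(n_restarts, 0L))) {
    R0 <- matrix(stats::runif(nrow(cp$U) * k), ncol = k)
    starts[[length(starts) + 1L]] <- R0 / rowSums(R0)
  }
  best <- NULL
  for (R0 in starts) {
    fit <- em_lca_cond(cp, k, R0, tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (max(abs(best$B)) > 15) {
    cond <- simpleCondition(
      "separation detected in the structural multinomial model")
    class(cond) <- c("lcmediate_nonconvergence", "warning", "condition")
    warning(cond)
  }
  pi_marg <- colSums(cp$counts * best$prior) / n
  cn <- colnames(covariates)
  if (is.null(cn)) cn <- paste0("z", seq_len(ncol(covariates)))
  B <- best$B
  dimnames(B) <- list(paste0("class", seq_len(k - 1L)), c("(Intercept)", cn))
  new_lca(k, pi = pi_marg, item_probs = best$item_probs, loglik = best$loglik,
          n = n, trace = best$trace, clamped = best$clamped,
          converged = best$converged, item_names = colnames(U),
          struct_coef = B, covariate_names = cn)
}

em_lca_cond <- function(cp, k, R, tol, max_iter) {
  counts <- cp$counts
  Z <- cp$extra
  A <- ifelse(is.na(cp$U), 0, cp$U)
  O <- (!is.na(cp$U)) * 1
  OmA <- O - A
  ll_prev <- -Inf; trace <- numeric(0); converged <- FALSE
  B <- matrix(0, k - 1L, ncol(Z))
  for (it in seq_len(max_iter)) {
    Rw <- R * counts
    mfit <- mlogit_fit(Z, Rw, maxit = 30L, start = as.vector(t(B)))
    B <- mfit$coef
    prior_logits <- cbind(Z %*% t(B), 0)
    num <- crossprod(Rw, A); den <- crossprod(Rw, O)
    P <- pmin(pmax(num / pmax(den, 1e-300), P_CLAMP), 1 - P_CLAMP)
    lprior <- prior_logits - log_sum_exp_rows(prior_logits)
    L <- meas_ll_fast(A, OmA, P) + lprior
    lse <- log_sum_exp_rows(L)
    ll <- sum(counts * lse)
    R <- exp(L - lse)
    trace <- c(trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * abs(ll_prev)) { converged <- TRUE; break }
    ll_prev <- ll
  }
  list(B = B, item_probs = P, loglik = ll, trace = trace,
       clamped = P <= P_CLAMP | P >= 1 - P_CLAMP, converged = converged,
       prior = exp(lprior))
}
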