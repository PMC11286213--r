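## One-step estimator: joint maximum likelihood of the latent class
## measurement model and the structural mediation models, by EM. The
## mediator and outcome act as additional class indicators, so posteriors
## condition on (U, M, Y) and the joint observed information propagates
## class-derivation uncertainty into the effect standard errors.

## Per-class structural log-likelihood contributions log P(M | x) +
## log P(Y | x, M) for given rows.
struct_loglik_rows <- function(alpha, beta, k, M, Y, C = NULL) {
  n <- length(M)
  nc <- if (is.null(C)) 0L else ncol(C)
  ac <- if (nc) drop(C %*% alpha[k + seq_len(nc)]) else 0
  bc <- if (nc) drop(C %*% beta[2L * k + seq_len(nc)]) else 0
  out <- matrix(0, n, k)
  for (x in seq_len(k)) {
    a_x <- if (x < k) alpha[1L + x] else 0
    b_x <- if (x < k) beta[2L + x] else 0
    b_xm <- if (x < k) beta[1L + k + x] else 0
    ## clamp away from 0/1 so extreme perturbed parameters cannot produce
    ## 0 * -Inf = NaN in the log-likelihood
    pm <- pmin(pmax(expit(alpha[1L] + a_x + ac), 1e-12), 1 - 1e-12)
    py <- pmin(pmax(expit(beta[1L] + beta[2L] * M + b_x + b_xm * M + bc),
                    1e-12), 1 - 1e-12)
    out[, x] <- M * log(pm) + (1 - M) * log1p(-pm) +
      Y * log(py) + (1 - Y) * log1p(-py)
  }
  out
}

onestep_loglik_theta <- function(theta, k, p, nc, cp) {
  gamma <- theta[seq_len(k - 1L)]
  tau <- matrix(theta[k - 1L + seq_len(k * p)], k, p)
  rest <- theta[-seq_len(k - 1L + k * p)]
  alpha <- rest[seq_len(k + nc)]
  beta <- rest[k + nc + seq_len(2L * k + nc)]
  pi <- exp(c(gamma, 0)); pi <- pi / sum(pi)
  ex <- cp$extra
  C <- if (nc) ex[, 2L + seq_len(nc), drop = FALSE] else NULL
  L <- sweep(measurement_loglik(cp$U, expit(tau)), 2L, log(pi), `+`) +
    struct_loglik_rows(alpha, beta, k, ex[, 1L], ex[, 2L], C)
  sum(cp$counts * log_sum_exp_rows(L))
}

em_onestep <- function(cp, k, R, tol, max_iter, firth) {
  counts <- cp$counts
  n <- sum(counts)
  A <- ifelse(is.na(cp$U), 0, cp$U)
  O <- (!is.na(cp$U)) * 1
  OmA <- O - A
  ex <- cp$extra
  M <- ex[, 1L]; Y <- ex[, 2L]
  nc <- ncol(ex) - 2L
  C <- if (nc) ex[, 2L + seq_len(nc), drop = FALSE] else NULL
  nrow_pat <- nrow(cp$U)
  ll_prev <- -Inf; trace <- numeric(0); converged <- FALSE
  alpha <- NULL; beta <- NULL
  Xm_design <- mediator_design(rep(seq_len(k), each = nrow_pat), k,
                               if (nc) C[rep(seq_len(nrow_pat), k), , drop = FALSE] else NULL)
  Xy_design <- outcome_design(rep(seq_len(k), each = nrow_pat), rep(M, k), k,
                              if (nc) C[rep(seq_len(nrow_pat), k), , drop = FALSE] else NULL)
  Mrep <- rep(M, k); Yrep <- rep(Y, k)
  for (it in seq_len(max_iter)) {
    Rw <- R * counts
    pi <- colSums(Rw) / n
    pi <- pmax(pi, 1e-12); pi <- pi / sum(pi)
    P <- crossprod(Rw, A) / pmax(crossprod(Rw, O), 1e-300)
    P <- pmin(pmax(P, P_CLAMP), 1 - P_CLAMP)
    ## M-step for the structural models: each pattern contributes one row
    ## per class, weighted by its responsibility mass.
    wts <- as.vector(Rw)
    fm <- logit_fit(Xm_design, Mrep, wts, start = alpha)
    fy <- logit_fit(Xy_design, Yrep, wts, start = beta)
    alpha <- fm$coef; beta <- fy$coef
    L <- meas_ll_fast(A, OmA, P) + rep(log(pi), each = nrow_pat) +
      struct_loglik_rows(alpha, beta, k, M, Y, C)
    lse <- log_sum_exp_rows(L)
    ll <- sum(counts * lse)
    R <- exp(L - lse)
    trace <- c(trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * abs(ll_prev)) { converged <- TRUE; break }
    ll_prev <- ll
  }
  list(pi = pi, item_probs = P, alpha = alpha, beta = beta, loglik = ll,
       trace = trace, clamped = P <= P_CLAMP | P >= 1 - P_CLAMP,
       converged = converged)
}

run_onestep <- function(U, M, Y, C, k, onestep_restarts, seed, ref_profiles,
                        firth, lca_fit = NULL, tol = 1e-8, max_iter = 5000L) {
  U <- check_indicators(U)
  n <- nrow(U); p <- ncol(U)
  nc <- if (is.null(C)) 0L else ncol(C)
  extra <- cbind(M, Y, C)
  cp <- compress_patterns(U, extra = extra)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  ## warm start: unconditional LCA responsibilities
  warm <- if (is.null(lca_fit)) {
    align_classes(lca(U, k, n_restarts = 10L, seed = seed),
                  ref = ref_profiles)
  } else lca_fit
  L0 <- sweep(measurement_loglik(cp$U, warm$item_probs), 2L,
              log(warm$pi), `+`)
  starts <- c(list(softmax_rows(L0)),
              replicate(onestep_restarts, {
                R0 <- matrix(stats::runif(nrow(cp$U) * k), ncol = k)
                R0 / rowSums(R0)
              }, simplify = FALSE))
  best <- NULL
  for (R0 in starts) {
    fit <- em_onestep(cp, k, R0, tol, max_iter, firth)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!best$converged) {
    cond <- simpleCondition("one-step EM did not converge in any start")
    class(cond) <- c("lcmediate_nonconvergence", "warning", "condition")
    warning(cond)
  }
  ## align the joint fit to the reference profiles
  lfit <- new_lca(k, pi = best$pi, item_probs = best$item_probs,
                  loglik = best$loglik, n = n, trace = best$trace,
                  clamped = best$clamped, converged = best$converged,
                  item_names = colnames(U))
  perm <- if (is.null(ref_profiles)) order(best$pi, decreasing = TRUE) else {
    perms <- permutations(k)
    perms[which.min(apply(perms, 1L, function(pr)
      sum(abs(best$item_probs[pr, , drop = FALSE] - ref_profiles)))), ]
  }
  lfit <- permute_lca(lfit, perm)
  alpha <- permute_struct_coefs(best$alpha, perm, k, nc, interaction = FALSE)
  beta <- permute_struct_coefs(best$beta, perm, k, nc, interaction = TRUE)
  ## joint observed information -> parameter covariance
  theta <- c(lfit$gamma, as.vector(lfit$tau), alpha, beta)
  H <- num_hessian(function(th) onestep_loglik_theta(th, k, p, nc, cp), theta)
  V <- tryCatch(solve(-H), error = function(e) MASS::ginv(psd_repair(-H, 1e-10)))
  V <- psd_repair(V)
  se <- sqrt(pmax(diag(V), 0))
  ntau <- k * p
  se_tau <- matrix(se[k - 1L + seq_len(ntau)], k, p)
  iab <- k - 1L + ntau + seq_len(3L * k + 2L * nc)
  sp <- structure(list(alpha = alpha, beta = beta,
                       cov_alpha = V[k - 1L + ntau + seq_len(k + nc),
                                     k - 1L + ntau + seq_len(k + nc)],
                       cov_beta = V[k - 1L + ntau + k + nc + seq_len(2L * k + nc),
                                    k - 1L + ntau + k + nc + seq_len(2L * k + nc)],
                       cov_alphabeta = V[iab, iab],
                       k = k, n_confounders = nc, fit_method = "ML",
                       separated = FALSE, converged = best$converged),
                  class = "lcm_struct")
  list(effects = mediation_effects(sp, C_rows = C),
       structural = sp, lca = lfit,
       diagnostics = list(max_tau_se = max(se_tau), se_tau = se_tau,
                          loglik = best$loglik,
                          clamped = any(best$clamped)))
}

## Permute the class labels inside structural coefficient vectors. The
## dummies are defined against the reference (last) class, so re-labelling
## classes re-expresses every class effect relative to the new reference.
permute_struct_coefs <- function(coefs, perm, k, nc, interaction) {
  main_full <- c(coefs[if (interaction) 2L + seq_len(k - 1L) else
    1L + seq_len(k - 1L)], 0)
  main_new <- main_full[perm]; main_new <- main_new - main_new[k]
  out <- coefs
  if (interaction) {
    int_full <- c(coefs[1L + k + seq_len(k - 1L)], 0)
    int_new <- int_full[perm]; int_new <- int_new - int_new[k]
    out[1L] <- coefs[1L] + main_full[perm][k]
    out[2L] <- coefs[2L] + int_full[perm][k]
    out[2L + seq_len(k - 1L)] <- main_new[-k]
    out[1L + k + seq_len(k - 1L)] <- int_new[-k]
  } else {
    out[1L] <- coefs[1L] + main_full[perm][k]
    out[1L + seq_len(k - 1L)] <- main_new[-k]
  }
  out
}
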