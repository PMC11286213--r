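## Newton-Raphson fitters for weighted binary and multinomial logistic
## regression. stats::glm() refuses the negative case weights that the
## modified BCH correction produces, and the EM loops here need fractional
## responsibility weights on aggregated cells, so both fitters are written
## against the weighted estimating equations directly. The Firth (Jeffreys
## prior) modification is available for the binary fitter and is used when
## separation (perfect prediction) is detected.

## Weighted binary logistic regression.
## X: design matrix, y: 0/1 response, w: case weights (may be negative for
## BCH pseudo-groups). Returns ML (or Firth-penalised) coefficients with
## covariance from the observed information of the weighted log-likelihood.
logit_fit <- function(X, y, w = NULL, firth = FALSE,
                      maxit = 200L, tol = 1e-8, start = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); q <- ncol(X)
  if (is.null(w)) w <- rep(1, n)
  stopifnot(length(y) == n, length(w) == n, all(is.finite(w)))
  if (!is.null(start) && length(start) == q && all(is.finite(start))) {
    beta <- start
  } else {
    beta <- numeric(q)
    ## start the intercept at the weighted logit of the mean response
    if (all(X[, 1L] == 1)) {
      ybar <- min(max(sum(w * y) / sum(w), 1e-6), 1 - 1e-6)
      beta[1L] <- logit(ybar)
    }
  }
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- expit(eta)
    v <- w * p * (1 - p)
    H <- crossprod(X, X * v)
    score <- drop(crossprod(X, w * (y - p)))
    if (firth) {
      ## hat values of the weighted information; requires positive weights
      R <- tryCatch(chol(H), error = function(e) NULL)
      if (is.null(R)) break
      XW <- X * sqrt(pmax(v, 0))
      hat <- rowSums((XW %*% chol2inv(R))* XW)
      score <- drop(crossprod(X, w * (y - p) + hat * (0.5 - p)))
    }
    ## tiny ridge keeps the solve nonsingular at zero cells without a
    ## per-iteration tryCatch (this fitter runs ~10^5 times in the chains)
    diag(H) <- diag(H) + 1e-10 * max(abs(diag(H)), 1)
    step <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(step)) break
    ## dampen enormous steps (separation) so iterates stay finite
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(score)) < tol || max(abs(step)) < 1e-9) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  p <- expit(eta)
  v <- w * p * (1 - p)
  H <- crossprod(X, X * v)
  ## singular information (a draw can empty a design cell): report the
  ## Moore-Penrose pseudo-covariance rather than failing outright
  vc <- tryCatch(solve(H), error = function(e) MASS::ginv(H))
  active <- abs(w) > 0
  separated <- (!converged && max(abs(beta)) > 10) ||
    (max(abs(beta)) > 10 &&
       any(active & (p < 1e-8 | p > 1 - 1e-8)))
  list(coef = beta, vcov = vc, fitted = p, converged = converged,
       separated = separated, firth = firth, loglik =
         sum(w * (y * eta - log1p(exp(pmin(eta, 700))))))
}

## Fit with automatic Firth fallback on detected separation.
logit_fit_auto <- function(X, y, w = NULL, firth_on_separation = TRUE,
                           start = NULL, ...) {
  fit <- logit_fit(X, y, w, firth = FALSE, start = start, ...)
  if (firth_on_separation && (fit$separated || !fit$converged) && all(w >= 0 | is.null(w))) {
    fit2 <- logit_fit(X, y, w, firth = TRUE, ...)
    if (fit2$converged) { fit2$separated <- TRUE; return(fit2) }
  }
  fit
}

## Weighted multinomial logistic regression with the LAST category as the
## reference. Z: u x q design (unique covariate rows), Wt: u x k matrix of
## nonnegative class weights per row (fractional responsibilities allowed).
## Returns a (k-1) x q coefficient matrix.
mlogit_fit <- function(Z, Wt, maxit = 200L, tol = 1e-9, start = NULL) {
  Z <- as.matrix(Z)
  u <- nrow(Z); q <- ncol(Z); k <- ncol(Wt)
  stopifnot(nrow(Wt) == u, k >= 2L)
  nrow_tot <- rowSums(Wt)
  d <- (k - 1L) * q
  theta <- if (!is.null(start) && length(start) == d && all(is.finite(start)))
    start else numeric(d)
  for (it in seq_len(maxit)) {
    B <- matrix(theta, k - 1L, q, byrow = TRUE)     # (k-1) x q
    Eta <- cbind(Z %*% t(B), 0)                     # u x k
    P <- softmax_rows(Eta)
    ## score
    resid <- Wt[, -k, drop = FALSE] - nrow_tot * P[, -k, drop = FALSE]
    score <- as.vector(crossprod(Z, resid))         # class-major blocks
    ## Hessian blocks: H[(a,b)] = -sum_i n_i z z' (P_a (1(a=b) - P_b))
    H <- matrix(0, d, d)
    for (a in seq_len(k - 1L)) for (b in seq.int(a, k - 1L)) {
      wab <- nrow_tot * (P[, a] * ((a == b) - P[, b]))
      blk <- crossprod(Z, Z * wab)
      ia <- (a - 1L) * q + seq_len(q); ib <- (b - 1L) * q + seq_len(q)
      H[ia, ib] <- blk
      if (a != b) H[ib, ia] <- t(blk)
    }
    step <- tryCatch(solve(H, score), error = function(e)
      solve(H + diag(1e-8, d), score))
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    ## step-halve on the weighted multinomial log-likelihood so the
    ## surrounding EM loop keeps its monotone ascent
    obj0 <- sum(Wt * (Eta - log_sum_exp_rows(Eta)))
    for (half in 0:8) {
      th_new <- pmin(pmax(theta + step, -15), 15)
      Bn <- matrix(th_new, k - 1L, q, byrow = TRUE)
      En <- cbind(Z %*% t(Bn), 0)
      if (sum(Wt * (En - log_sum_exp_rows(En))) >= obj0 - 1e-10) break
      step <- step / 2
    }
    theta <- th_new
    if (max(abs(score)) < tol || max(abs(step)) < 1e-12) break
  }
  B <- matrix(theta, k - 1L, q, byrow = TRUE)
  list(coef = B, converged = max(abs(step)) < 1, niter = it)
}
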