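## Structural mediation models for an observed (or imputed) class variable
## W, binary mediator M and binary outcome Y, with an exposure-mediator
## interaction:
##   P(Y = 1 | W, M, C) = expit(b0 + b1 M + sum_x b_x I(W=x) + sum_x b_xm I(W=x) M + C)
##   P(M = 1 | W, C)    = expit(a0 + sum_x a_x I(W=x) + C)
## Dummy coding is fixed with the LAST class as the reference, matching the
## aligned class order (risk classes first, "Low" last). Counterfactual
## effects are computed by direct application of the mediation formula and
## reported as log risk ratios.

## ---- design builders -------------------------------------------------------

dummy_matrix <- function(W, k) {
  D <- matrix(0, length(W), k - 1L)
  for (x in seq_len(k - 1L)) D[, x] <- as.numeric(W == x)
  colnames(D) <- paste0("X", seq_len(k - 1L))
  D
}

outcome_design <- function(W, M, k, C = NULL) {
  D <- dummy_matrix(W, k)
  X <- cbind(`(Intercept)` = 1, M = M, D, D * M)
  colnames(X)[(k + 2L):(2L * k)] <- paste0("X", seq_len(k - 1L), ":M")
  if (!is.null(C)) X <- cbind(X, C)
  X
}

mediator_design <- function(W, k, C = NULL) {
  X <- cbind(`(Intercept)` = 1, dummy_matrix(W, k))
  if (!is.null(C)) X <- cbind(X, C)
  X
}

## Aggregate (W, M, Y) rows with summed weights: logistic fits with only
## categorical predictors depend on the data through these cell sums alone,
## which keeps per-draw refits O(k) rather than O(n).
aggregate_cells <- function(W, M, Y, w) {
  idx <- (W - 1L) + max(W) * (M + 2L * Y) + 1L
  sums <- rowsum(w, idx)
  keep <- as.integer(rownames(sums))
  first <- match(keep, idx)
  list(W = W[first], M = M[first], Y = Y[first], w = as.vector(sums))
}

## ---- structural fits -------------------------------------------------------

#' Fit the mediator and outcome models for an observed class variable
#'
#' Maximum-likelihood logistic fits of the outcome model (with
#' class-by-mediator interaction) and the mediator model, honouring case
#' weights (negative weights from the BCH correction are accepted). On
#' detected separation the fit is retried with the Firth (Jeffreys-prior)
#' penalty when `firth_on_separation` is `TRUE`.
#'
#' @param W integer class labels in 1..k (reference = class k).
#' @param M,Y binary mediator and outcome vectors.
#' @param C optional complete confounder matrix, entering both models as
#'   main effects.
#' @param k number of classes.
#' @param weights optional case weights.
#' @param firth_on_separation retry with Firth penalty on separation.
#' @return an object of class `"lcm_struct"` carrying `alpha`, `beta`,
#'   their covariances, and fit metadata.
#' @export
structural_fit <- function(W, M, Y, C = NULL, k = max(W), weights = NULL,
                           firth_on_separation = TRUE, start = NULL) {
  n <- length(W)
  stopifnot(length(M) == n, length(Y) == n,
            !anyNA(W), !anyNA(M), !anyNA(Y))
  if (length(unique(Y)) < 2L || length(unique(M)) < 2L)
    stop("both levels of M and Y must be present", call. = FALSE)
  if (is.null(C) && is.null(weights)) {
    ## unweighted categorical-only fits depend on the data through the
    ## (W, M, Y) cell counts alone: tabulate once over the fixed 4k grid
    cw <- tabulate(W + k * (M + 2L * Y), 4L * k)
    gW <- rep(seq_len(k), 4L)
    gM <- rep(rep(0:1, each = k), 2L)
    gY <- rep(0:1, each = 2L * k)
    fy <- logit_fit_auto(outcome_design(gW, gM, k), gY, cw,
                         firth_on_separation = firth_on_separation,
                         start = start$beta)
    fm <- logit_fit_auto(mediator_design(gW, k), gM, cw,
                         firth_on_separation = firth_on_separation,
                         start = start$alpha)
    return(structure(list(alpha = fm$coef, beta = fy$coef,
                          cov_alpha = fm$vcov, cov_beta = fy$vcov,
                          k = k, n_confounders = 0L,
                          fit_method = if (fy$firth || fm$firth) "Firth" else "ML",
                          separated = fy$separated || fm$separated,
                          converged = fy$converged && fm$converged),
                     class = "lcm_struct"))
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(C)) {
    cells <- aggregate_cells(W, M, Y, weights)
    Xy <- outcome_design(cells$W, cells$M, k)
    Xm <- mediator_design(cells$W, k)
    fy <- logit_fit_auto(Xy, cells$Y, cells$w,
                         firth_on_separation = firth_on_separation)
    ## the mediator model ignores Y: same cells, response M
    fm <- logit_fit_auto(Xm, cells$M, cells$w,
                         firth_on_separation = firth_on_separation)
  } else {
    C <- as.matrix(C)
    if (is.null(colnames(C))) colnames(C) <- paste0("c", seq_len(ncol(C)))
    fy <- logit_fit_auto(outcome_design(W, M, k, C), Y, weights,
                         firth_on_separation = firth_on_separation)
    fm <- logit_fit_auto(mediator_design(W, k, C), M, weights,
                         firth_on_separation = firth_on_separation)
  }
  structure(list(alpha = fm$coef, beta = fy$coef,
                 cov_alpha = fm$vcov, cov_beta = fy$vcov,
                 k = k, n_confounders = if (is.null(C)) 0L else ncol(C),
                 fit_method = if (fy$firth || fm$firth) "Firth" else "ML",
                 separated = fy$separated || fm$separated,
                 converged = fy$converged && fm$converged),
            class = "lcm_struct")
}

#' @export
print.lcm_struct <- function(x, ...) {
  cat(sprintf("Structural mediation models (k = %d classes, %s fit)\n",
              x$k, x$fit_method))
  cat("alpha (mediator model):", round(x$alpha, 4), "\n")
  cat("beta  (outcome model): ", round(x$beta, 4), "\n")
  invisible(x)
}

## ---- mediation formula -----------------------------------------------------

## Split the stacked parameter vector into model pieces.
sp_split <- function(theta, k, nc) {
  na <- k + nc; nb <- 2L * k + nc
  list(alpha = theta[seq_len(na)], beta = theta[na + seq_len(nb)])
}

## E[Y(x, M(x*))] for one (x, x*) pair given parameter values, averaging
## over the empirical confounder rows when supplied (marginal
## standardisation).
po_value <- function(alpha, beta, k, x, x_star, C_rows = NULL) {
  if (is.null(C_rows)) C_rows <- matrix(0, 1L, 0L)
  nc <- ncol(C_rows)
  ac <- if (nc) C_rows %*% alpha[k + seq_len(nc)] else 0
  bc <- if (nc) C_rows %*% beta[2L * k + seq_len(nc)] else 0
  a_x <- function(x) if (x < k) alpha[1L + x] else 0
  b_x <- function(x) if (x < k) beta[2L + x] else 0
  b_xm <- function(x) if (x < k) beta[1L + k + x] else 0
  pm <- expit(alpha[1L] + a_x(x_star) + ac)
  py0 <- expit(beta[1L] + b_x(x) + bc)
  py1 <- expit(beta[1L] + beta[2L] + b_x(x) + b_xm(x) + bc)
  if (any(pm %in% c(0, 1)) || any(py0 %in% c(0, 1)) || any(py1 %in% c(0, 1)))
    stop("degenerate cell: a required conditional probability is exactly 0 or 1",
         call. = FALSE)
  mean(py0 * (1 - pm) + py1 * pm)
}

#' Potential-outcome probability E\[Y(x, M(x*))\]
#'
#' Mediation-formula evaluation
#' `sum_m P(Y = 1 | X = x, M = m) P(M = m | X = x*)` from fitted structural
#' parameters. With confounders the expression is evaluated per confounder
#' row and averaged over the supplied empirical rows, so effects derived
#' from it are marginal rather than conditional.
#'
#' @param sp an `"lcm_struct"` fit (see [structural_fit()]).
#' @param x class whose outcome model is used.
#' @param x_star class whose mediator distribution is used.
#' @param C_rows optional confounder sample to standardise over.
#' @return a probability in (0, 1).
#' @export
potential_outcome <- function(sp, x, x_star, C_rows = NULL) {
  stopifnot(x %in% seq_len(sp$k), x_star %in% seq_len(sp$k))
  po_value(sp$alpha, sp$beta, sp$k, x, x_star, C_rows)
}

effects_from_theta <- function(theta, k, nc, comparisons, reference, C_rows) {
  pr <- sp_split(theta, k, nc)
  l_ref <- log(po_value(pr$alpha, pr$beta, k, reference, reference, C_rows))
  out <- matrix(0, length(comparisons), 3L,
                dimnames = list(NULL, c("TE", "TNIE", "PNDE")))
  for (i in seq_along(comparisons)) {
    x <- comparisons[i]
    l_xx <- log(po_value(pr$alpha, pr$beta, k, x, x, C_rows))
    l_xr <- log(po_value(pr$alpha, pr$beta, k, x, reference, C_rows))
    out[i, ] <- c(l_xx - l_ref, l_xx - l_xr, l_xr - l_ref)
  }
  out
}

#' Counterfactual mediation effects on the log risk-ratio scale
#'
#' For each non-reference class x the total effect
#' `TE = log E[Y(x, M(x))] - log E[Y(ref, M(ref))]`, the total natural
#' indirect effect `TNIE = log E[Y(x, M(x))] - log E[Y(x, M(ref))]` and the
#' pure natural direct effect `PNDE = log E[Y(x, M(ref))] - log E[Y(ref,
#' M(ref))]`; `TE = TNIE + PNDE` holds identically. Standard errors use the
#' delta method: central finite-difference gradients in `(alpha, beta)`
#' sandwiched with the block-diagonal covariance of the two fits.
#'
#' @param sp an `"lcm_struct"` fit.
#' @param reference reference class (default: the last, "Low", class).
#' @param C_rows optional confounder rows for marginal standardisation.
#' @param se compute delta-method standard errors (disable for speed inside
#'   tight loops that only need point estimates).
#' @return a data frame of class `"mediation_effects"` with columns
#'   `comparison`, `estimand`, `estimate` (log RR), `se`, `rr`, `ci_low`,
#'   `ci_high` (Wald 95%, log scale).
#' @export
mediation_effects <- function(sp, reference = sp$k, C_rows = NULL, se = TRUE) {
  k <- sp$k; nc <- sp$n_confounders
  if (!is.null(C_rows)) C_rows <- as.matrix(C_rows)
  stopifnot(reference %in% seq_len(k), nc == 0L || !is.null(C_rows))
  comparisons <- setdiff(seq_len(k), reference)
  theta <- c(sp$alpha, sp$beta)
  est <- effects_from_theta(theta, k, nc, comparisons, reference, C_rows)
  if (se) {
    d <- length(theta)
    G <- matrix(0, length(comparisons) * 3L, d)
    for (j in seq_len(d)) {
      e <- numeric(d); e[j] <- 1e-5
      G[, j] <- (as.vector(effects_from_theta(theta + e, k, nc, comparisons,
                                              reference, C_rows)) -
                 as.vector(effects_from_theta(theta - e, k, nc, comparisons,
                                              reference, C_rows))) / 2e-5
    }
    na <- length(sp$alpha)
    if (!is.null(sp$cov_alphabeta)) {
      ## joint fits (one-step) carry the full (alpha, beta) covariance,
      ## including cross terms and propagated measurement uncertainty
      Sigma <- sp$cov_alphabeta
    } else {
      Sigma <- matrix(0, d, d)
      Sigma[seq_len(na), seq_len(na)] <- sp$cov_alpha
      Sigma[na + seq_len(d - na), na + seq_len(d - na)] <- sp$cov_beta
    }
    ses <- matrix(sqrt(pmax(rowSums((G %*% Sigma) * G), 0)),
                  length(comparisons), 3L)
  } else ses <- matrix(NA_real_, length(comparisons), 3L)
  out <- data.frame(
    comparison = rep(paste0("class", comparisons, " vs class", reference),
                     each = 3L),
    estimand = rep(c("TE", "TNIE", "PNDE"), length(comparisons)),
    estimate = as.vector(t(est)),
    se = as.vector(t(ses)))
  out$rr <- exp(out$estimate)
  out$ci_low <- out$estimate - 1.96 * out$se
  out$ci_high <- out$estimate + 1.96 * out$se
  attr(out, "scale") <- "log risk ratio"
  attr(out, "reference") <- reference
  class(out) <- c("mediation_effects", "data.frame")
  out
}

#' @export
print.mediation_effects <- function(x, digits = 4, ...) {
  cat("Counterfactual mediation effects (log risk-ratio scale; reference = class",
      attr(x, "reference"), ")\n")
  df <- as.data.frame(x)
  df[] <- lapply(df, function(v) if (is.numeric(v)) round(v, digits) else v)
  print(df, row.names = FALSE)
  invisible(x)
}
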