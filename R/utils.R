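## Small numerical helpers shared across the package.

expit <- function(x) stats::plogis(x)
logit <- function(p) stats::qlogis(p)

## Fast row maxima (k is small; pmax over columns beats apply by ~10x).
row_maxima <- function(L) {
  m <- L[, 1L]
  for (j in seq_len(ncol(L))[-1L]) m <- pmax(m, L[, j])
  m
}

## Row-wise log-sum-exp for an n x k matrix of log-weights.
log_sum_exp_rows <- function(L) {
  m <- row_maxima(L)
  m + log(rowSums(exp(L - m)))
}

## Normalise rows of exp(L) safely; returns a probability matrix.
softmax_rows <- function(L) {
  m <- row_maxima(L)
  E <- exp(L - m)
  E / rowSums(E)
}

## Deterministic child seeds derived from a root seed. Keeps every seed a
## positive 32-bit integer so set.seed() accepts it anywhere.
derive_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

## All permutations of 1..k (k small; used for label alignment).
permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(k - 1L)
  out <- matrix(0L, 0L, k)
  for (pos in seq_len(k)) {
    left <- sub[, seq_len(pos - 1L), drop = FALSE]
    right <- if (pos <= k - 1L) sub[, seq.int(pos, k - 1L), drop = FALSE]
             else sub[, 0L, drop = FALSE]
    out <- rbind(out, cbind(left, k, right))
  }
  out
}

## Symmetrise and floor the eigenvalues of a covariance matrix so that
## downstream Cholesky/MVN draws never fail on tiny negative eigenvalues.
psd_repair <- function(S, floor = 0) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < floor) {
    v <- pmax(e$values, floor)
    S <- e$vectors %*% (v * t(e$vectors))
    S <- (S + t(S)) / 2
  }
  S
}

## Draw one class label per row from an n x k probability matrix using a
## single uniform per row (shared by all pseudo-class-draw methods so that
## equal posteriors plus equal seeds give equal draws).
draw_classes <- function(probs, u = NULL) {
  n <- nrow(probs); k <- ncol(probs)
  if (is.null(u)) u <- stats::runif(n)
  W <- rep(1L, n)
  cp <- probs[, 1L]
  if (k > 1L) for (x in seq_len(k - 1L)) {
    W <- W + (u > cp)
    if (x < k - 1L) cp <- cp + probs[, x + 1L]
  }
  pmin.int(W, k)
}

## Central-difference gradient of a scalar function.
num_gradient <- function(f, x, h = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    e <- numeric(length(x)); e[i] <- h
    g[i] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  g
}

## Central-difference Hessian of a scalar function (symmetrised).
num_hessian <- function(f, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- f(x)
  hs <- pmax(h, h * abs(x))
  for (i in seq_len(d)) {
    ei <- numeric(d); ei[i] <- hs[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / hs[i]^2
    if (i < d) for (j in seq.int(i + 1L, d)) {
      ej <- numeric(d); ej[j] <- hs[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * hs[i] * hs[j])
    }
  }
  H
}
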