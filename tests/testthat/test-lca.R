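test_that("one-class fit collapses to independent Bernoulli estimates", {
  set.seed(2)
  U <- matrix(rbinom(200, 1, rep(c(0.3, 0.7), each = 100)), ncol = 2)
  f <- lca(U, k = 1)
  expect_equal(f$pi, 1)
  expect_equal(unname(f$tau[1, ]), unname(qlogis(colMeans(U))),
               tolerance = 1e-9)
  ll <- sum(dbinom(U, 1, rep(colMeans(U), each = 100), log = TRUE))
  expect_equal(f$loglik, ll, tolerance = 1e-8)
})

test_that("EM log-likelihood is monotone nondecreasing on every trace", {
  for (seed in 1:4) {
    d <- make_two_class_data(300, p1 = c(0.8, 0.6), p2 = c(0.3, 0.2),
                             seed = seed)
    f <- lca(d$U, k = 2, n_restarts = 3, seed = seed)
    expect_true(all(diff(f$trace) >= -1e-7 * abs(f$loglik)))
  }
  ## and on a realistic four-class dataset
  sc <- get_scenario("medium")
  dd <- lcm_simulate(sc, n = 2000, seed = 9)
  f <- lca(as.matrix(dd[paste0("u", 1:5)]), 4, n_restarts = 5, seed = 3)
  expect_true(all(diff(f$trace) >= -1e-7 * abs(f$loglik)))
})

test_that("two-class parameter recovery within 0.02 at n = 10,000", {
  d <- make_two_class_data(10000, seed = 7)
  f <- align_classes(lca(d$U, 2, seed = 11), ref = d$item_probs)
  expect_lt(max(abs(f$item_probs - d$item_probs)), 0.02)
  expect_lt(abs(f$pi[1] - 0.5), 0.02)
})

test_that("EM beats a brute-force grid with items constrained equal within class", {
  U <- rbind(c(1, 1), c(1, 1), c(1, 0), c(0, 0), c(0, 0), c(0, 1))
  f <- suppressWarnings(lca(U, 2, n_restarts = 10, seed = 3))
  ## oracle: grid over (pi1, p1, p2), both items sharing p within a class
  grid <- seq(0.025, 0.975, length.out = 20)
  best <- -Inf
  for (pi1 in grid) for (p1 in grid) for (p2 in grid) {
    l1 <- rowSums(U) * log(p1) + rowSums(1 - U) * log(1 - p1)
    l2 <- rowSums(U) * log(p2) + rowSums(1 - U) * log(1 - p2)
    ll <- sum(log(pi1 * exp(l1) + (1 - pi1) * exp(l2)))
    if (ll > best) best <- ll
  }
  expect_gte(f$loglik, best)
})

test_that("degenerate k and malformed indicator input are rejected", {
  U <- rbind(c(1, 1), c(1, 1), c(0, 0))   # two distinct patterns
  expect_error(lca(U, k = 3), class = "lcmediate_degenerate_fit")
  expect_error(lca(matrix(c(1, 2, 0, 1), 2), 1), "0, 1 or NA")
  expect_error(lca(rbind(c(NA, NA), c(1, 0)), 1), "non-missing")
})

test_that("posteriors follow Bayes rule exactly on a hand-computed toy", {
  pi <- c(0.3, 0.7)
  P <- rbind(c(0.9, 0.2), c(0.4, 0.6))
  f <- suppressWarnings(lca(rbind(c(1, 0), c(0, 1), c(1, 1), c(0, 0)), 2,
                            n_restarts = 2, seed = 1))
  f$pi <- pi; f$item_probs <- P; f$tau <- qlogis(P)  # inject known params
  U <- rbind(c(1, 0), c(0, 1), c(1, 1))
  pp <- posterior(f, U)
  for (i in 1:3) {
    num <- pi * apply(P, 1, function(px)
      prod(px^U[i, ] * (1 - px)^(1 - U[i, ])))
    expect_equal(unname(pp[i, ]), unname(num / sum(num)), tolerance = 1e-12)
  }
  expect_equal(rowSums(pp), rep(1, 3), tolerance = 1e-10)
})

test_that("posterior edge cases: one class, symmetric classes, missing cells", {
  set.seed(4)
  U <- matrix(rbinom(60, 1, 0.5), ncol = 2)
  f1 <- lca(U, 1)
  expect_equal(unname(posterior(f1, U)[, 1]), rep(1, 30))
  ## identical measurement rows and equal priors: posterior is uniform
  d <- make_two_class_data(50, seed = 2)
  f2 <- suppressWarnings(lca(d$U, 2, n_restarts = 2, seed = 2))
  f2$pi <- c(0.5, 0.5)
  f2$item_probs <- rbind(c(0.4, 0.7), c(0.4, 0.7))
  pp <- posterior(f2, d$U)
  expect_equal(unname(pp), matrix(0.5, nrow(d$U), 2), tolerance = 1e-12)
  ## FIML: a missing cell contributes nothing
  f2$item_probs <- rbind(c(0.9, 0.2), c(0.3, 0.8))
  p_miss <- posterior(f2, rbind(c(1, NA)))
  num <- c(0.5 * 0.9, 0.5 * 0.3)
  expect_equal(unname(p_miss[1, ]), num / sum(num), tolerance = 1e-12)
  ## rows with the same observed pattern share a posterior row
  p2 <- posterior(f2, rbind(c(1, 0), c(1, 0)))
  expect_identical(p2[1, ], p2[2, ])
})

test_that("relative entropy spans [0, 1] with the right endpoints", {
  onehot <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(relative_entropy(onehot), 1)
  expect_equal(relative_entropy(matrix(1 / 4, 10, 4)), 0, tolerance = 1e-12)
})

test_that("classification matrix rows sum to 1, with documented tie-breaking", {
  onehot <- diag(4)[sample(1:4, 40, replace = TRUE), ]
  expect_equal(classification_matrix(onehot), diag(4))
  unif <- matrix(1 / 3, 9, 3)
  D <- classification_matrix(unif)   # ties resolved to class 1
  expect_equal(D, cbind(rep(1, 3), 0, 0))
  set.seed(1)
  pp <- lcmediate:::softmax_rows(matrix(rnorm(300), ncol = 3))
  expect_equal(rowSums(classification_matrix(pp)), rep(1, 3),
               tolerance = 1e-10)
})

test_that("parameter covariance matches the binomial closed form in the one-class limit", {
  set.seed(12)
  U <- matrix(rbinom(400, 1, 0.3), ncol = 1)
  f <- lca(U, 1)
  pc <- param_covariance(f, U)
  phat <- mean(U)
  expect_equal(unname(pc$se_tau[1, 1]),
               sqrt(1 / (400 * phat * (1 - phat))), tolerance = 1e-4)
})

test_that("parameter variance scales as 1/n", {
  set.seed(77)
  ratios <- replicate(10, {
    s <- sample.int(1e6, 1)
    d1 <- make_two_class_data(1500, p1 = c(0.85, 0.8), p2 = c(0.2, 0.15),
                              seed = s)
    d2 <- make_two_class_data(3000, p1 = c(0.85, 0.8), p2 = c(0.2, 0.15),
                              seed = s + 1)
    v1 <- param_covariance(align_classes(lca(d1$U, 2, n_restarts = 5,
                                             seed = s), d1$item_probs), d1$U)
    v2 <- param_covariance(align_classes(lca(d2$U, 2, n_restarts = 5,
                                             seed = s), d2$item_probs), d2$U)
    mean(diag(v1$cov)) / mean(diag(v2$cov))
  })
  expect_lt(abs(mean(ratios) - 2), 0.3)
})

test_that("boundary-clamped item probabilities are flagged", {
  ## an indicator that is always 1 drives its probability to the clamp
  set.seed(3)
  U <- cbind(rep(1, 100), rbinom(100, 1, 0.4))
  f <- lca(U, 1)
  pc <- param_covariance(f, U)
  expect_true(f$clamped[1, 1])
  expect_true(any(pc$flagged))
})

test_that("label alignment is permutation-proof and re-references conditional coefficients", {
  d <- make_two_class_data(4000, seed = 21)
  f <- lca(d$U, 2, seed = 5)
  a1 <- align_classes(f, ref = d$item_probs)
  a2 <- align_classes(lcmediate:::permute_lca(f, c(2, 1)), ref = d$item_probs)
  expect_equal(a1$item_probs, a2$item_probs, tolerance = 1e-12)
  expect_equal(a1$pi, a2$pi, tolerance = 1e-12)
  ## descending-size ordering when no reference is given
  a3 <- align_classes(f)
  expect_true(all(diff(a3$pi) <= 0))
})

test_that("conditional LCA with null covariates matches the unconditional fit", {
  d <- make_two_class_data(2000, p1 = c(0.9, 0.8), p2 = c(0.2, 0.1),
                           seed = 33)
  f0 <- align_classes(lca(d$U, 2, n_restarts = 5, seed = 2), d$item_probs)
  fc <- align_classes(lca_conditional(d$U, matrix(0, 2000, 1), 2,
                                      n_restarts = 5, seed = 2),
                      d$item_probs)
  expect_equal(fc$loglik, f0$loglik, tolerance = 1e-6)
  expect_equal(fc$pi, f0$pi, tolerance = 1e-4)
  expect_equal(fc$item_probs, f0$item_probs, tolerance = 1e-4)
})

test_that("conditional LCA recovers a class-on-covariate log-odds of 1", {
  set.seed(61)
  n <- 10000
  z <- rbinom(n, 1, 0.5)
  ## class 1 log-odds increases by 1 with z (reference class 2)
  pr1 <- plogis(-0.5 + 1.0 * z)
  X <- ifelse(runif(n) < pr1, 1L, 2L)
  P <- rbind(c(0.9, 0.85, 0.8), c(0.15, 0.2, 0.25))
  U <- sapply(1:3, function(j) rbinom(n, 1, P[X, j]))
  fc <- align_classes(lca_conditional(U, cbind(z = z), 2, n_restarts = 5,
                                      seed = 4), P)
  expect_lt(abs(fc$struct_coef[1, "z"] - 1.0), 0.15)
  ## posteriors move in the direction of the fitted coefficient
  pp <- posterior(fc, rbind(c(1, 1, 0), c(1, 1, 0)),
                  covariates = cbind(z = c(0, 1)))
  expect_gt(pp[2, 1], pp[1, 1])
  ## covariates must be complete
  expect_error(lca_conditional(U, cbind(c(NA, z[-1])), 2), "complete")
})
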