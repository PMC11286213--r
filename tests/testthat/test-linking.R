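test_that("BCH weights: identity, 2x2 closed form, unit row sums", {
  ## identity classification: weights are one-hot
  W <- c(1L, 2L, 3L, 2L)
  H <- bch_weights(diag(3), W)
  expect_equal(H, diag(3)[W, ])
  ## symmetric 2x2 error matrix has a closed-form inverse
  e <- 0.15
  D <- matrix(c(1 - e, e, e, 1 - e), 2, byrow = TRUE)
  Hinv <- matrix(c(1 - e, -e, -e, 1 - e), 2, byrow = TRUE) / (1 - 2 * e)
  expect_equal(bch_weights(D, c(1L, 2L)), Hinv, tolerance = 1e-12)
  ## row sums are 1 for every person, for any classification matrix
  set.seed(6)
  pp <- lcmediate:::softmax_rows(matrix(rnorm(200 * 4, sd = 2), ncol = 4))
  D4 <- classification_matrix(pp)
  Hw <- bch_weights(D4, modal_assignment(pp))
  expect_equal(rowSums(Hw), rep(1, 200), tolerance = 1e-10)
})

test_that("with perfect class separation, modal, BCH and one-step match the oracle true-class fit", {
  set.seed(14)
  n <- 1200
  X <- sample(1:3, n, replace = TRUE, prob = c(0.25, 0.3, 0.45))
  ## deterministic indicator patterns: no residual class ambiguity at all
  P <- rbind(c(1, 1, 0), c(0, 1, 1), c(0, 0, 0))
  U <- sapply(1:3, function(j) P[X, j])
  M <- rbinom(n, 1, plogis(-1 + 0.5 * (X == 1)))
  Y <- rbinom(n, 1, plogis(-0.5 + 0.4 * M + 0.6 * (X == 1) - 0.3 * (X == 2)))
  oracle <- mediation_effects(structural_fit(X, M, Y, k = 3))
  fm <- lcmediate(U, M, Y, k = 3, method = "modal", ref_profiles = P,
                  seed = 2)
  fb <- lcmediate(U, M, Y, k = 3, method = "bch", ref_profiles = P, seed = 2)
  fo <- lcmediate(U, M, Y, k = 3, method = "onestep", ref_profiles = P,
                  seed = 2)
  expect_equal(coef(fm), setNames(oracle$estimate,
                                  names(coef(fm))), tolerance = 1e-6)
  expect_equal(coef(fb), coef(fm), tolerance = 1e-6)
  expect_equal(coef(fo), coef(fm), tolerance = 0.02)
  expect_gt(fm$diagnostics$entropy, 0.999)
})

test_that("nPCD with one-hot posteriors reduces to modal assignment", {
  set.seed(14)
  n <- 1200
  X <- sample(1:3, n, replace = TRUE, prob = c(0.25, 0.3, 0.45))
  P <- rbind(c(0.999, 0.999, 0.001), c(0.001, 0.999, 0.999),
             c(0.001, 0.001, 0.001))
  U <- sapply(1:3, function(j) rbinom(n, 1, P[X, j]))
  M <- rbinom(n, 1, plogis(-1 + 0.5 * (X == 1)))
  Y <- rbinom(n, 1, plogis(-0.5 + 0.4 * M + 0.6 * (X == 1)))
  fmod <- lcmediate(U, M, Y, k = 3, method = "modal", ref_profiles = P,
                    seed = 5)
  fnp <- lcmediate(U, M, Y, k = 3, method = "npcd", m = 7, ref_profiles = P,
                   seed = 5)
  expect_equal(coef(fnp), coef(fmod), tolerance = 1e-9)
  ## degenerate posteriors: between-imputation variance vanishes
  expect_lt(max(fnp$effects$between_var), 1e-20)
})

test_that("modal ties break deterministically to the lowest class index", {
  expect_equal(modal_assignment(matrix(1 / 3, 5, 3)), rep(1L, 5))
  expect_equal(modal_assignment(rbind(c(0.2, 0.4, 0.4))), 2L)
})

test_that("Rubin pooling follows the textbook identities", {
  ## identical draws: no between-imputation variance
  p0 <- rubin_pool(rep(1.7, 8), rep(0.04, 8))
  expect_equal(p0$between_var, 0)
  expect_equal(p0$total_se, sqrt(0.04))
  ## hand example: m = 2, estimates {0, 1}, variances {1, 1}
  p <- rubin_pool(c(0, 1), c(1, 1))
  expect_equal(p$estimate, 0.5)
  expect_equal(p$between_var, 0.5)
  expect_equal(p$total_se^2, 1 + 1.5 * 0.5)
  expect_equal(p$mc_error, sqrt(0.5 / 2))
  ## the imputation-count rule: mc_error / SE <= 10% is measurable
  expect_lt(p0$mc_error / p0$total_se, 0.10)
})

test_that("pooled estimates stabilise as the number of imputations grows", {
  sc <- get_scenario("good")
  d <- lcm_simulate(sc, n = 1500, seed = 42)
  U <- as.matrix(d[paste0("u", 1:5)])
  f <- align_classes(lca(U, 4, n_restarts = 5, seed = 1),
                     sc$item_profiles)
  f10 <- lcmediate(U, d$m, d$y, k = 4, method = "npcd", m = 10,
                   lca_fit = f, seed = 3)
  f60 <- lcmediate(U, d$m, d$y, k = 4, method = "npcd", m = 60,
                   lca_fit = f, seed = 3)
  ## mc_error shrinks roughly as 1/sqrt(m)
  expect_lt(median(f60$effects$mc_error / f10$effects$mc_error), 0.7)
  ## pooled estimates agree within joint Monte Carlo error
  dd <- abs(coef(f10) - coef(f60))
  tol <- 3 * sqrt(f10$effects$mc_error^2 + f60$effects$mc_error^2)
  expect_true(all(dd <= pmax(tol, 1e-6)))
})

test_that("incPCD agrees with nPCD in distribution when conditioning adds nothing", {
  ## M and Y independent of class: the conditional posterior equals the
  ## unconditional one up to sampling noise in the structural coefficients
  set.seed(50)
  sc <- get_scenario("good")
  n <- 2500
  d <- lcm_simulate(sc, n = n, seed = 77)
  U <- as.matrix(d[paste0("u", 1:5)])
  M <- rbinom(n, 1, 0.2); Y <- rbinom(n, 1, 0.35)  # no class effect
  f <- align_classes(lca(U, 4, n_restarts = 5, seed = 1), sc$item_profiles)
  fn <- lcmediate(U, M, Y, k = 4, method = "npcd", m = 15, lca_fit = f,
                  seed = 8)
  fi <- lcmediate(U, M, Y, k = 4, method = "incpcd", m = 15, lca_fit = f,
                  n_restarts = 3, ref_profiles = sc$item_profiles, seed = 8)
  dd <- abs(coef(fn) - coef(fi))
  tol <- 3 * sqrt(fn$effects$se^2 + fi$effects$se^2)
  expect_true(all(dd <= tol))
})

test_that("study runners expose print, summary, coef and confint", {
  sc <- get_scenario("good")
  d <- lcm_simulate(sc, n = 1000, seed = 3)
  U <- as.matrix(d[paste0("u", 1:5)])
  fit <- lcmediate(U, d$m, d$y, k = 4, method = "modal",
                   ref_profiles = sc$item_profiles, seed = 1)
  expect_output(print(fit), "method = modal")
  expect_output(print(summary(fit)), "relative entropy")
  expect_length(coef(fit), 9)
  ci <- confint(fit)
  expect_equal(dim(ci), c(9L, 2L))
  expect_true(all(ci[, 1] < ci[, 2]))
})
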