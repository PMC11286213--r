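test_that("perturbation draws match the requested covariance", {
  est <- c(0.5, -1)
  expect_identical(perturb_params(est, matrix(0, 2, 2)), est)
  S <- matrix(c(0.04, 0.01, 0.01, 0.09), 2)
  set.seed(9)
  draws <- t(replicate(10000, perturb_params(est, S)))
  expect_lt(max(abs(colMeans(draws) - est)), 0.01)
  expect_lt(max(abs(cov(draws) - S) / max(S)), 0.05)
})

test_that("the conditional posterior reduces to the unconditional one under null slopes", {
  sc <- get_scenario("medium")
  d <- lcm_simulate(sc, n = 800, seed = 4)
  U <- as.matrix(d[paste0("u", 1:5)])
  f <- align_classes(lca(U, 4, n_restarts = 5, seed = 1), sc$item_profiles)
  p0 <- posterior(f, U)
  alpha_null <- c(-1.2, 0, 0, 0)
  beta_null <- c(-0.4, 0.7, rep(0, 6))
  p1 <- upcd_posterior(f$gamma, f$tau, alpha_null, beta_null, U, d$m, d$y)
  expect_equal(unname(p1), unname(p0), tolerance = 1e-12)
})

test_that("the conditional posterior matches a hand-computed single-person product", {
  gamma <- log(0.3 / 0.7)
  tau <- qlogis(rbind(c(0.9, 0.8), c(0.2, 0.3)))
  alpha <- c(-1, 0.8)          # P(M|x): class1 expit(-0.2), class2 expit(-1)
  beta <- c(-0.5, 0.6, 0.9, -0.4)
  U <- rbind(c(1, 0)); M <- 1; Y <- 1
  pm <- plogis(c(-1 + 0.8, -1))
  py <- plogis(c(-0.5 + 0.6 + 0.9 - 0.4, -0.5 + 0.6))
  pu <- c(0.9 * 0.2, 0.2 * 0.7)
  num <- c(0.3, 0.7) * pu * pm * py
  pp <- upcd_posterior(gamma, tau, alpha, beta, U, M, Y)
  expect_equal(unname(pp[1, ]), num / sum(num), tolerance = 1e-12)
})

test_that("a larger class effect on the outcome pulls posterior mass toward that class", {
  sc <- get_scenario("poor")
  d <- lcm_simulate(sc, n = 500, seed = 6)
  U <- as.matrix(d[paste0("u", 1:5)])
  f <- align_classes(lca(U, 4, n_restarts = 5, seed = 1), sc$item_profiles)
  alpha <- c(-1.5, 0, 0, 0)
  beta_small <- c(-0.7, 0.4, 0.2, 0, 0, 0, 0, 0)
  beta_big <- c(-0.7, 0.4, 2.0, 0, 0, 0, 0, 0)
  sel <- d$y == 1
  p_small <- upcd_posterior(f$gamma, f$tau, alpha, beta_small, U, d$m, d$y)
  p_big <- upcd_posterior(f$gamma, f$tau, alpha, beta_big, U, d$m, d$y)
  expect_true(all(p_big[sel, 1] >= p_small[sel, 1] - 1e-12))
})

test_that("uPCD with frozen null slopes, no perturbation and thin 1 reproduces the nPCD draw", {
  sc <- get_scenario("medium")
  d <- lcm_simulate(sc, n = 1000, seed = 13)
  U <- as.matrix(d[paste0("u", 1:5)])
  f <- align_classes(lca(U, 4, n_restarts = 5, seed = 2), sc$item_profiles)
  f$param_cov <- param_covariance(f, U)
  ctrl <- upcd_control(burn_in = 0, thin = 1, m = 1, perturb = FALSE)
  up <- lcmediate:::run_upcd(f, U, d$m, d$y, NULL, 4, m = 1, control = ctrl,
                             seed = 99, firth = TRUE,
                             freeze_null_slopes = TRUE)
  np <- lcmediate:::pcd_pool(posterior(f, U), d$m, d$y, NULL, 4, m = 1,
                             seed = 99, firth = TRUE)
  expect_equal(up$effects$estimate, np$effects$estimate, tolerance = 1e-12)
})

test_that("uPCD is deterministic given the seed and stores exactly m spaced imputations", {
  sc <- get_scenario("good")
  d <- lcm_simulate(sc, n = 800, seed = 21)
  U <- as.matrix(d[paste0("u", 1:5)])
  f <- align_classes(lca(U, 4, n_restarts = 5, seed = 2), sc$item_profiles)
  f$param_cov <- param_covariance(f, U)
  ctrl <- upcd_control(burn_in = 10, thin = 3, m = 6)
  f1 <- lcmediate(U, d$m, d$y, k = 4, method = "upcd", lca_fit = f,
                  m = 6, upcd = ctrl, seed = 31)
  f2 <- lcmediate(U, d$m, d$y, k = 4, method = "upcd", lca_fit = f,
                  m = 6, upcd = ctrl, seed = 31)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$effects$se, f2$effects$se)
  expect_equal(f1$diagnostics$store_at, 10 + 3 * (1:6))
  expect_equal(f1$diagnostics$m, 6)
  expect_equal(attr(f1$effects, "m"), 6)
})

test_that("class sizes and cross-tab cell counts are conserved every iteration", {
  sc <- get_scenario("medium")
  d <- lcm_simulate(sc, n = 600, seed = 8)
  U <- as.matrix(d[paste0("u", 1:5)])
  f <- align_classes(lca(U, 4, n_restarts = 5, seed = 2), sc$item_profiles)
  f$param_cov <- param_covariance(f, U)
  fit <- lcmediate(U, d$m, d$y, k = 4, method = "upcd", lca_fit = f,
                   m = 5, upcd = upcd_control(burn_in = 8, thin = 2, m = 5),
                   seed = 7)
  tr <- fit$diagnostics$trace
  size_cols <- grep("^size", names(tr))
  cell_cols <- grep("^cell_", names(tr))
  ok <- !is.na(tr[[2]])
  expect_true(all(rowSums(tr[ok, size_cols]) == 600))
  expect_true(all(rowSums(tr[ok, cell_cols]) == 600))
})

test_that("with perfect separation and no perturbation the chain fixes W at the truth", {
  set.seed(3)
  n <- 900
  X <- sample(1:3, n, replace = TRUE, prob = c(0.3, 0.3, 0.4))
  ## deterministic indicators: each class has its own response pattern
  P <- rbind(c(1, 1, 0), c(0, 1, 1), c(0, 0, 0))
  U <- sapply(1:3, function(j) P[X, j])
  M <- rbinom(n, 1, plogis(-1 + 0.6 * (X == 1)))
  Y <- rbinom(n, 1, plogis(-0.4 + 0.5 * M + 0.5 * (X == 1)))
  f <- align_classes(suppressWarnings(lca(U, 3, n_restarts = 5, seed = 2)), P)
  f$param_cov <- param_covariance(f, U)
  f$param_cov$cov[] <- 0          # freeze the measurement parameters too
  ctrl <- upcd_control(burn_in = 5, thin = 2, m = 4, perturb = FALSE)
  fit <- lcmediate:::run_upcd(f, U, M, Y, NULL, 3, m = 4, control = ctrl,
                              seed = 5, firth = TRUE)
  oracle <- mediation_effects(structural_fit(X, M, Y, k = 3))
  expect_equal(fit$effects$estimate, oracle$estimate, tolerance = 1e-9)
  expect_equal(max(fit$effects$between_var), 0, tolerance = 1e-18)
})

test_that("perturbation inflates the pooled standard error", {
  sc <- get_scenario("poor")
  ratios <- numeric(8)
  for (r in seq_len(8)) {
    d <- lcm_simulate(sc, n = 700, seed = 100 + r)
    U <- as.matrix(d[paste0("u", 1:5)])
    f <- suppressWarnings(align_classes(lca(U, 4, n_restarts = 5, seed = 2),
                                        sc$item_profiles))
    f$param_cov <- param_covariance(f, U)
    ctrl_on <- upcd_control(burn_in = 15, thin = 3, m = 12, perturb = TRUE)
    ctrl_off <- upcd_control(burn_in = 15, thin = 3, m = 12, perturb = FALSE)
    on <- lcmediate(U, d$m, d$y, k = 4, method = "upcd", lca_fit = f,
                    m = 12, upcd = ctrl_on, seed = 40 + r)
    off <- lcmediate(U, d$m, d$y, k = 4, method = "upcd", lca_fit = f,
                     m = 12, upcd = ctrl_off, seed = 40 + r)
    ratios[r] <- mean(on$effects$se / off$effects$se)
  }
  expect_gt(mean(ratios), 1)
})

test_that("trace diagnostics implement the threshold-SE rule boundary exactly", {
  sc <- get_scenario("good")
  d <- lcm_simulate(sc, n = 800, seed = 55)
  U <- as.matrix(d[paste0("u", 1:5)])
  f <- align_classes(lca(U, 4, n_restarts = 5, seed = 2), sc$item_profiles)
  f$param_cov <- param_covariance(f, U)
  fit <- lcmediate(U, d$m, d$y, k = 4, method = "upcd", lca_fit = f,
                   m = 5, upcd = upcd_control(burn_in = 10, thin = 2, m = 5),
                   seed = 3)
  mts <- fit$diagnostics$max_tau_se
  ## cohort engineered so this dataset sits at exactly 2.0x the mean: kept
  at_boundary <- diagnose_trace(fit, cohort_max_tau_se = rep(mts / 2, 50))
  expect_false(at_boundary$threshold_se_excluded)
  ## just above 2x: excluded
  over <- diagnose_trace(fit, cohort_max_tau_se = rep(mts / 2.1, 50))
  expect_true(over$threshold_se_excluded)
  ## single-dataset mode: rule not evaluable, absolute SEs reported
  solo <- diagnose_trace(fit)
  expect_true(is.na(solo$threshold_se_excluded))
  expect_match(solo$threshold_se_rule, "not evaluable")
  expect_equal(solo$max_tau_se, mts)
})

test_that("a healthy long chain is judged stationary", {
  sc <- get_scenario("good")
  d <- lcm_simulate(sc, n = 2000, seed = 70)
  U <- as.matrix(d[paste0("u", 1:5)])
  f <- align_classes(lca(U, 4, n_restarts = 5, seed = 2), sc$item_profiles)
  f$param_cov <- param_covariance(f, U)
  fit <- lcmediate(U, d$m, d$y, k = 4, method = "upcd", lca_fit = f, m = 10,
                   upcd = upcd_control(burn_in = 100, thin = 20, m = 10),
                   seed = 17)
  dg <- diagnose_trace(fit, cohort_max_tau_se = rep(f$param_cov$max_tau_se, 20))
  expect_true(dg$stationary)
  expect_true(dg$pass)
  expect_equal(dg$iterations_with_empty_cells +
                 sum(rowSums(fit$diagnostics$trace[grep("^cell_",
                   names(fit$diagnostics$trace))] == 0) == 0,
                   na.rm = TRUE),
               sum(!is.na(fit$diagnostics$trace[[2]])))
})
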