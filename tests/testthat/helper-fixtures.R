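## Shared fixtures, built once per test run. Everything is generated in
## code; nothing is read from disk.

## A two-class, two-indicator generator used by several recovery tests.
make_two_class_data <- function(n, p1 = c(0.95, 0.95), p2 = c(0.05, 0.05),
                                pi1 = 0.5, seed = 1) {
  set.seed(seed)
  X <- 1L + (runif(n) > pi1)
  P <- rbind(p1, p2)
  U <- cbind(rbinom(n, 1, P[X, 1]), rbinom(n, 1, P[X, 2]))
  colnames(U) <- c("u1", "u2")
  list(U = U, X = X, item_probs = P)
}

## The simulation cross-tabulation expanded to weighted rows.
crosstab_rows <- function() {
  t1 <- population_crosstab()
  list(W = t1$class, M = t1$m, Y = t1$y, w = t1$n)
}

## Structural fit of the full population table (exact saturated fit).
crosstab_fit <- function() {
  r <- crosstab_rows()
  structural_fit(r$W, r$M, r$Y, k = 4, weights = r$w)
}

## Scenario objects are cheap to build (exact-enumeration calibration) but
## used in many files; cache them.
scenario_cache <- new.env(parent = emptyenv())
get_scenario <- function(entropy, n = 5000L) {
  key <- paste0(entropy, "_", n)
  if (is.null(scenario_cache[[key]]))
    scenario_cache[[key]] <- lcm_scenario(entropy, n = n)
  scenario_cache[[key]]
}
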