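# lcmediate

Counterfactual mediation analysis with a **latent class exposure**, for
epidemiologists and developmental researchers whose exposure is a set of
trajectory classes estimated from binary indicators rather than an
observed variable.

The package estimates natural mediation effects on the log risk-ratio
scale for each risk class *x* against a reference class *x\**, from two
logistic structural models (outcome model with class-by-mediator
interaction, mediator model) via the mediation formula

    E[Y(x, M(x*))] = sum_m P(Y = 1 | X = x, M = m) P(M = m | X = x*)

    TE   = log E[Y(x,M(x))]  - log E[Y(x*,M(x*))]
    TNIE = log E[Y(x,M(x))]  - log E[Y(x,M(x*))]
    PNDE = log E[Y(x,M(x*))] - log E[Y(x*,M(x*))]

with `TE = TNIE + PNDE` holding identically, and delta-method standard
errors. Because the exposure is latent, the estimate depends on how the
measurement model is linked to the structural models; `lcmediate()`
implements six linking methods:

| method    | idea                                                             |
|-----------|------------------------------------------------------------------|
| `onestep` | joint ML of measurement + structural models                      |
| `bch`     | bias-adjusted three-step with inverse classification-error weights |
| `modal`   | classify-analyze (no correction; biased at low entropy)          |
| `npcd`    | multiple imputation of class labels from the unconditional posterior |
| `incpcd`  | as `npcd`, posterior from a conditional model with M, Y as covariates |
| `upcd`    | **updated pseudo class draws**: iteratively re-derives P(X \| U, M, Y) from the unconditional fit plus current structural estimates, perturbing all parameters so classification uncertainty reaches the pooled SEs |

uPCD is the centrepiece: it avoids both the class-distortion risk of
one-step/incPCD and the bias of modal/nPCD, and its imputed class labels
can feed any downstream mediation machinery. The package also ships the
supporting stack: an EM fitter for binary-indicator latent class models
(`lca()`, `lca_conditional()`), an entropy-calibrated synthetic data
generator (`lcm_scenario()`, `lcm_simulate()`, `true_effects()`), and a
Monte Carlo performance harness (`lcm_study()`, `apply_exclusions()`,
`lcm_performance()`).

## Worked example

Simulate a medium-separation cohort (four trajectory classes at
8/10/12/70%, five binary indicators, binary mediator and outcome) and
estimate the mediation effects with uPCD:

```r
library(lcmediate)

sc  <- lcm_scenario("medium")            # relative entropy calibrated to 0.80
d   <- lcm_simulate(sc, n = 2000, seed = 42)
fit <- lcmediate(d[paste0("u", 1:5)], d$m, d$y, k = 4, method = "upcd",
                 m = 20, upcd = upcd_control(burn_in = 50, thin = 10, m = 20),
                 ref_profiles = sc$item_profiles, seed = 42)
fit
```

```
Latent class mediation fit: method = upcd, k = 4, n = 2000
Counterfactual mediation effects (log risk-ratio scale; reference = class 4 )
       comparison estimand estimate     se     rr  ci_low ci_high ...
 class1 vs class4       TE   0.1922 0.2344 1.2119 -0.2672  0.6516
 class1 vs class4     TNIE   0.1675 0.1705 1.1824 -0.1666  0.5017
 class1 vs class4     PNDE   0.0247 0.3501 1.0250 -0.6614  0.7108
 class2 vs class4       TE   0.2039 0.1131 1.2262 -0.0178  0.4255
 ...
```

Each row is one estimand for one risk class versus the reference (class 4
= "Low"): the log risk ratio, its Rubin-pooled standard error, the risk
ratio, and the Wald 95% interval; pooled rows also carry the within- and
between-imputation variances and the Monte Carlo error of the pooled
estimate. At n = 2,000 the intervals are wide but cover the generating
truths (`true_effects(sc)` prints TE = 0.3567/0.2513/0.1335, TNIE =
0.0570/0.0809/0.0116, PNDE = 0.2996/0.1704/0.1220). `diagnose_trace(fit)`
reports chain stationarity, empty-cell events and the threshold-SE
exclusion flag; `plot(fit)` draws the parameter traces.

A method comparison over replicate datasets:

```r
st   <- lcm_study(sc, n_sim = 100, methods = c("modal", "npcd"), seed = 1)
perf <- lcm_performance(apply_exclusions(st), true_effects(sc))
```

gives Morris-style bias / coverage / empirical-SE tables with Monte Carlo
standard errors.

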