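# cenplam

Semiparametric regression for **right-censored responses**: partially
linear additive models (PLAM) estimated by modified local linear regression
with backfitting. The package is aimed at biostatisticians and
epidemiologists modelling (possibly log-scale) survival-type outcomes where
some covariates act linearly and others through unknown smooth functions,
and where a fraction of the responses is censored from the right.

## The model and the three censorship solutions

For observed pairs `z_i = min(y_i, c_i)` and `delta_i = I(y_i <= c_i)`, the
model is

    E(z | x, t) = beta0 + x'beta + sum_j f_j(t_j),      j = 1..q,

with each `f_j` an unknown smooth mean-zero function estimated by a local
linear smoother, bandwidths chosen per component by generalized
cross-validation, and the whole fit obtained by a modified backfitting
algorithm (an equivalent non-iterative solver is included for small
problems). Because least squares on censored `z` is biased, three working
response constructions are provided:

| method | idea |
|---|---|
| `"st"` | synthetic data transformation `z_i^G = delta_i z_i / (1 - Ghat(z_i))`, with `Ghat` the Kaplan-Meier estimate of the censoring distribution |
| `"kmw"` | weighted least squares with Kaplan-Meier weights (the jumps of the lifetime product-limit estimate); the weights enter both the coefficient step and the component smoothers |
| `"knni"` | censored responses imputed by the mean of the k nearest uncensored responses, nearness measured on the most response-correlated parametric covariate, k chosen in 2:10 |

Estimator quality is summarised by the study's metrics: SMDE (mean squared
Euclidean coefficient error), relative efficiency (SMDE ratios),
per-function RMSE, and ARMSE. A simulation engine reproduces the evaluation
design (quartic + sine-bump components, `beta = (1, -0.5)`, error variance
0.5, designed censoring at a target level).

## Worked example

```r
library(cenplam)

d <- simulate_plam(n = 120, cl = 0.2, seed = 1)   # 20% censoring
fit <- plam(d, parametric = c("x1", "x2"), nonparametric = c("t1", "t2"),
            method = "kmw")
fit
#> <plam> KMW solution (backfitting), n = 120
#>   beta0: 0.06068
#>   beta:  x1 = 0.9884, x2 = -0.5472
#>   bandwidths: t1: 0.06087, t2: 0.2441
#>   sigma^2 = 1.56 on 103.79 residual df
#>   3 backfitting sweep(s), converged: TRUE

tidy(fit)
#> # A tibble: 3 x 2
#>   term        estimate
#> 1 (Intercept)   0.0607
#> 2 x1            0.988
#> 3 x2           -0.547
```

The true coefficients behind this draw are `(1, -0.5)`: the Kaplan-Meier
weighted fit recovers them to about one standard error despite one fifth of
the responses being censored. The two bandwidths are on the scale of each
covariate (the wiggly quartic on `t1` gets a much smaller bandwidth than
the smoother sine-bump on `t2`). `sigma^2` is the residual variance of the
working response over the residual degrees of freedom; `augment(fit)`,
`glance(fit)` and `autoplot(fit)` expose per-row results, the one-row
summary, and the fitted component curves.

Monte-Carlo scenario runs use the same surface:

```r
sc <- run_scenario(n = 50, cl = 0.35, reps = 100,
                   methods = c("st", "kmw"), seed = 42)
sc$smde          # named SMDE per method
sc$re            # relative-efficiency matrix (column method in numerator)
tidy(sc)         # tidy metric table
```

A small command-line shim (`inst/cli/cenplam`) exposes `transform`, `fit`,
`simulate` and `evaluate` subcommands over the same functions; see
`cenplam --help`.

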