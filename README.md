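# pfcrsvr — robust hybrid support vector regression

Coefficient estimation for linear models whose data are simultaneously
**ill-conditioned** (near-collinear predictors) and **contaminated**
(vertical outliers in the response). Both failure modes are endemic in
epidemiological and biostatistical tabular data — mortality vs. correlated
environmental exposures, macro-economic predictors, clinical panels — and
each alone is enough to destabilize least squares or classical
$\varepsilon$-SVR.

The package implements six estimators behind one fitting interface:

| method | dimension reduction | regression loss |
|---|---|---|
| `svr` | — | $\varepsilon$-insensitive (e1071 baseline) |
| `eqsvr` | — | bounded exponential quantile |
| `pcsvr` / `pfcsvr` | principal components / principal fitted components | $\varepsilon$-insensitive |
| `pcrsvr` / `pfcrsvr` | principal components / principal fitted components | bounded exponential quantile |

The core is **EQSVR**: linear SVR under the bounded loss
$L_{eq}(u) = \eta\,(\sigma(\lambda\,l_\text{pin}(u)) - \phi)$, where
$l_\text{pin}(u) = \max(u, -\tau u)$ is the pinball loss, $\sigma$ the
logistic sigmoid, $\phi = 1/2$, $\eta = 2$. The loss is zero at zero
residual, increases with $|u|$, and saturates at 1, so a gross outlier has
bounded influence. The penalized objective
$\tfrac12\lVert(w,b)\rVert^2 + C\sum_i L_{eq}(y_i - w^\top x_i - b)$
is non-convex; it is minimized by the concave-convex procedure (CCCP),
each convex subproblem solved in its dual by clipped dual coordinate
descent (ClipDCD, compiled inner loop). The hybrids reduce standardized
predictors to the components covering 80% of variance — PFC components are
extracted from an inverse regression of predictors on $(y, y^2)$, so they
target response-informative directions — then run the regression on the
scores and map coefficients back.

Also included: the full Monte Carlo benchmark engine (collinear generator,
eigenvector-defined true coefficients, vertical contamination
$y^* = 10\,\max(y) + y$, MSE/MAE/PMSE summaries), a bootstrap stability
evaluator (MSEBE) for real CSV data, and a command-line front end.

## Worked example

```r
library(pfcrsvr)
set.seed(7)
x    <- generate_predictors(100, 5, 0.9)        # pairwise correlation 0.81
z    <- standardize_predictors(x)$z
beta <- true_beta(z)                            # unit-norm signal direction
y    <- generate_response(z, beta)
yc   <- contaminate_response(y, 0.15, b = 10)$y # 15% vertical outliers
fit  <- rsvr(z, yc, method = "pfcrsvr", standardize = FALSE)
fit
#> Robust hybrid SVR fit: method = PFCRSVR
#>   PFC basis, q = 1 components retained
#>   Coefficients (standardized-predictor scale):
#> (Intercept)
#>   0.0415544   0.4325103   0.4729025   0.4175693   0.4171666   0.4659253
```

One principal fitted component already carries 80% of the fitted variance,
and the recovered slopes sit near the true direction
(`beta` is approximately `(0.45, 0.45, ...)`). Despite 15% of the
responses being shifted by ten times the maximum of `y`:

```r
for (m in c("svr", "eqsvr", "pfcrsvr"))
  cat(sprintf("  %-8s %.5f\n", m,
      mse_beta(rsvr(z, yc, method = m, standardize = FALSE)$beta, beta)))
#>   svr      0.08824
#>   eqsvr    0.01123
#>   pfcrsvr  0.00048
```

The bounded loss cuts the coefficient MSE by an order of magnitude, and the
PFC reduction by another. `summary()`, `coef()` (standardized or original
scale), `predict()`, and `residuals()` behave as for any fitted model;
`rsvr(y ~ ., data = df, method = "pfcrsvr")` is the formula interface.

For a benchmark table:

```r
tab <- run_monte_carlo(sim_config(n = c(50, 300), p = 5, rho = 0.8, seed = 1))
format_metrics_table(tab, "mse")   # estimator x n rows vs contamination columns
```

For real data (CSV with a header):

```r
rep <- bootstrap_msebe(x, y, method = "pfcrsvr", B = 500)  # stability: mean
rep$msebe                                                  # bootstrap SD of coefs
```

or from a shell: `inst/cli/rsvr fit|bootstrap|simulate|bench --help`.

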