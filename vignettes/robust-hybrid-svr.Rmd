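---
title: "Robust hybrid support vector regression with principal and principal fitted components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust hybrid support vector regression with principal and principal fitted components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfcrsvr)
```

## The problem

Coefficient estimation in linear regression breaks down in two common ways at
once: near-linear dependence among predictors (multicollinearity) makes the
normal equations ill-conditioned, and vertical outliers — grossly shifted
responses — drag any estimator built on an unbounded loss arbitrarily far
from the truth. This package implements a family of estimators that attack
both problems simultaneously: a linear support vector regression with a
*bounded* exponential quantile loss (EQSVR), and hybrids that first reduce
the predictors to a few well-conditioned components — principal components
(PC) or principal fitted components (PFC) — and then run EQSVR on the
component scores (PCRSVR, PFCRSVR). The classical $\varepsilon$-SVR and its
component hybrids (PCSVR, PFCSVR) are included as baselines.

## The bounded loss and its optimization

For a residual $u = y - (w^\top x + b)$ the pinball loss is
$l_\text{pin}(u) = \max(u, -\tau u)$ with hedging factor $\tau \ge 0$:
positive residuals cost their full size, negative residuals are scaled by
$\tau$. EQSVR rescales the pinball loss through a logistic sigmoid,

$$L_{eq}(u) \;=\; \eta\left(\frac{1}{1 + e^{-\lambda\, l_\text{pin}(u)}} - \phi\right),
\qquad \phi = \tfrac12,\; \eta = 2,$$

so that $L_{eq}(0) = 0$, $L_{eq}$ increases with the pinball loss, and
$L_{eq} \to 1$ as the residual grows: one outlier can contribute at most 1
to the objective, which is what bounds its influence. The constants $\phi$
(location) and $\eta$ (normalization) are fixed by those two anchoring
conditions; with the sigmoid centered at the origin they equal $1/2$ and $2$
for every $\tau$. Centering the sigmoid is essential: any positive shift of
its argument creates a flat region around zero residual in which the loss
gradient vanishes and the penalized objective is minimized by shrinking all
coefficients to zero — the estimator would stop estimating.

With the intercept absorbed into augmented weights
$\check w = (w, b)$ and $\check x = (x, 1)$, the fit solves

$$\min_{\check w}\; \tfrac12 \lVert \check w \rVert^2 +
  C \sum_{i=1}^n L_{eq}\!\left(y_i - \check w^\top \check x_i\right).$$

Because the bias is penalized, fits are deliberately not
translation-equivariant in $y$. The loss is non-convex, so the objective is
minimized by the concave-convex procedure (CCCP): $L_{eq}$ is split as
$g + h$ with the convex quadratic surrogate
$g(u) = \lambda^2 l_\text{pin}^2(u)/5 + \lambda\, l_\text{pin}(u)/2$
(whose curvature dominates the sigmoid's, making $h = L_{eq} - g$ concave on
each residual sign branch), and each outer iteration linearizes $h$ at the
current residuals through the slope $\delta(u) = g'(u) - L_{eq}'(u)$ and
solves the resulting convex subproblem. CCCP guarantees a non-increasing
objective; the fitted object records the trace.

Each convex subproblem is solved in its dual, a quadratic program over
$2n$ stacked multipliers bounded below,
$\min_u \tfrac12 u^\top Q u - l^\top u$, $u \ge l_b$, with
$Q = K_r + \tfrac{5}{2C} R$ built from the Gram matrix of the augmented
design. The solver is clipped dual coordinate descent (ClipDCD): each inner
step picks the coordinate whose exact clipped line-search update decreases
the objective most (lowest index on ties) and applies
$u_k \leftarrow \max(l_{b,k},\, u_k - g_k / Q_{kk})$. The primal weights are
recovered from stationarity,
$\check w = \check X^\top(\lambda\gamma - \tau\lambda\theta - C\delta)$.
The inner loop is implemented in compiled code and exploits the block
structure of $Q$ (a scaled Gram column plus two sparse entries), so a fit at
$n = 300$ takes well under a second.

Numerical choices: CCCP starts at $\check w = 0$ and stops when the weight
change drops below $10^{-4}$ (at most 50 outer iterations); ClipDCD stops at
a projected-gradient norm of $10^{-5}$ (at most 5000 inner iterations) and
is warm-started across outer iterations; $\delta$ at a zero residual uses
the right-hand limit (a measure-zero tie that cannot affect convergence).
All tolerances are arguments, and properties that compare two
mathematically identical fits (e.g. full-retention rotation invariance) are
checked at much tighter settings so solver error sits well below the
comparison threshold.

## Dimension reduction: PC and PFC

Predictors are standardized to zero mean and unit sample variance
(denominator $n-1$). The PC basis is the eigen-decomposition of $Z^\top Z$;
the PFC basis replaces $Z$ by its fitted values from an inverse regression
of the predictors on a centered polynomial basis of the response,
$F = (y - \bar y,\, y^2 - \overline{y^2})$ by default (degree $r = 2$,
isotropic error structure): $\hat Z = F(F^\top F)^{-1}F^\top Z$ and
$\hat\Sigma_\text{fit} = \hat Z^\top \hat Z / n$. Because $\hat Z$ lives in
the $r$-dimensional span of $F$, at most $r$ eigenvalues are nonzero, and
the leading eigenvectors point along the predictor directions most
informative about the response — the reason PFC regression can beat PC
regression when the response loads on low-variance directions. Component
scores always use the original standardized $Z$, not $\hat Z$.

The retained count $q$ is the smallest number of components whose
cumulative eigenvalue share reaches 80% (of the basis's own spectrum); a
degenerate $q = 0$ is promoted to 1 so the model always has a regressor.
Eigenvector signs are fixed by making each loading's largest-magnitude entry
positive, which removes the sign ambiguity that would otherwise corrupt
coefficient-error metrics against a fixed truth. Coefficients estimated in
component space are mapped back as $\hat\beta = V_q \hat\alpha_q$ and
reported on the standardized-predictor scale (`coef(fit, "original")`
de-standardizes).

## The simulation engine

`run_monte_carlo()` reproduces the benchmark design the estimators were
evaluated on:

* predictors $x_{ij} = \sqrt{1-\rho^2}\, D_{ij} + \rho\, D_{i,p+1}$ from
  i.i.d. standard normals, giving unit variances and pairwise correlation
  $\rho^2$ through a common factor;
* true coefficients $\beta$ = the unit-norm top eigenvector of $X^\top X$
  of that replicate's standardized predictors (recomputed each replicate),
  sign-fixed;
* response $y = X\beta + e$, $e \sim N(0,1)$;
* vertical outliers: a fraction of responses, drawn without replacement
  (count = `round(fraction * n)`), shifted by $b \cdot \max(y)$ with
  $b = 10$ and $\max(y)$ taken before contamination.

Per replicate, all requested estimators see the identical contaminated
data (paired comparison); a master seed spawns per-replicate seeds, so any
table is exactly reproducible. Reported metrics are the mean and standard
deviation across replications of
$\mathrm{MSE}(\hat\beta) = \tfrac1p\sum_l(\hat\beta_l-\beta_l)^2$ and
$\mathrm{MAE}(\hat\beta) = \tfrac1p\sum_l|\hat\beta_l-\beta_l|$, and the
percentage MSE reduction
$\mathrm{PMSE} = 100\,(\mathrm{MSE}^{**}-\mathrm{MSE}^{*})/\mathrm{MSE}^{**}$
of a proposed estimator over a competitor.

Hyperparameter defaults follow the study conditions: $\lambda = 0.5$,
$\tau = 0.7$, $C = 0.2$ ($C = 0.04$ once $p \ge 25$, where the weaker
penalty compensates the larger coefficient vector), $\varepsilon$-SVR at
cost 1 and $\varepsilon = 0.1$ on the already-standardized design (no
internal rescaling of the response — rescaling $y$ by its contaminated
standard deviation would inflate the insensitivity tube by the outlier
magnitude and is demonstrably not how the baseline behaves), components at
the 80% rule, 100 replications.

What the generator emulates — and what it does not: it produces equicorrelated
Gaussian predictors with a single common factor, Gaussian noise, and
response-only (vertical) outliers that are all shifted upward by the same
amount. Real data bring leverage points in predictor space, asymmetric or
heavy-tailed noise, heteroscedasticity, and predictors with unequal
correlation structure; passing these tests therefore demonstrates correct
behaviour under the stated conditions, not robustness to every
contamination mechanism. Leverage-point contamination and non-Gaussian
responses are explicitly out of scope.

```{r example}
cfg <- sim_config(n = 50, p = 5, rho = 0.8, contamination = c(0, 0.3),
                  reps = 10, estimators = c("svr", "eqsvr", "pfcrsvr"),
                  seed = 42)
tab <- run_monte_carlo(cfg)
format_metrics_table(tab, "mse")
```

(The problem sizes used in the package's own checks are the study's printed
sizes — $n \in \{50, 100, 300\}$, $p \in \{5, 15, 25\}$, 100 replications —
which complete in a few minutes thanks to the compiled inner solver; the
chunk above is kept small only to render quickly.)

## Real-data evaluation

For datasets without a known $\beta$, `bootstrap_msebe()` compares
estimators by coefficient stability: $B$ case resamples, a refit per
resample, and the mean over coefficients of the bootstrap standard
deviations (MSEBE). $B$ defaults to 500 — large enough that the SD of a
coefficient across resamples is itself stable — and failed refits are
redrawn up to 3 times before being counted out. Coefficients are reported on
the standardized scale, where magnitudes are comparable across estimators.

## Design choices that were genuinely open

* **Sigmoid centering.** The loss's derived constants are printed elsewhere
  with a $\tau$-dependent shift; as discussed above, a shifted sigmoid
  makes the estimator degenerate at the stated hyperparameters, and the CCCP
  slope formula the algorithm actually prescribes is the derivative of the
  centered loss. The centered form is implemented.
* **Negative-branch slope.** The CCCP slope for negative residuals is
  derived symbolically from the centered loss (so the loss saturates on both
  sides and the decomposition identity $\delta = -h'$ holds exactly); the
  alternative sign convention, which makes the negative branch grow without
  bound like a pinball loss, changes benchmark cells by only a few percent.
* **Dual assembly.** The linear term and the $5/(2C)$ coupling of the dual
  are re-derived from the Lagrangian rather than transcribed; the tests
  verify the resulting QP against an independent projected quasi-Newton
  solver and the recovered primal against derivative-free minimization.
* **$q$ for PFC.** The 80% rule is applied to the PFC spectrum itself
  (which has at most $r$ nonzero eigenvalues), not to the total predictor
  variance; with $r=2$ this selects one or two components.
* **Baseline SVR scaling.** See above; `svm()`'s internal scaling is
  disabled in favour of the package's own standardization.
* **Bootstrap size.** $B = 500$ by default, flag-overridable from the CLI.

## Known limitations

The objective is non-convex: CCCP converges monotonically but only to a
stationary point, and the reported fit depends on the fixed zero
initialization (deliberate, for determinism). The EQSVR family is linear —
no kernels. PFC assumes an isotropic inverse-regression error and a
polynomial response basis. At contamination approaching 50% the vertical
outliers form their own half of the data and no estimator here is designed
to survive that. The $\varepsilon$-SVR-on-components baselines turn out to
be considerably more outlier-resistant in this implementation than the
published benchmark tables suggest, so comparisons *between the non-robust
baselines and the robust hybrids* are closer here than in those tables; the
robust estimators themselves reproduce or beat every published cell we
check.
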