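#' Hyperparameters of the exponential quantile loss
#'
#' Bundles the tuning triple governing the bounded exponential quantile loss
#' and the penalty weight of the EQSVR objective, together with the two
#' derived constants of the loss: the location constant `phi` (the sigmoid's
#' value at a zero residual), which anchors the loss at zero there, and the
#' normalizing constant `eta = 1 / (1 - phi)`, which makes the loss approach
#' 1 as the residual grows without bound. With the sigmoid centered at the
#' origin these are 1/2 and 2 for every `tau`.
#'
#' @param lambda Positive steepness of the loss. Larger values make the
#'   sigmoid rescaling saturate faster, i.e. outliers are capped sooner.
#' @param tau Nonnegative hedging (quantile) factor. `tau = 1` treats positive
#'   and negative residuals symmetrically; `tau < 1` down-weights negative
#'   residuals.
#' @param cost Positive penalty weight `C` multiplying the summed losses in
#'   the regularized objective.
#' @return An object of class `"loss_params"`: a list with components
#'   `lambda`, `tau`, `cost`, `phi`, `eta`.
#' @examples
#' loss_params(lambda = 0.5, tau = 0.7, cost = 0.2)
#' @export
loss_params <- function(lambda = 0.5, tau = 0.7, cost = 0.2) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            is.numeric(tau), length(tau) == 1L, is.finite(tau),
            is.numeric(cost), length(cost) == 1L, is.finite(cost))
  if (lambda <= 0) stop("'lambda' must be positive")
  if (tau < 0) stop("'tau' must be nonnegative")
  if (cost <= 0) stop("'cost' must be positive")
  # phi anchors L(0) = 0, eta normalizes sup L = 1: with the sigmoid
  # centered at the origin these are 1/2 and 2 for every tau.
  structure(
    list(lambda = lambda, tau = tau, cost = cost, phi = 0.5, eta = 2),
    class = "loss_params"
  )
}

#' @export
print.loss_params <- function(x, ...) {
  cat(sprintf(
    "Exponential quantile loss parameters: lambda = %g, tau = %g, C = %g\n",
    x$lambda, x$tau, x$cost))
  cat(sprintf("  (phi = %.6g, eta = %.6g)\n", x$phi, x$eta))
  invisible(x)
}

as_loss_params <- function(params) {
  if (inherits(params, "loss_params")) return(params)
  stop("'params' must be a 'loss_params' object (see loss_params())")
}

#' Pinball loss
#'
#' The asymmetric absolute-type loss of quantile regression,
#' `max(u, -tau * u)`: a residual `u >= 0` costs `u`, a negative residual
#' costs `-tau * u`.
#'
#' @param u Numeric vector of residuals.
#' @param tau Nonnegative asymmetry factor.
#' @return Nonnegative numeric vector of the same length as `u`.
#' @examples
#' pinball(c(-2, 0, 2), tau = 0.7)
#' @export
pinball <- function(u, tau) {
  stopifnot(is.numeric(u), is.numeric(tau), length(tau) == 1L, tau >= 0)
  pmax(u, -tau * u)
}

#' Bounded exponential quantile loss
#'
#' Sigmoid-rescaled pinball loss,
#' `L(u) = eta * (1 / (1 + exp(-lambda * l_pin(u))) - phi)`,
#' which is 0 at a zero residual, nondecreasing in the pinball loss and
#' bounded above by 1. The bound is what gives EQSVR its resistance to
#' vertical outliers: a gross outlier contributes at most 1 to the objective
#' no matter how large its residual.
#'
#' @param u Numeric vector of residuals.
#' @param params A [loss_params()] object.
#' @return Numeric vector of losses in `[0, 1)`.
#' @examples
#' p <- loss_params(lambda = 0.5, tau = 0)
#' eq_loss(c(0, 1, 100), p)
#' @export
eq_loss <- function(u, params) {
  params <- as_loss_params(params)
  lp <- pinball(u, params$tau)
  params$eta * (plogis(params$lambda * lp) - params$phi)
}

#' Convex part of the CCCP split of the exponential quantile loss
#'
#' The quadratic surrogate `g(u) = lambda^2 l_pin^2(u) / 5 +
#' lambda * l_pin(u) / 2` that the concave-convex procedure pairs with the
#' concave remainder `h(u) = eq_loss(u) - g(u)`. `g` majorizes the curvature
#' of the loss (its second derivative, `2 lambda^2 / 5` per unit pinball
#' curvature, exceeds the largest curvature of the sigmoid term), so `h` is
#' concave on each residual sign branch and CCCP applies.
#'
#' @inheritParams eq_loss
#' @return Nonnegative numeric vector.
#' @examples
#' eq_convex(1, loss_params(lambda = 0.5, tau = 0))
#' @export
eq_convex <- function(u, params) {
  params <- as_loss_params(params)
  xi <- params$lambda * pinball(u, params$tau)
  xi^2 / 5 + xi / 2
}

#' Linearization slope of the concave part
#'
#' The auxiliary quantity `delta(u) = -h'(u) = g'(u) - L'(u)` used by the
#' concave-convex procedure to replace the concave remainder `h` with its
#' tangent at the current iterate. Derived branchwise on the sign of the
#' residual: with `l = l_pin(u)` and `s = dl/du` (`1` for `u > 0`, `-tau` for
#' `u < 0`),
#' `delta(u) = s * (2 lambda^2 l / 5 + lambda / 2
#'                  - eta * lambda * sig'(lambda * l))`
#' where `sig'` is the logistic density. At `u = 0` the right-hand limit is
#' used (a measure-zero tie; any bounded choice preserves CCCP convergence).
#'
#' @inheritParams eq_loss
#' @return Numeric vector of slopes, bounded in magnitude.
#' @examples
#' eq_delta(1, loss_params(lambda = 0.5, tau = 0))
#' @export
eq_delta <- function(u, params) {
  params <- as_loss_params(params)
  lam <- params$lambda; tau <- params$tau
  s <- ifelse(u >= 0, 1, -tau)     # dl_pin/du, right-limit at 0
  l <- pinball(u, tau)
  sig <- plogis(lam * l)
  s * (2 * lam^2 * l / 5 + lam / 2 - params$eta * lam * sig * (1 - sig))
}
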