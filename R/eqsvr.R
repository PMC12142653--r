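#' Augment a design matrix with an intercept column
#'
#' Appends a column of ones so that the augmented weight vector
#' `(w, b)` carries the bias as its last coordinate and the bias is penalized
#' together with the slopes (`||w||^2 + b^2` in the objective). Fits are
#' therefore not translation-equivariant in `y`.
#'
#' @param x Numeric matrix of predictors, `n x p`.
#' @param y Numeric response vector of length `n`.
#' @return A list with components `x` (the `n x (p+1)` augmented matrix) and
#'   `y`, of class `"augmented_design"`.
#' @export
augment_design <- function(x, y) {
  x <- as.matrix(x)
  if (nrow(x) == 0L || ncol(x) == 0L) stop("'x' must be a non-empty matrix")
  if (!is.numeric(x) || !all(is.finite(x))) stop("'x' must be finite numeric")
  if (!is.numeric(y) || !all(is.finite(y))) stop("'y' must be finite numeric")
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  if (nrow(x) < 2L) stop("need at least 2 observations")
  structure(list(x = cbind(x, 1, deparse.level = 0L), y = as.numeric(y)),
            class = "augmented_design")
}

#' Assemble the dual quadratic program of one CCCP subproblem
#'
#' Each CCCP iteration of EQSVR linearizes the concave part of the loss at
#' the current slopes `delta` and solves a convex subproblem whose dual is a
#' quadratic program bounded below,
#' `min_u 0.5 u'Qu - l'u, u >= lb`, over the stacked transformed multipliers
#' `u = (gamma - C delta / lambda, theta)` of length `2n`. With
#' `K = Xa Xa'` the Gram matrix of the augmented design,
#' `Q = Kr + (5 / (2C)) R` where `Kr` is the 2x2 block matrix of
#' `lambda^2 K`, `-tau lambda^2 K`, `tau^2 lambda^2 K` and `R` the all-ones
#' 2x2 block of identities;
#' `l = (lambda y + (5/4) e - (5/2) delta / lambda,
#'       -tau lambda y + (5/4) e - (5/2) delta / lambda)`; and
#' `lb = (-C delta / lambda, 0)`.
#'
#' @param ad An [augment_design()] object.
#' @param delta Numeric vector of length `n`: current concave-part slopes.
#' @param params A [loss_params()] object.
#' @param K Optional precomputed Gram matrix `Xa %*% t(Xa)` (reused across
#'   CCCP iterations; only `l` and `lb` depend on `delta`).
#' @return List with components `Q`, `l`, `lb`.
#' @export
eqsvr_dual <- function(ad, delta, params, K = NULL) {
  stopifnot(inherits(ad, "augmented_design"))
  params <- as_loss_params(params)
  n <- length(ad$y)
  if (length(delta) != n) stop("'delta' must have one slope per observation")
  lam <- params$lambda; tau <- params$tau; C <- params$cost
  if (is.null(K)) K <- tcrossprod(ad$x)
  # R = [[I, I], [I, I]] couples the two dual blocks
  In <- diag(n)
  R <- rbind(cbind(In, In), cbind(In, In))
  Q <- rbind(cbind(lam^2 * K, -tau * lam^2 * K),
             cbind(-tau * lam^2 * K, tau^2 * lam^2 * K)) + (5 / (2 * C)) * R
  common <- 5 / 4 - (5 / 2) * delta / lam
  l <- c(lam * ad$y + common, -tau * lam * ad$y + common)
  lb <- c(-C * delta / lam, rep(0, n))
  list(Q = Q, l = l, lb = lb)
}

#' Clipped dual coordinate descent for a bounded-below quadratic program
#'
#' Solves `min_u 0.5 u'Qu - l'u` subject to `u >= lb` by greedy coordinate
#' descent with clipping at the bound: each step picks the coordinate whose
#' exact clipped line-search update decreases the objective most (lowest
#' index on ties) and applies `u_k <- max(lb_k, u_k - g_k / Q_kk)`.
#'
#' @param Q Symmetric matrix with strictly positive diagonal (positive
#'   semidefinite plus a strictly positive diagonal contribution in the
#'   EQSVR dual).
#' @param l Linear term vector.
#' @param lb Lower-bound vector.
#' @param u0 Optional start (clipped to the feasible set); defaults to `lb`.
#' @param tol Convergence threshold on the largest projected-gradient
#'   magnitude.
#' @param max_iter Inner iteration cap; if reached, the best iterate is
#'   returned with `converged = FALSE` and a warning.
#' @return List with `u` (the minimizer), `objective`, `iterations`,
#'   `converged`.
#' @export
clipdcd <- function(Q, l, lb, u0 = NULL, tol = 1e-5, max_iter = 5000L) {
  Q <- as.matrix(Q)
  m <- nrow(Q)
  if (ncol(Q) != m || length(l) != m || length(lb) != m)
    stop("nonconforming dual problem")
  if (!all(is.finite(lb))) stop("'lb' must be finite")
  if (any(diag(Q) <= 0)) stop("ClipDCD requires strictly positive diagonal entries")
  if (is.null(u0)) u0 <- lb
  res <- .clipdcd_cpp(Q, as.numeric(l), as.numeric(lb), as.numeric(u0),
                      tol, as.integer(max_iter))
  if (!res$converged)
    warning(sprintf("ClipDCD stopped at max_iter = %d without meeting tol = %g",
                    max_iter, tol))
  res
}

#' Recover the augmented primal weights from the dual state
#'
#' Stationarity of the subproblem Lagrangian in the augmented weights gives
#' `wa = Xa' (lambda * gamma - tau * lambda * theta - C * delta)`.
#'
#' @param ad An [augment_design()] object.
#' @param gamma,theta Nonnegative dual vectors of length `n`.
#' @param delta Concave-part slope vector of length `n`.
#' @param params A [loss_params()] object.
#' @return Numeric vector of length `p + 1`: slopes then bias.
#' @export
recover_weights <- function(ad, gamma, theta, delta, params) {
  stopifnot(inherits(ad, "augmented_design"))
  params <- as_loss_params(params)
  n <- length(ad$y)
  if (length(gamma) != n || length(theta) != n || length(delta) != n)
    stop("dual vectors must have length n")
  drop(crossprod(ad$x, params$lambda * gamma - params$tau * params$lambda * theta -
                   params$cost * delta))
}

eqsvr_objective <- function(ad, wa, params) {
  r <- ad$y - drop(ad$x %*% wa)
  0.5 * sum(wa^2) + params$cost * sum(eq_loss(r, params))
}

#' Fit linear EQSVR by CCCP with a ClipDCD inner solver
#'
#' Minimizes `0.5 ||wa||^2 + C * sum(L_eq(y_i - wa' xa_i))` over the
#' augmented weights `wa = (w, b)`, where `L_eq` is the bounded exponential
#' quantile loss. The concave-convex procedure alternates (i) updating the
#' concave-part slopes `delta` at the current residuals, (ii) solving the
#' resulting convex subproblem in its dual form with [clipdcd()] (warm
#' started from the previous iterate), and (iii) recovering the primal
#' weights, until the weight change falls below `tol`. The objective trace is
#' non-increasing (CCCP majorization).
#'
#' @param x Numeric predictor matrix `n x p` (standardize beforehand if
#'   desired; [rsvr()] does this for you).
#' @param y Numeric response vector.
#' @param params A [loss_params()] object; defaults to
#'   `loss_params(0.5, 0.7, 0.2)`.
#' @param tol Outer convergence threshold on `||wa_new - wa_old||`.
#' @param max_outer Maximum CCCP iterations.
#' @param inner_tol,inner_max_iter Passed to [clipdcd()].
#' @return An object of class `"eqsvr"`: list with `w` (slopes), `b` (bias),
#'   `params`, `n_cccp_iters`, `objective_trace`, `converged`, `dual`
#'   (final `gamma`, `theta`, `delta`), `fitted`, `residuals`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), 30, 2)
#' y <- x %*% c(1, -1) + rnorm(30, sd = 0.1)
#' fit <- eqsvr(x, y, loss_params(0.5, 0.7, 1))
#' coef(fit)
#' @export
eqsvr <- function(x, y, params = loss_params(), tol = 1e-4, max_outer = 50L,
                  inner_tol = 1e-5, inner_max_iter = 5000L) {
  params <- as_loss_params(params)
  ad <- augment_design(x, y)
  n <- length(ad$y)
  p1 <- ncol(ad$x)
  lam <- params$lambda; tau <- params$tau; C <- params$cost

  K <- tcrossprod(ad$x)
  wa <- numeric(p1)                       # CCCP start: zero weights
  u <- NULL
  trace <- eqsvr_objective(ad, wa, params)
  converged <- FALSE
  inner_iters <- integer(0)
  gamma <- theta <- delta <- numeric(n)

  for (k in seq_len(max_outer)) {
    resid <- ad$y - drop(ad$x %*% wa)
    delta <- eq_delta(resid, params)
    common <- 5 / 4 - (5 / 2) * delta / lam
    l <- c(lam * ad$y + common, -tau * lam * ad$y + common)
    lb <- c(-C * delta / lam, rep(0, n))
    u0 <- if (is.null(u)) lb else pmax(u, lb)
    sol <- .clipdcd_eqsvr_cpp(K, lam, tau, C, l, lb, u0, inner_tol,
                              as.integer(inner_max_iter))
    u <- sol$u
    inner_iters <- c(inner_iters, sol$iterations)
    gamma <- u[seq_len(n)] + C * delta / lam
    theta <- u[n + seq_len(n)]
    wa_new <- recover_weights(ad, gamma, theta, delta, params)
    trace <- c(trace, eqsvr_objective(ad, wa_new, params))
    step <- sqrt(sum((wa_new - wa)^2))
    wa <- wa_new
    if (step <= tol) { converged <- TRUE; break }
  }

  fitted <- drop(ad$x %*% wa)
  structure(
    list(w = wa[-p1], b = wa[p1], params = params,
         n_cccp_iters = length(inner_iters), inner_iterations = inner_iters,
         objective_trace = trace, converged = converged,
         dual = list(gamma = gamma, theta = theta, delta = delta, u = u),
         fitted = fitted, residuals = ad$y - fitted, y = ad$y),
    class = "eqsvr"
  )
}

#' @export
print.eqsvr <- function(x, ...) {
  cat("Linear EQSVR fit (bounded exponential quantile loss, CCCP + ClipDCD)\n")
  cat(sprintf("  lambda = %g, tau = %g, C = %g\n",
              x$params$lambda, x$params$tau, x$params$cost))
  cat(sprintf("  %d CCCP iterations (%s), final objective %.6g\n",
              x$n_cccp_iters, if (x$converged) "converged" else "not converged",
              tail(x$objective_trace, 1L)))
  cat("  Coefficients:\n")
  print(c(x$w, bias = x$b))
  invisible(x)
}

#' @export
coef.eqsvr <- function(object, ...) c(object$w, bias = object$b)

#' @export
residuals.eqsvr <- function(object, ...) object$residuals

#' @export
fitted.eqsvr <- function(object, ...) object$fitted

#' Predict from an EQSVR fit
#'
#' @param object An `"eqsvr"` fit.
#' @param newdata Numeric matrix with the same columns (and preprocessing)
#'   as the training predictors.
#' @param ... Unused.
#' @return Numeric vector `newdata %*% w + b`.
#' @export
predict.eqsvr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$w))
    stop(sprintf("'newdata' has %d columns; fit used %d predictors",
                 ncol(newdata), length(object$w)))
  drop(newdata %*% object$w) + object$b
}
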