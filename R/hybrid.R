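#' Robust hybrid support vector regression estimators
#'
#' One front door to the six estimators compared throughout the package:
#' \describe{
#'   \item{`"svr"`}{classical linear epsilon-SVR on the standardized
#'     predictors (delegated to \pkg{e1071}).}
#'   \item{`"eqsvr"`}{linear SVR with the bounded exponential quantile loss,
#'     fit by CCCP + ClipDCD ([eqsvr()]).}
#'   \item{`"pcsvr"` / `"pfcsvr"`}{epsilon-SVR on the retained principal
#'     components / principal fitted components.}
#'   \item{`"pcrsvr"` / `"pfcrsvr"`}{EQSVR on the retained principal
#'     components / principal fitted components — the robust hybrids.}
#' }
#' Component-space fits map their slopes back to the (standardized)
#' predictor space through the basis loadings; the component-model intercept
#' is kept as the estimate's intercept. Coefficients are reported on the
#' standardized-predictor scale (see [coef.rsvr()] for the original scale).
#'
#' @param x Numeric predictor matrix (default method) or a formula.
#' @param y Numeric response vector.
#' @param method One of `"svr"`, `"eqsvr"`, `"pcsvr"`, `"pcrsvr"`,
#'   `"pfcsvr"`, `"pfcrsvr"`.
#' @param params A [loss_params()] object for the EQSVR-based methods.
#' @param svr_cost,svr_epsilon Cost and epsilon of the classical epsilon-SVR
#'   baseline (conventional defaults 1 and 0.1).
#' @param threshold Cumulative variance share deciding how many components
#'   are retained (default 0.80).
#' @param pfc_degree Degree of the response polynomial basis of the
#'   principal fitted components (default 2).
#' @param standardize Standardize predictor columns before fitting
#'   (default `TRUE`; the component constructions assume standardized
#'   predictors).
#' @param ... Further arguments passed to [eqsvr()] (e.g. `tol`,
#'   `max_outer`).
#' @return An object of class `"rsvr"`: list with `beta`
#'   (standardized-scale slopes), `intercept`, `method`, `q_used` (`NA` for
#'   non-component methods), `basis`, `center`, `scale`, `fit` (the
#'   underlying [eqsvr()] or \pkg{e1071} fit) and `fit_meta`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 50, 4)
#' y <- x %*% c(0.5, 0.5, 0.5, 0.5) + rnorm(50, sd = 0.2)
#' fit <- rsvr(x, y, method = "pfcrsvr")
#' coef(fit)
#' @export
rsvr <- function(x, ...) UseMethod("rsvr")

#' @rdname rsvr
#' @export
rsvr.default <- function(x, y,
                         method = c("pfcrsvr", "pcrsvr", "eqsvr",
                                    "pfcsvr", "pcsvr", "svr"),
                         params = loss_params(),
                         svr_cost = 1, svr_epsilon = 0.1,
                         threshold = 0.80, pfc_degree = 2L,
                         standardize = TRUE, ...) {
  method <- match.arg(tolower(method[1L]),
                      c("pfcrsvr", "pcrsvr", "eqsvr", "pfcsvr", "pcsvr", "svr"))
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be numeric")
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")

  if (standardize) {
    std <- standardize_predictors(x)
    z <- std$z; center <- std$center; scale <- std$scale
  } else {
    z <- x; center <- rep(0, ncol(x)); scale <- rep(1, ncol(x))
  }
  p <- ncol(z)

  basis <- switch(method,
    pcsvr = , pcrsvr = pc_basis(z, threshold, center, scale),
    pfcsvr = , pfcrsvr = pfc_basis(z, y, degree = pfc_degree,
                                   threshold = threshold,
                                   center = center, scale = scale),
    NULL)

  design <- if (is.null(basis)) z else component_scores(z, basis)
  robust <- method %in% c("eqsvr", "pcrsvr", "pfcrsvr")

  if (robust) {
    fit <- eqsvr(design, y, params = params, ...)
    slopes <- fit$w
    intercept <- fit$b
    meta <- list(cccp_iterations = fit$n_cccp_iters, converged = fit$converged)
  } else {
    fit <- e1071::svm(x = design, y = y, type = "eps-regression",
                      kernel = "linear", cost = svr_cost,
                      epsilon = svr_epsilon, scale = FALSE, fitted = FALSE)
    slopes <- if (fit$tot.nSV > 0) drop(crossprod(fit$coefs, fit$SV))
              else rep(0, ncol(design))     # all residuals inside the tube
    intercept <- -fit$rho
    meta <- list(n_support_vectors = fit$tot.nSV)
  }

  beta <- if (is.null(basis)) slopes else backtransform_coef(slopes, basis)
  names(beta) <- colnames(x)
  resid <- y - (drop(z %*% beta) + intercept)
  structure(
    list(beta = beta, intercept = intercept, residuals = resid,
         method = method,
         q_used = if (is.null(basis)) NA_integer_ else basis$q,
         basis = basis, center = center, scale = scale,
         params = if (robust) params else NULL,
         svr_params = if (robust) NULL else
           list(cost = svr_cost, epsilon = svr_epsilon),
         fit = fit, fit_meta = meta, standardized = standardize),
    class = "rsvr"
  )
}

#' @rdname rsvr
#' @param data A data frame for the formula method.
#' @export
rsvr.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  mm <- stats::model.matrix(attr(mf, "terms"), mf)
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  out <- rsvr.default(mm, y, ...)
  out$terms <- attr(mf, "terms")
  out
}

#' @export
print.rsvr <- function(x, ...) {
  cat(sprintf("Robust hybrid SVR fit: method = %s\n", toupper(x$method)))
  if (!is.na(x$q_used))
    cat(sprintf("  %s basis, q = %d components retained\n",
                x$basis$kind, x$q_used))
  cat("  Coefficients (standardized-predictor scale):\n")
  print(coef(x))
  invisible(x)
}

#' Coefficients of a robust hybrid SVR fit
#'
#' @param object An `"rsvr"` fit.
#' @param scale `"standardized"` (the scale on which the model was fit) or
#'   `"original"` (de-standardized slopes and intercept for raw predictors).
#' @param ... Unused.
#' @return Named numeric vector: intercept followed by slopes.
#' @export
coef.rsvr <- function(object, scale = c("standardized", "original"), ...) {
  scale <- match.arg(scale)
  if (scale == "standardized")
    return(c("(Intercept)" = object$intercept, object$beta))
  b <- object$beta / object$scale
  c("(Intercept)" = object$intercept - sum(object$center * b), b)
}

#' Predict from a robust hybrid SVR fit
#'
#' @param object An `"rsvr"` fit.
#' @param newdata Numeric matrix or data frame of raw (unstandardized)
#'   predictors with the training columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.rsvr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$beta))
    stop(sprintf("'newdata' has %d columns; fit used %d predictors",
                 ncol(newdata), length(object$beta)))
  z <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
  drop(z %*% object$beta) + object$intercept
}

#' @export
summary.rsvr <- function(object, ...) {
  structure(list(fit = object), class = "summary.rsvr")
}

#' @export
print.summary.rsvr <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  if (!is.null(f$params)) {
    cat(sprintf("  Loss: lambda = %g, tau = %g, C = %g; CCCP iterations: %s\n",
                f$params$lambda, f$params$tau, f$params$cost,
                f$fit_meta$cccp_iterations))
  } else {
    cat(sprintf("  epsilon-SVR baseline: cost = %g, epsilon = %g, %d SVs\n",
                f$svr_params$cost, f$svr_params$epsilon,
                f$fit_meta$n_support_vectors))
  }
  invisible(x)
}

#' @export
residuals.rsvr <- function(object, ...) object$residuals

rsvr_methods <- function() c("svr", "eqsvr", "pcsvr", "pcrsvr", "pfcsvr", "pfcrsvr")
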