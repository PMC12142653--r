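#' Standardize predictor columns
#'
#' Centers each column to mean zero and scales to unit sample standard
#' deviation (denominator `n - 1`).
#'
#' @param x Numeric matrix `n x p`.
#' @return A list with `z` (the standardized matrix), `center` and `scale`
#'   (length-`p` vectors).
#' @export
standardize_predictors <- function(x) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("'x' must be finite numeric")
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  bad <- which(scl <= 0 | !is.finite(scl))
  if (length(bad))
    stop("zero-variance column(s): ",
         paste(if (is.null(colnames(x))) bad else colnames(x)[bad],
               collapse = ", "))
  z <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  list(z = z, center = ctr, scale = scl)
}

# Sign convention: flip each column so its largest-magnitude entry is
# positive; removes the eigenvector sign ambiguity.
fix_signs <- function(v) {
  flip <- apply(v, 2L, function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  sweep(v, 2L, flip, "*")
}

new_component_basis <- function(loadings, eigenvalues, kind, threshold,
                                center, scale) {
  q <- select_ncomp(eigenvalues, threshold)
  structure(list(loadings = loadings, eigenvalues = eigenvalues, q = q,
                 kind = kind, threshold = threshold,
                 center = center, scale = scale),
            class = "component_basis")
}

#' @export
print.component_basis <- function(x, ...) {
  share <- cumsum(x$eigenvalues) / sum(x$eigenvalues)
  cat(sprintf("%s basis: p = %d, q = %d retained (cumulative share %.3f at threshold %.2f)\n",
              x$kind, ncol(x$loadings), x$q, share[x$q], x$threshold))
  invisible(x)
}

#' Principal component basis of standardized predictors
#'
#' Eigen-decomposition of the cross-product matrix `Z'Z` of the standardized
#' predictors. Loadings are orthonormal, eigenvalues nonincreasing, and the
#' number of retained components `q` is the smallest count whose cumulative
#' eigenvalue share reaches `threshold`.
#'
#' @param z Standardized predictor matrix (see [standardize_predictors()]).
#' @param threshold Cumulative variance share for component retention.
#' @param center,scale Optional centering/scaling vectors recorded in the
#'   basis (for later de-standardization of coefficients).
#' @return A `"component_basis"` object with fields `loadings`,
#'   `eigenvalues`, `q`, `kind = "PC"`.
#' @export
pc_basis <- function(z, threshold = 0.80, center = NULL, scale = NULL) {
  z <- as.matrix(z)
  if (!all(is.finite(z))) stop("'z' must be finite numeric")
  es <- eigen(crossprod(z), symmetric = TRUE)
  new_component_basis(fix_signs(es$vectors), pmax(es$values, 0), "PC",
                      threshold, center, scale)
}

#' Principal fitted component basis
#'
#' Builds the inverse-regression basis: the predictors are regressed on a
#' centered polynomial basis of the response,
#' `F = (y - mean(y), ..., y^r - mean(y^r))`, giving fitted predictors
#' `Zhat = F (F'F)^{-1} F' Z`; the basis is the eigen-decomposition of the
#' fitted covariance `Sigma_fit = Zhat' Zhat / n` (isotropic error
#' structure). Because the fitted predictors live in the `r`-dimensional
#' span of `F`, at most `r` eigenvalues are nonzero, and the leading
#' eigenvectors point along the predictor directions most associated with
#' the response.
#'
#' @param z Standardized predictor matrix.
#' @param y Response vector.
#' @param degree Polynomial degree `r` of the response basis (default 2).
#' @param threshold Cumulative variance share for component retention.
#' @param center,scale Optional centering/scaling vectors recorded in the
#'   basis.
#' @return A `"component_basis"` object with `kind = "PFC"`.
#' @export
pfc_basis <- function(z, y, degree = 2L, threshold = 0.80,
                      center = NULL, scale = NULL) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (length(y) != n) stop("length(y) must equal nrow(z)")
  if (degree < 1L) stop("'degree' must be at least 1")
  if (n <= degree + 1L) stop("need n > degree + 1 observations")
  Fy <- sapply(seq_len(degree), function(j) y^j)
  Fy <- scale(Fy, center = TRUE, scale = FALSE)
  qrF <- qr(Fy)
  if (qrF$rank < degree)
    stop("response polynomial basis is rank deficient (constant y?)")
  zhat <- qr.fitted(qrF, z)
  sigma_fit <- crossprod(zhat) / n
  es <- eigen(sigma_fit, symmetric = TRUE)
  new_component_basis(fix_signs(es$vectors), pmax(es$values, 0), "PFC",
                      threshold, center, scale)
}

#' Number of components meeting a cumulative variance threshold
#'
#' @param eigenvalues Nonnegative, nonincreasing eigenvalue vector.
#' @param threshold Required cumulative share (default 0.80).
#' @return The smallest `q` whose cumulative eigenvalue share reaches
#'   `threshold`; at least 1.
#' @examples
#' select_ncomp(c(3, 1, 1))          # 2
#' select_ncomp(rep(1, 5))           # 4
#' @export
select_ncomp <- function(eigenvalues, threshold = 0.80) {
  if (any(eigenvalues < -1e-12)) stop("eigenvalues must be nonnegative")
  eigenvalues <- pmax(eigenvalues, 0)
  tot <- sum(eigenvalues)
  if (tot <= 0) stop("all eigenvalues are zero")
  q <- which(cumsum(eigenvalues) / tot >= threshold - 1e-12)[1L]
  max(q, 1L)
}

#' Component scores
#'
#' Projects (standardized) predictors onto the first `q` columns of a
#' component basis: `M_q = Z V_q`. PFC scores also use the original
#' standardized predictors (not the fitted ones).
#'
#' @param z Standardized predictor matrix compatible with `basis`.
#' @param basis A `"component_basis"` object.
#' @param q Number of components; defaults to `basis$q`.
#' @return `n x q` score matrix.
#' @export
component_scores <- function(z, basis, q = basis$q) {
  stopifnot(inherits(basis, "component_basis"))
  z <- as.matrix(z)
  if (ncol(z) != nrow(basis$loadings))
    stop("'z' has a different number of columns than the basis loadings")
  z %*% basis$loadings[, seq_len(q), drop = FALSE]
}

#' Map component-space coefficients back to predictor space
#'
#' `beta = V_q %*% alpha_q`, on the standardized-predictor scale.
#'
#' @param alpha_q Coefficient vector for the `q` retained components.
#' @param basis A `"component_basis"` object.
#' @return Length-`p` coefficient vector.
#' @export
backtransform_coef <- function(alpha_q, basis) {
  stopifnot(inherits(basis, "component_basis"))
  if (length(alpha_q) != basis$q)
    stop(sprintf("length(alpha_q) = %d but basis retains q = %d components",
                 length(alpha_q), basis$q))
  drop(basis$loadings[, seq_len(basis$q), drop = FALSE] %*% alpha_q)
}
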