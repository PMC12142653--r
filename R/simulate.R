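#' Generate collinear Gaussian predictors
#'
#' Draws `x[i, j] = sqrt(1 - rho^2) * D[i, j] + rho * D[i, p + 1]` from
#' independent standard normals `D`, so every column has unit variance and
#' each pair of distinct columns shares population correlation `rho^2`
#' through the common factor `D[, p + 1]`.
#'
#' @param n Number of observations.
#' @param p Number of predictors.
#' @param rho Collinearity parameter in `[0, 1)`.
#' @return `n x p` numeric matrix.
#' @export
generate_predictors <- function(n, p, rho) {
  stopifnot(n >= 1, p >= 1)
  if (rho < 0 || rho >= 1) stop("'rho' must lie in [0, 1)")
  d <- matrix(stats::rnorm(n * (p + 1L)), n, p + 1L)
  sqrt(1 - rho^2) * d[, seq_len(p), drop = FALSE] + rho * d[, p + 1L]
}

#' True coefficient vector of a simulated replicate
#'
#' The unit-norm eigenvector of `X'X` belonging to its largest eigenvalue,
#' sign-fixed so the first nonzero entry is positive. Under the collinear
#' generator this points (asymptotically) along the common-factor direction,
#' so the signal lies in the best-conditioned subspace of the predictors.
#'
#' @param x Predictor matrix (standardized before use in the study design).
#' @return Unit-norm numeric vector of length `ncol(x)`.
#' @export
true_beta <- function(x) {
  x <- as.matrix(x)
  es <- eigen(crossprod(x), symmetric = TRUE)
  if (es$values[1L] <= 0) stop("'x' has rank 0")
  b <- es$vectors[, 1L]
  nz <- which(b != 0)[1L]
  if (is.na(nz)) stop("degenerate eigenvector")
  b <- b * sign(b[nz])
  b / sqrt(sum(b^2))
}

#' Simulate the response
#'
#' `y = X beta + e` with standard normal noise (`sd = 0`, a testing hook,
#' gives the noise-free response).
#'
#' @param x Predictor matrix.
#' @param beta Coefficient vector.
#' @param sd Noise standard deviation (default 1).
#' @return Numeric response vector.
#' @export
generate_response <- function(x, beta, sd = 1) {
  x <- as.matrix(x)
  if (ncol(x) != length(beta)) stop("length(beta) must equal ncol(x)")
  drop(x %*% beta) + if (sd > 0) stats::rnorm(nrow(x), sd = sd) else 0
}

#' Inject vertical outliers into a response
#'
#' Picks `round(fraction * n)` distinct positions uniformly without
#' replacement and shifts each by `b * max(y)`, with `max(y)` taken over the
#' uncontaminated vector; all other entries are unchanged.
#'
#' @param y Response vector.
#' @param fraction Contamination fraction in `[0, 1]`.
#' @param b Outlier magnitude multiplier (default 10).
#' @return List with `y` (contaminated vector) and `indices` (the shifted
#'   positions, possibly empty).
#' @export
contaminate_response <- function(y, fraction, b = 10) {
  if (fraction < 0 || fraction > 1) stop("'fraction' must lie in [0, 1]")
  n <- length(y)
  k <- round(fraction * n)
  if (k == 0L) return(list(y = y, indices = integer(0)))
  idx <- sample.int(n, k)
  y[idx] <- b * max(y) + y[idx]
  list(y = y, indices = sort(idx))
}

#' Coefficient estimation error metrics
#'
#' `mse_beta` is the mean squared coordinatewise deviation
#' `mean((beta_hat - beta)^2)`; `mae_beta` the mean absolute deviation.
#'
#' @param beta_hat,beta Equal-length coefficient vectors.
#' @return Nonnegative scalar.
#' @export
mse_beta <- function(beta_hat, beta) {
  if (length(beta_hat) != length(beta)) stop("coefficient lengths differ")
  mean((beta_hat - beta)^2)
}

#' @rdname mse_beta
#' @export
mae_beta <- function(beta_hat, beta) {
  if (length(beta_hat) != length(beta)) stop("coefficient lengths differ")
  mean(abs(beta_hat - beta))
}

#' Percentage reduction in MSE
#'
#' `100 * (mse_competitor - mse_proposed) / mse_competitor`; positive values
#' favour the proposed estimator.
#'
#' @param mse_proposed MSE of the proposed estimator.
#' @param mse_competitor MSE of the competitor (must be positive).
#' @return Percentage (can be negative).
#' @export
pmse <- function(mse_proposed, mse_competitor) {
  if (mse_competitor <= 0) stop("'mse_competitor' must be positive")
  100 * (mse_competitor - mse_proposed) / mse_competitor
}

#' Monte Carlo study configuration
#'
#' Captures one full factorial slice of the benchmark design: sample sizes,
#' predictor count, collinearity, contamination levels, outlier magnitude,
#' replication count, loss hyperparameters and the component retention
#' threshold. The default penalty is `C = 0.2`, switching to `C = 0.04` when
#' `p >= 25` (the larger predictor sets need the weaker penalty).
#'
#' @param n Vector of sample sizes.
#' @param p Number of predictors.
#' @param rho Collinearity parameter in `[0, 1)`.
#' @param contamination Vector of contamination fractions.
#' @param b_outlier Outlier magnitude multiplier (default 10).
#' @param reps Monte Carlo replications per cell (default 100).
#' @param lambda,tau Loss steepness and hedging factor (defaults 0.5, 0.7).
#' @param cost EQSVR penalty `C`; default `NULL` resolves to 0.2, or 0.04
#'   when `p >= 25`.
#' @param svr_cost,svr_epsilon Baseline epsilon-SVR settings.
#' @param threshold Component retention threshold (default 0.80).
#' @param pfc_degree Response polynomial degree for PFC (default 2).
#' @param estimators Estimators to run (default all six).
#' @param seed Master seed; per-replicate seeds are spawned from it so every
#'   estimator sees identical data within a replicate.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n = c(50, 100, 300), p = 5, rho = 0.8,
                       contamination = c(0, 0.05, 0.15, 0.30),
                       b_outlier = 10, reps = 100,
                       lambda = 0.5, tau = 0.7, cost = NULL,
                       svr_cost = 1, svr_epsilon = 0.1,
                       threshold = 0.80, pfc_degree = 2L,
                       estimators = rsvr_methods(), seed = 1L) {
  if (is.null(cost)) cost <- if (p >= 25) 0.04 else 0.2
  estimators <- match.arg(tolower(estimators), rsvr_methods(),
                          several.ok = TRUE)
  stopifnot(all(n >= 10), p >= 2, rho >= 0, rho < 1,
            all(contamination >= 0 & contamination < 1), reps >= 1)
  structure(list(n = n, p = p, rho = rho, contamination = contamination,
                 b_outlier = b_outlier, reps = as.integer(reps),
                 params = loss_params(lambda, tau, cost),
                 svr_cost = svr_cost, svr_epsilon = svr_epsilon,
                 threshold = threshold, pfc_degree = pfc_degree,
                 estimators = estimators, seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from YAML or JSON
#'
#' Keys mirror the arguments of [sim_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `"sim_config"` object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(sim_config, cfg)
}

#' Run one replicate: simulate, contaminate, fit every estimator
#' @noRd
run_replicate <- function(n, cfg) {
  x <- generate_predictors(n, cfg$p, cfg$rho)
  z <- standardize_predictors(x)$z
  beta <- true_beta(z)
  y <- generate_response(z, beta)
  out <- vector("list", length(cfg$contamination))
  names(out) <- as.character(cfg$contamination)
  for (ci in seq_along(cfg$contamination)) {
    ystar <- contaminate_response(y, cfg$contamination[ci], cfg$b_outlier)$y
    res <- lapply(cfg$estimators, function(m) {
      est <- tryCatch(
        rsvr(z, ystar, method = m, params = cfg$params,
             svr_cost = cfg$svr_cost, svr_epsilon = cfg$svr_epsilon,
             threshold = cfg$threshold, pfc_degree = cfg$pfc_degree,
             standardize = FALSE),
        error = function(e) NULL)
      if (is.null(est)) return(c(mse = NA_real_, mae = NA_real_))
      c(mse = mse_beta(est$beta, beta), mae = mae_beta(est$beta, beta))
    })
    out[[ci]] <- do.call(rbind, res)
  }
  out
}

#' Run the Monte Carlo benchmark
#'
#' For every cell (sample size x contamination level) and every replicate:
#' fresh collinear predictors, true coefficients as the top eigenvector of
#' the standardized cross-product, Gaussian response, vertical-outlier
#' contamination, then all requested estimators fit to the same contaminated
#' data; per-replicate MSE and MAE of the coefficient estimates are
#' aggregated into means and standard deviations across replicates. Fully
#' reproducible from `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @param verbose Print per-cell progress to `stderr`.
#' @return A data frame of class `"metrics_table"` with columns `estimator`,
#'   `n`, `p`, `rho`, `contamination`, `mean_mse`, `sd_mse`, `mean_mae`,
#'   `sd_mae`, `reps_used`, `failures`.
#' @export
run_monte_carlo <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rep_seeds <- matrix(
    sample.int(.Machine$integer.max - 1L, length(config$n) * config$reps),
    nrow = config$reps)
  rows <- list()
  for (ni in seq_along(config$n)) {
    n <- config$n[ni]
    # reps x contamination x estimator arrays of mse / mae
    acc <- array(NA_real_,
                 dim = c(config$reps, length(config$contamination),
                         length(config$estimators), 2L))
    for (r in seq_len(config$reps)) {
      set.seed(rep_seeds[r, ni])
      rep_out <- run_replicate(n, config)
      for (ci in seq_along(config$contamination)) {
        acc[r, ci, , 1L] <- rep_out[[ci]][, "mse"]
        acc[r, ci, , 2L] <- rep_out[[ci]][, "mae"]
      }
    }
    for (ci in seq_along(config$contamination)) {
      for (ei in seq_along(config$estimators)) {
        mse <- acc[, ci, ei, 1L]; mae <- acc[, ci, ei, 2L]
        ok <- is.finite(mse)
        rows[[length(rows) + 1L]] <- data.frame(
          estimator = config$estimators[ei], n = n, p = config$p,
          rho = config$rho, contamination = config$contamination[ci],
          mean_mse = mean(mse[ok]), sd_mse = stats::sd(mse[ok]),
          mean_mae = mean(mae[ok]), sd_mae = stats::sd(mae[ok]),
          reps_used = sum(ok), failures = sum(!ok))
      }
    }
    if (verbose)
      message(sprintf("n = %d done (%d reps x %d contamination levels)",
                      n, config$reps, length(config$contamination)))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("metrics_table", "data.frame")
  attr(out, "config") <- config
  out
}

#' Format a metrics table in the benchmark's row layout
#'
#' Renders mean +/- SD cells as `estimator x n` rows against contamination
#' columns, for either metric.
#'
#' @param tab A `"metrics_table"` from [run_monte_carlo()].
#' @param metric `"mse"` or `"mae"`.
#' @param digits Significant digits per cell.
#' @return A character matrix (invisibly printed with [print()]).
#' @export
format_metrics_table <- function(tab, metric = c("mse", "mae"), digits = 4L) {
  metric <- match.arg(metric)
  mcol <- paste0("mean_", metric); scol <- paste0("sd_", metric)
  keys <- unique(tab[, c("estimator", "n")])
  levels_c <- sort(unique(tab$contamination))
  out <- matrix("", nrow(keys), length(levels_c),
                dimnames = list(paste(toupper(keys$estimator), keys$n),
                                sprintf("%g%%", 100 * levels_c)))
  for (i in seq_len(nrow(keys))) {
    for (j in seq_along(levels_c)) {
      row <- tab[tab$estimator == keys$estimator[i] & tab$n == keys$n[i] &
                   tab$contamination == levels_c[j], ]
      if (nrow(row))
        out[i, j] <- sprintf("%.*f ± %.*f", digits, row[[mcol]],
                             digits, row[[scol]])
    }
  }
  out
}

#' @export
print.metrics_table <- function(x, ...) {
  cfg <- attr(x, "config")
  if (!is.null(cfg))
    cat(sprintf(
      "Monte Carlo metrics: p = %d, rho = %g, b = %g, %d reps, seed %d\n",
      cfg$p, cfg$rho, cfg$b_outlier, cfg$reps, cfg$seed))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
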