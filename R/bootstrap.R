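#' Load a regression dataset from CSV
#'
#' Reads a numeric CSV with a header row, splits off the response column and
#' returns the predictor matrix with column names.
#'
#' @param path Path to the CSV file.
#' @param response Name of the response column.
#' @return List with `x` (numeric predictor matrix), `y` (response vector)
#'   and `names` (predictor column names).
#' @export
load_dataset <- function(path, response) {
  if (!file.exists(path)) stop("dataset not found: ", path)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  if (!response %in% names(df))
    stop(sprintf("response column '%s' not present (columns: %s)",
                 response, paste(names(df), collapse = ", ")))
  non_num <- names(df)[!vapply(df, is.numeric, logical(1L))]
  if (length(non_num))
    stop("non-numeric column(s): ", paste(non_num, collapse = ", "))
  bad <- which(!stats::complete.cases(df))
  if (length(bad))
    stop(sprintf("%d row(s) with missing values: %s", length(bad),
                 paste(bad, collapse = ", ")))
  y <- df[[response]]
  x <- as.matrix(df[setdiff(names(df), response)])
  list(x = x, y = y, names = colnames(x))
}

#' Bootstrap stability of an estimator's coefficients (MSEBE)
#'
#' Case-resamples the rows `B` times with replacement, refits the chosen
#' estimator on every resample, and summarizes coefficient stability as the
#' Mean Standard Error of the Bootstrap Estimates: the average over the `p`
#' coefficients of their bootstrap standard deviations. Smaller MSEBE means
#' more stable coefficient estimation, the comparison criterion used for
#' real datasets where the true coefficients are unknown. Point coefficients
#' come from the full-data fit.
#'
#' @param x Predictor matrix.
#' @param y Response vector.
#' @param method Estimator name as in [rsvr()].
#' @param B Number of bootstrap resamples (default 500).
#' @param params,svr_cost,svr_epsilon,threshold,pfc_degree,standardize As in
#'   [rsvr()].
#' @param max_retries Resamples on which the estimator errors are redrawn up
#'   to this many times, then counted as failed.
#' @param indices Optional list of `B` row-index vectors overriding the
#'   random resampling (each of length `nrow(x)`, values in `1..nrow(x)`);
#'   mainly a reproducibility hook.
#' @return An object of class `"bootstrap_report"`: list with `method`,
#'   `coefficients` (full-data, standardized scale), `boot_sd`
#'   (per-coefficient bootstrap SD), `msebe`, `B`, `failures`.
#' @export
bootstrap_msebe <- function(x, y, method = "pfcrsvr", B = 500L,
                            params = loss_params(), svr_cost = 1,
                            svr_epsilon = 0.1, threshold = 0.80,
                            pfc_degree = 2L, standardize = TRUE,
                            max_retries = 3L, indices = NULL) {
  if (B < 2) stop("'B' must be at least 2")
  if (!is.null(indices) && length(indices) != B)
    stop("'indices' must hold one resample per bootstrap draw")
  x <- as.matrix(x)
  n <- nrow(x)
  fit_once <- function(xi, yi)
    rsvr(xi, yi, method = method, params = params, svr_cost = svr_cost,
         svr_epsilon = svr_epsilon, threshold = threshold,
         pfc_degree = pfc_degree, standardize = standardize)$beta
  full <- fit_once(x, y)
  betas <- matrix(NA_real_, B, ncol(x))
  failures <- 0L
  for (bdx in seq_len(B)) {
    done <- FALSE
    for (try in seq_len(max_retries + 1L)) {
      idx <- if (is.null(indices)) sample.int(n, n, replace = TRUE)
             else indices[[bdx]]
      bhat <- tryCatch(fit_once(x[idx, , drop = FALSE], y[idx]),
                       error = function(e) NULL)
      if (!is.null(bhat)) { betas[bdx, ] <- bhat; done <- TRUE; break }
    }
    if (!done) failures <- failures + 1L
  }
  sds <- apply(betas, 2L, stats::sd, na.rm = TRUE)
  structure(
    list(method = method, coefficients = full, boot_sd = sds,
         msebe = mean(sds), B = as.integer(B), failures = failures),
    class = "bootstrap_report"
  )
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf("Bootstrap coefficient stability: method = %s, B = %d%s\n",
              toupper(x$method), x$B,
              if (x$failures) sprintf(" (%d failed resamples)", x$failures)
              else ""))
  tab <- cbind(estimate = x$coefficients, boot_sd = x$boot_sd)
  print(round(tab, 6))
  cat(sprintf("MSEBE = %.6g\n", x$msebe))
  invisible(x)
}
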