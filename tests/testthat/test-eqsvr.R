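test_that("augment_design appends the intercept column and validates", {
  ad <- augment_design(diag(2), c(1, 2))
  expect_equal(ad$x, cbind(diag(2), c(1, 1)))
  ad3 <- augment_design(matrix(c(5, 6, 7), 3, 1), 1:3)
  expect_equal(ad3$x[, 2], rep(1, 3))
  expect_error(augment_design(matrix(0, 0, 2), numeric(0)), "non-empty")
  expect_error(augment_design(diag(3), 1:2), "length")
  expect_error(augment_design(matrix(c(1, NA), 2, 1), 1:2), "finite")
})

test_that("dual assembly reproduces the block-matrix form", {
  # single-observation instance worked out by hand:
  # K = xa xa' = 2, lambda = tau = C = 1
  ad <- structure(list(x = matrix(c(1, 1), 1, 2), y = 3), # bypass n >= 2 guard
                  class = "augmented_design")
  p <- loss_params(1, 1, 1)
  qp <- eqsvr_dual(ad, delta = 0, p)
  Kr <- matrix(c(2, -2, -2, 2), 2)
  expect_equal(qp$Q, Kr + 2.5 * matrix(1, 2, 2))
  expect_equal(qp$lb, c(0, 0))            # delta = 0 frees the lower bound
  expect_equal(qp$l, c(1 * 3 + 5 / 4, -1 * 3 + 5 / 4))
  # general instance: Q symmetric positive semidefinite + positive diagonal
  task <- make_task(n = 12, p = 2, seed = 3)
  ad2 <- augment_design(task$z, task$y)
  pars <- loss_params(0.5, 0.7, 0.2)
  qp2 <- eqsvr_dual(ad2, eq_delta(task$y, pars), pars)
  expect_equal(qp2$Q, t(qp2$Q))
  expect_true(min(eigen(qp2$Q, symmetric = TRUE, only.values = TRUE)$values) >
                -1e-8)
  expect_true(all(diag(qp2$Q) > 0))
  expect_error(eqsvr_dual(ad2, delta = 1:5, pars), "slope per observation")
})

test_that("ClipDCD solves scalar cases exactly and matches the QP oracle", {
  expect_equal(clipdcd(matrix(2), 4, 0)$u, 2)      # interior optimum l/Q
  expect_equal(clipdcd(matrix(2), -4, 0)$u, 0)     # bound active
  set.seed(42)
  for (i in 1:6) {
    m <- 6
    A <- matrix(rnorm(m * m), m)
    Q <- crossprod(A) + 0.5 * diag(m)
    l <- rnorm(m)
    lb <- rep(0, m)
    s <- clipdcd(Q, l, lb, tol = 1e-7)
    o <- qp_oracle(Q, l, lb)
    expect_lt(abs(s$objective - o$objective), 1e-5)
    expect_true(all(s$u >= lb - 1e-12))
  }
  expect_error(clipdcd(matrix(c(0, 0, 0, 1), 2), c(1, 1), c(0, 0)),
               "positive diagonal")
})

test_that("ClipDCD reports non-convergence at the iteration cap", {
  set.seed(5)
  A <- matrix(rnorm(100), 10)
  Q <- crossprod(A) + diag(10)
  expect_warning(res <- clipdcd(Q, rnorm(10), rep(0, 10), tol = 1e-12,
                                max_iter = 3L),
                 "max_iter")
  expect_false(res$converged)
})

test_that("recover_weights applies the stationarity identity", {
  ad1 <- structure(list(x = matrix(c(1, 1), 1, 2), y = 3),
                   class = "augmented_design")
  p <- loss_params(1, 0.5, 1)
  expect_equal(recover_weights(ad1, gamma = 2, theta = 1, delta = 0, p),
               c(1.5, 1.5))
  expect_equal(recover_weights(ad1, 0, 0, 0, p), c(0, 0))
  task <- make_task(n = 10, p = 2, seed = 4)
  ad <- augment_design(task$z, task$y)
  expect_error(recover_weights(ad, 1:3, 1:10, 1:10, p), "length n")
})

test_that("CCCP fit recovers a noise-free linear signal", {
  set.seed(11)
  x <- matrix(rnorm(90), 30, 3)
  beta <- c(1, -0.5, 2) / sqrt(sum(c(1, -0.5, 2)^2))  # unit norm, as in the study design
  y <- drop(x %*% beta)
  fit <- eqsvr(x, y, loss_params(0.5, 0.7, 0.2))
  expect_lt(sqrt(mean((fitted(fit) - y)^2)), 0.1)
  expect_true(fit$converged)
})

test_that("objective trace is non-increasing (CCCP majorization)", {
  for (seed in 1:4) {
    task <- make_task(n = 25, p = 3, seed = seed, noise = 1)
    ycon <- task$y
    ycon[1] <- ycon[1] + 10 * max(task$y)
    fit <- eqsvr(task$z, ycon, loss_params(0.5, 0.7, 0.2), inner_tol = 1e-8)
    expect_true(all(diff(fit$objective_trace) <= 1e-8))
  }
})

test_that("a gross outlier moves EQSVR far less than least squares", {
  task <- make_task(n = 30, p = 3, seed = 7, noise = 0.2)
  pars <- loss_params(0.5, 0.7, 0.2)
  clean <- eqsvr(task$z, task$y, pars)
  ycon <- task$y
  ycon[1] <- ycon[1] + 10 * max(task$y)
  cont <- eqsvr(task$z, ycon, pars)
  ols_clean <- qr.solve(cbind(task$z, 1), task$y)
  ols_cont <- qr.solve(cbind(task$z, 1), ycon)
  shift_eq <- sqrt(sum((cont$w - clean$w)^2))
  shift_ols <- sqrt(sum((ols_cont[1:3] - ols_clean[1:3])^2))
  expect_lt(shift_eq, shift_ols)
})

test_that("EQSVR influence is bounded as the outlier grows; OLS is not", {
  task <- make_task(n = 30, p = 2, seed = 8, noise = 0.2)
  pars <- loss_params(0.5, 0.7, 0.2)
  base <- eqsvr(task$z, task$y, pars)$w
  shifts_eq <- shifts_ols <- numeric(0)
  for (b in c(10, 100, 1000)) {
    ycon <- task$y
    ycon[1] <- ycon[1] + b * max(task$y)
    shifts_eq <- c(shifts_eq, sqrt(sum((eqsvr(task$z, ycon, pars)$w - base)^2)))
    ols <- qr.solve(cbind(task$z, 1), ycon)
    ols0 <- qr.solve(cbind(task$z, 1), task$y)
    shifts_ols <- c(shifts_ols, sqrt(sum((ols[1:2] - ols0[1:2])^2)))
  }
  expect_lt(max(shifts_eq), 1)               # bounded influence
  expect_gt(shifts_ols[3] / shifts_ols[1], 50)  # OLS grows ~ linearly in b
})

test_that("predictions are the linear form in the trained weights", {
  m <- structure(list(w = c(1, 0), b = 0), class = "eqsvr")
  expect_equal(predict(m, matrix(c(3, 9), 1)), 3)
  m0 <- structure(list(w = c(0, 0), b = 4.5), class = "eqsvr")
  expect_equal(predict(m0, matrix(rnorm(10), 5)), rep(4.5, 5))
  expect_error(predict(m, matrix(1, 1, 3)), "columns")
  set.seed(12)
  x <- matrix(rnorm(40), 20, 2)
  y <- drop(x %*% c(2, 0))
  fit <- eqsvr(x, y, loss_params(0.5, 0.7, 1))
  expect_equal(predict(fit, x), y, tolerance = 0.1)
})

test_that("all-zero response yields (near-)zero weights", {
  set.seed(13)
  x <- matrix(rnorm(60), 30, 2)
  fit <- eqsvr(x, rep(0, 30), loss_params(0.5, 0.7, 0.2))
  expect_lt(sqrt(sum(c(fit$w, fit$b)^2)), 1e-4)
})
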