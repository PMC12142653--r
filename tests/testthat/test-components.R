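test_that("standardization gives exact zero mean and unit sample SD", {
  x <- cbind(a = c(1, 2, 3), b = c(10, -4, 2))
  s <- standardize_predictors(x)
  expect_equal(colMeans(s$z), c(a = 0, b = 0))
  expect_equal(apply(s$z, 2, sd), c(a = 1, b = 1))
  # already standardized input is unchanged
  s2 <- standardize_predictors(s$z)
  expect_equal(s2$z, s$z, tolerance = 1e-12)
  expect_error(standardize_predictors(cbind(a = 1:3, b = rep(2, 3))), "b")
})

test_that("PC basis is an orthonormal eigenbasis with sorted eigenvalues", {
  set.seed(21)
  z <- standardize_predictors(generate_predictors(200, 4, 0.6))$z
  b <- pc_basis(z)
  expect_equal(crossprod(b$loadings), diag(4), tolerance = 1e-8)
  expect_true(all(diff(b$eigenvalues) <= 1e-8))
  expect_true(all(b$eigenvalues >= 0))
  expect_identical(b$kind, "PC")
  # two independent columns split variance evenly
  set.seed(22)
  z2 <- standardize_predictors(matrix(rnorm(2e4), 1e4, 2))$z
  b2 <- pc_basis(z2)
  expect_equal(b2$eigenvalues[1] / sum(b2$eigenvalues), 0.5, tolerance = 0.05)
  # near-perfect correlation concentrates variance on the first component
  set.seed(23)
  u <- rnorm(500)
  z3 <- standardize_predictors(cbind(u, u + rnorm(500, sd = 1e-4)))$z
  b3 <- pc_basis(z3)
  expect_gt(b3$eigenvalues[1] / sum(b3$eigenvalues), 0.999)
  expect_equal(b3$q, 1L)
})

test_that("PFC basis concentrates on response-informative directions", {
  # response independent of predictors: fitted spectrum is noise of order r/n
  set.seed(24)
  z <- standardize_predictors(matrix(rnorm(2000 * 4), 2000, 4))$z
  y <- rnorm(2000)
  b <- pfc_basis(z, y)
  expect_true(all(b$eigenvalues <= 0.05))
  expect_equal(crossprod(b$loadings), diag(4), tolerance = 1e-8)
  # rank-1 inverse-regression signal: leading eigenvector within 5 degrees
  set.seed(25)
  y2 <- rnorm(400)
  gam <- c(2, -1, 0.5, 1)
  gam <- gam / sqrt(sum(gam^2))
  # rank-1 construction fed directly (column scaling would rotate the target)
  z2 <- outer(y2, gam) + matrix(rnorm(400 * 4, sd = 0.01), 400, 4)
  b2 <- pfc_basis(z2, y2)
  cosang <- abs(sum(b2$loadings[, 1] * gam))
  expect_gt(cosang, cos(5 * pi / 180))
  expect_identical(b2$kind, "PFC")
  # at most degree nonzero eigenvalues (fitted values live in an r-dim span)
  expect_lt(b2$eigenvalues[3] / b2$eigenvalues[1], 1e-10)
  expect_error(pfc_basis(z, rep(1, 2000)), "rank deficient")
})

test_that("PFC spectrum is invariant to affine response rescaling", {
  set.seed(26)
  task <- make_task(n = 80, p = 4, seed = 26)
  b1 <- pfc_basis(task$z, task$y)
  b2 <- pfc_basis(task$z, 3 * task$y - 7)
  expect_equal(b1$eigenvalues, b2$eigenvalues, tolerance = 1e-8)
  expect_equal(abs(crossprod(b1$loadings[, 1], b2$loadings[, 1]))[1, 1], 1,
               tolerance = 1e-8)
})

test_that("component count selection honours the threshold rule", {
  expect_equal(select_ncomp(c(3, 1, 1)), 2L)
  expect_equal(select_ncomp(rep(1, 5)), 4L)   # 4/5 meets >= 0.80 exactly
  expect_equal(select_ncomp(c(99, 1)), 1L)
  expect_equal(select_ncomp(c(5, 4, 2), threshold = 1), 3L)
  expect_error(select_ncomp(c(0, 0)), "zero")
  # concentrating mass on the leading eigenvalue never increases q
  ev <- c(10, 5, 3, 2)
  q1 <- select_ncomp(ev)
  q2 <- select_ncomp(c(20, 5, 3, 2))
  expect_lte(q2, q1)
})

test_that("scores and back-transformation are consistent projections", {
  set.seed(27)
  z <- standardize_predictors(generate_predictors(60, 3, 0.4))$z
  b <- pc_basis(z, threshold = 1)      # q = p
  sc <- component_scores(z, b)
  expect_equal(ncol(sc), 3L)
  expect_equal(sc, z %*% b$loadings)
  # column covariance of full scores is the diagonal eigenvalue matrix
  expect_equal(crossprod(sc), diag(b$eigenvalues), tolerance = 1e-8)
  # isometry at q = p
  alpha <- c(0.3, -1, 2)
  expect_equal(sqrt(sum(backtransform_coef(alpha, b)^2)), sqrt(sum(alpha^2)))
  expect_equal(backtransform_coef(rep(0, 3), b), rep(0, 3))
  # rotation by 90 degrees maps the first axis onto the second
  rot <- structure(list(loadings = matrix(c(0, 1, -1, 0), 2), q = 2L),
                   class = "component_basis")
  expect_equal(abs(backtransform_coef(c(1, 0), rot)), c(0, 1))
  expect_error(backtransform_coef(1:2, b), "q = 3")
  expect_error(component_scores(z[, 1:2], b), "columns")
})

test_that("PFC reproduces PC loadings when the response spans the predictors", {
  # noise-free invertible link with r = p: fitted values recover z exactly
  set.seed(28)
  z <- standardize_predictors(matrix(rnorm(300), 100, 3))$z
  # make z an exact polynomial function of y so the span matches
  y <- rnorm(100)
  zz <- standardize_predictors(cbind(y, y^2, y^3))$z
  bpfc <- pfc_basis(zz, y, degree = 3)
  bpc <- pc_basis(zz)
  # both diagonalize (up to scaling n) the same matrix
  agree <- abs(diag(crossprod(bpfc$loadings, bpc$loadings)))
  expect_equal(agree, rep(1, 3), tolerance = 1e-6)
})
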