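# Independent oracles used across the suite. Both deliberately avoid the
# package's own solver path: the QP oracle is projected quasi-Newton from
# base R, the primal oracle is derivative-free search from neutral starts.

# Bounded-below QP oracle: min 0.5 u'Qu - l'u, u >= lb, via L-BFGS-B.
qp_oracle <- function(Q, l, lb, start = NULL) {
  if (is.null(start)) start <- pmax(lb, 0)
  obj <- function(u) 0.5 * sum(u * (Q %*% u)) - sum(l * u)
  grad <- function(u) drop(Q %*% u) - l
  o <- stats::optim(start, obj, grad, method = "L-BFGS-B", lower = lb,
                    control = list(factr = 10, maxit = 2000))
  list(u = o$par, objective = o$value)
}

# Regularized EQSVR primal objective at augmented weights wa = (w, b).
eqsvr_primal <- function(wa, x, y, params) {
  r <- y - drop(cbind(x, 1) %*% wa)
  0.5 * sum(wa^2) + params$cost * sum(eq_loss(r, params))
}

# Derivative-free minimization of the primal from several neutral starts
# (zero and least squares); returns the best objective value found.
primal_oracle <- function(x, y, params) {
  obj <- function(wa) eqsvr_primal(wa, x, y, params)
  p1 <- ncol(x) + 1L
  starts <- list(rep(0, p1), qr.solve(cbind(x, 1), y))
  best <- Inf
  for (st in starts) {
    o <- stats::optim(st, obj, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# Small simulated regression task shared by several files.
make_task <- function(n = 40, p = 3, rho = 0.5, seed = 1, noise = 0.2) {
  set.seed(seed)
  x <- generate_predictors(n, p, rho)
  z <- standardize_predictors(x)$z
  beta <- true_beta(z)
  y <- generate_response(z, beta, sd = noise)
  list(x = x, z = z, beta = beta, y = y)
}
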