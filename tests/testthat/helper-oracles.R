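# Independent oracles used to pin expected values.  These deliberately use
# naive dense linear algebra / brute-force enumeration, not the package's
# efficient code paths.

# Newton-Raphson logistic regression, written from the score/Hessian.
oracle_logistic_nr <- function(y, X, tol = 1e-12, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    H <- crossprod(X, X * W)
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Dense evaluation of the working-model quasi log-likelihood:
# -1/2 [ log|V| + (Y' - X ahat)' V^{-1} (Y' - X ahat) ],
# V = tau2 Z Z' + diag(r), ahat = (X'V^{-1}X)^{-1} X'V^{-1} Y'.
oracle_quasi_loglik_dense <- function(yw, X, Z, r, tau2) {
  n <- length(yw)
  V <- diag(r, n)
  if (!is.null(Z) && ncol(Z) > 0) V <- V + tau2 * tcrossprod(Z)
  Vi <- solve(V)
  ahat <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% yw)
  resid <- yw - drop(X %*% ahat)
  -0.5 * (determinant(V, logarithm = TRUE)$modulus[1] +
            drop(t(resid) %*% Vi %*% resid))
}

# Dense GLS fixed-effect estimate at a given tau2.
oracle_gls_alpha_dense <- function(yw, X, Z, r, tau2) {
  n <- length(yw)
  V <- diag(r, n)
  if (!is.null(Z) && ncol(Z) > 0) V <- V + tau2 * tcrossprod(Z)
  Vi <- solve(V)
  unname(drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% yw)))
}

# Maximize f over [0, upper] by a dense grid refined by golden section.
oracle_grid_golden_max <- function(f, upper, n_grid = 1e4) {
  grid <- seq(0, upper, length.out = n_grid)
  vals <- vapply(grid, f, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, n_grid)]
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  while (hi - lo > 1e-12 * (1 + hi)) {
    if (f1 < f2) {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- f(x2)
    } else {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- f(x1)
    }
  }
  xmax <- (lo + hi) / 2
  list(argmax = xmax, max = f(xmax))
}

# Monte-Carlo tail probability of sum_j lambda_j chi2_1.
oracle_quadform_mc <- function(q, lambda, n_draws = 1e6) {
  Q <- numeric(n_draws)
  for (l in lambda) Q <- Q + l * stats::rchisq(n_draws, df = 1)
  mean(Q >= q)
}

# Brute-force score quadratic form: sum_k ( sum_i z_ik (y_i - mu0_i) )^2.
oracle_score_q <- function(y, X, Z) {
  mu0 <- 1 / (1 + exp(-drop(X %*% oracle_logistic_nr(y, X))))
  res <- y - mu0
  total <- 0
  for (k in seq_len(ncol(Z))) {
    s <- 0
    for (i in seq_len(nrow(Z))) s <- s + Z[i, k] * res[i]
    total <- total + s^2
  }
  unname(total)
}

# Profiled working-model quasi log-likelihood of a converged fit, as a
# function of tau2, with the residual scale sigma2 maximized out
# numerically at every point (shares the fit's working response and
# weights; independent of the fit's own optimizer).
fit_profile_ll <- function(fit) {
  function(tau2) {
    optimize(function(s2) quasi_loglik(fit$working_response, fit$data$X,
                                       fit$data$Z, fit$r_diag, tau2, s2),
             c(1e-3, 50), maximum = TRUE, tol = 1e-10)$objective
  }
}
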