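#' Quasi log-likelihood of the PQL working linear mixed model
#'
#' Evaluates, up to an additive constant,
#' `-1/2 [ log|V| + (Y' - X alpha_hat)' V^{-1} (Y' - X alpha_hat) ]`
#' with `V = tau2 Z Z' + sigma2 R`, `R = diag(r_diag)`, and `alpha_hat`
#' the generalized least squares estimate
#' `(X' V^{-1} X)^{-1} X' V^{-1} Y'`.  The default `sigma2 = 1` is the
#' fixed-scale working covariance; [pql_fit()] additionally profiles the
#' residual scale `sigma2`.
#'
#' The computation standardizes by `R^{-1/2}` and uses one thin SVD of the
#' standardized `Z`, so `log|V|` and the quadratic form reduce to sums over
#' `min(n, K)` singular values; no `n x n` matrix is formed.
#'
#' @param working_response Working response vector `Y'` (length n).
#' @param X Fixed-effects matrix.
#' @param Z Random-effects (dosage) matrix; a zero-column or all-zero `Z`
#'   makes the value constant in `tau2`.
#' @param r_diag Strictly positive diagonal of the working weight matrix
#'   `R`.
#' @param tau2 Non-negative variance component at which to evaluate.
#' @param sigma2 Positive residual scale multiplying `R`.
#'
#' @return The scalar quasi log-likelihood.
#' @export
quasi_loglik <- function(working_response, X, Z, r_diag, tau2, sigma2 = 1) {
  yw <- as.numeric(working_response)
  X <- as.matrix(X)
  r_diag <- as.numeric(r_diag)
  if (any(r_diag <= 0))
    vclrt_stop("r_diag must be strictly positive", "vclrt_invalid_input")
  if (tau2 < 0)
    vclrt_stop("tau2 must be non-negative", "vclrt_invalid_input")
  if (sigma2 <= 0)
    vclrt_stop("sigma2 must be positive", "vclrt_invalid_input")
  n <- length(yw)
  stopifnot(nrow(X) == n, length(r_diag) == n)
  sw <- 1 / sqrt(r_diag)
  Xt <- X * sw
  yt <- yw * sw
  sumlogr <- sum(log(r_diag))
  G0 <- crossprod(Xt)
  g0 <- crossprod(Xt, yt)
  yy <- sum(yt^2)
  lam <- tau2 / sigma2
  use_z <- !is.null(Z) && ncol(as.matrix(Z)) > 0 && tau2 > 0 &&
    any(as.matrix(Z) != 0)
  if (use_z) {
    Zt <- as.matrix(Z) * sw
    sv <- svd(Zt, nv = 0)
    d <- sv$d^2
    A <- crossprod(sv$u, Xt)
    a <- drop(crossprod(sv$u, yt))
    w <- lam * d / (1 + lam * d)
    G <- G0 - crossprod(A, A * w)
    g <- g0 - crossprod(A, w * a)
    ld <- sum(log1p(lam * d))
    yMy <- yy - sum(w * a^2)
  } else {
    G <- G0
    g <- g0
    ld <- 0
    yMy <- yy
  }
  alpha <- tryCatch(solve(G, g), error = function(e)
    vclrt_stop("X' V^{-1} X is singular (rank-deficient design)",
               "vclrt_rank_deficient"))
  qf <- yMy - sum(alpha * g)
  -0.5 * (sumlogr + n * log(sigma2) + ld + qf / sigma2)
}
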