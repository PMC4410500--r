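#' Control parameters for the PQL algorithm
#'
#' @param max_iter Maximum PQL iterations (outer loop alternating working
#'   response and working linear mixed model).
#' @param tol Convergence tolerance on the maximum absolute change in
#'   `(alpha, beta, tau2)` between iterations.
#' @param tau2_upper Upper bound of the variance-component search interval;
#'   estimates at the bound trigger a boundary warning.
#' @param mu_clip Fitted probabilities are clipped to
#'   `[mu_clip, 1 - mu_clip]` before forming working weights, so the
#'   working-response weights `1 / [mu (1 - mu)]` stay finite.
#' @param tau2_init Starting value for the variance component.
#' @param n_grid Number of log-spaced grid points used to bracket the
#'   profiled quasi-likelihood maximum over `tau2` before golden-section
#'   refinement.
#' @param reml Use the residual (REML) form of the working-model
#'   quasi log-likelihood when estimating the variance parameters inside
#'   each PQL step (the default, matching the standard linear-mixed-model
#'   machinery PQL is built on); the LRT statistic itself is always
#'   formed from the ML quasi log-likelihood surface of the converged
#'   working response.  See the methods vignette.
#'
#' @return A list of class `vclrt_control`.
#' @export
pql_control <- function(max_iter = 50L, tol = 1e-6, tau2_upper = 100,
                        mu_clip = 1e-6, tau2_init = 0.1, n_grid = 64L,
                        reml = TRUE) {
  stopifnot(tol > 0, mu_clip > 0, mu_clip < 0.5, tau2_upper > 0,
            tau2_init >= 0, max_iter >= 1, n_grid >= 8)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 tau2_upper = tau2_upper, mu_clip = mu_clip,
                 tau2_init = tau2_init, n_grid = as.integer(n_grid),
                 reml = isTRUE(reml)),
            class = "vclrt_control")
}

#' Maximum-likelihood logistic regression of y on X
#'
#' The null model (no SNP set): ordinary logistic regression fitted by
#' iteratively reweighted least squares.  Used for PQL starting values,
#' for the parametric-bootstrap null, and as the null fit of the score
#' test.
#'
#' @param y Binary response vector.
#' @param X Covariate matrix with intercept column.
#' @param control A [pql_control()] list (only `max_iter`, `tol` and
#'   `mu_clip` are used here).
#'
#' @return A list with `alpha_hat` (coefficients), `mu` (fitted
#'   probabilities, clipped to `[mu_clip, 1 - mu_clip]`) and `converged`.
#'   Perfect separation or a degenerate response raises an error of class
#'   `vclrt_separation`; non-convergence signals a warning of class
#'   `vclrt_nonconvergence` and returns the last iterate.
#' @export
logistic_irls <- function(y, X, control = pql_control()) {
  y <- as.numeric(y)
  if (all(y == 0) || all(y == 1))
    vclrt_stop("response is all one class: logistic MLE does not exist",
               "vclrt_separation")
  X <- as.matrix(X)
  separated <- FALSE
  fit <- withCallingHandlers(
    glm.fit(X, y, family = binomial(),
            control = glm.control(epsilon = min(control$tol, 1e-8),
                                  maxit = control$max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separated || fit$boundary)
    vclrt_warn("(quasi-)separation detected: fitted probabilities at 0/1",
               "vclrt_separation")
  if (!fit$converged)
    vclrt_warn("logistic IRLS did not converge; returning last iterate",
               "vclrt_nonconvergence")
  mu <- pmin(pmax(fit$fitted.values, control$mu_clip), 1 - control$mu_clip)
  list(alpha_hat = unname(fit$coefficients), mu = as.numeric(mu),
       converged = fit$converged)
}

#' Fit the logistic mixed model by penalized quasi-likelihood
#'
#' Fits `logit(mu) = X alpha + Z beta`, `beta_k ~ N(0, tau2)` by the PQL
#' algorithm: each iteration linearizes the model around the current
#' estimates, forming the working response
#' `Y' = eta + (y - mu) / [mu (1 - mu)]` and weight matrix
#' `R = diag(1 / [mu (1 - mu)])`, then fits the working linear mixed
#' model `Y' = X alpha + Z beta + e`, `beta ~ N(0, tau2 I)`,
#' `e ~ N(0, sigma2 R)` by profiled maximization of its quasi
#' log-likelihood over the variance parameters (the residual scale
#' `sigma2` is estimated alongside `tau2`, as in the standard
#' linear-mixed-model machinery), with the fixed effects profiled out by
#' generalized least squares and `beta` set to its BLUP.  Iteration
#' stops when the maximum absolute change in `(alpha, beta, tau2)` drops
#' below `control$tol`.
#'
#' The returned fit carries both the maximized ML quasi log-likelihood
#' (`loglik_alt`, the sup over `tau2 >= 0` with `sigma2` free) and its
#' value at `tau2 = 0` (`sigma2` again free), both evaluated with the
#' same converged working response and weights — the ingredients of the
#' variance-component likelihood ratio statistic (see
#' [lrt_statistic()]).
#'
#' @param data A [design_data()] object with `K >= 1` SNP columns.
#' @param control A [pql_control()] list.
#'
#' @return An object of class `vclrt_pql` with elements `alpha_hat`,
#'   `beta_hat` (BLUPs), `tau2_hat`, `sigma2_hat`, `mu`,
#'   `working_response`, `r_diag`, `loglik_alt`, `loglik_null`,
#'   `converged`, `n_iter`, and the `data` dimensions.
#' @examples
#' set.seed(7)
#' d <- simulate_sim1(n = 200, K = 5, tau2 = 0.2)
#' fit <- pql_fit(d)
#' glance(fit)
#' @export
pql_fit <- function(data, control = pql_control()) {
  data <- as_design(data)
  if (data$K < 1)
    vclrt_stop("mixed-model fitting needs at least one SNP column (K >= 1)",
               "vclrt_no_snps")
  init <- suppressWarnings(logistic_irls(data$y, data$X, control))
  f <- pql_fit_cpp(data$y, data$X, data$Z, init$alpha_hat,
                   control$tau2_init, control$tol, control$max_iter,
                   control$tau2_upper, control$mu_clip, control$n_grid,
                   control$reml)
  if (!f$converged)
    vclrt_warn(sprintf("PQL did not converge in %d iterations; returning last iterate",
                       control$max_iter), "vclrt_nonconvergence")
  if (f$boundary)
    vclrt_warn(sprintf("tau2 estimate at the search bound tau2_upper = %g",
                       control$tau2_upper), "vclrt_boundary")
  structure(list(alpha_hat = as.numeric(f$alpha_hat),
                 beta_hat = as.numeric(f$beta_hat),
                 tau2_hat = f$tau2_hat,
                 sigma2_hat = f$sigma2_hat,
                 mu = as.numeric(f$mu),
                 working_response = as.numeric(f$working_response),
                 r_diag = as.numeric(f$r_diag),
                 loglik_alt = f$loglik_alt,
                 loglik_null = f$loglik_null,
                 converged = f$converged,
                 n_iter = f$n_iter,
                 boundary = f$boundary,
                 n = data$n, p = data$p, K = data$K,
                 data = data, control = control),
            class = "vclrt_pql")
}

#' @export
print.vclrt_pql <- function(x, ...) {
  cat(sprintf("<vclrt_pql> n = %d, K = %d | tau2_hat = %.5f | %s in %d iterations\n",
              x$n, x$K, x$tau2_hat,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}
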