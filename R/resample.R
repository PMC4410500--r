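#' Resample a dataset under the null of no SNP-set effect
#'
#' Permutation mode applies one uniformly random permutation of row
#' indices jointly to `y` and the rows of `X`, leaving `Z` untouched
#' (valid when `X` and `Z` are uncorrelated).  Bootstrap mode redraws
#' `y*_i ~ Bernoulli(null_mu_i)` from the fitted null logistic model,
#' leaving both `X` and `Z` untouched.
#'
#' @param data A [design_data()] object.
#' @param mode `"permutation"` or `"bootstrap"`.
#' @param null_mu Fitted null probabilities (required for bootstrap mode;
#'   see [logistic_irls()]).
#' @return A new `vclrt_design`.
#' @export
resample_dataset <- function(data, mode = c("permutation", "bootstrap"),
                             null_mu = NULL) {
  data <- as_design(data)
  mode <- match.arg(mode)
  if (mode == "permutation") {
    idx <- sample.int(data$n)
    design_data(data$y[idx], data$X[idx, , drop = FALSE], data$Z)
  } else {
    if (is.null(null_mu))
      vclrt_stop("bootstrap mode needs null_mu from the null logistic fit",
                 "vclrt_invalid_input")
    repeat {
      ystar <- rbinom(data$n, 1, null_mu)
      if (any(ystar == 0) && any(ystar == 1)) break
    }
    design_data(ystar, data$X, data$Z)
  }
}

#' Permutation (or parametric-bootstrap) variance-component LRT
#'
#' The resampling null distribution of the LRT statistic `T`:
#' 1. compute the observed `T_obs` by a full PQL fit of the original data;
#' 2. resample the dataset under the null (jointly permute `(y, X)`
#'    against fixed `Z`, or redraw `y` from the fitted null logistic
#'    model);
#' 3. refit the full PQL alternative model from cold start on the
#'    resampled data and record its statistic `T*_b`;
#' 4. repeat `B` times;
#' 5. the Monte-Carlo p-value is the proportion of `T*_b` equal to or
#'    greater than `T_obs`.
#'
#' An add-one estimate `(# + 1) / (B + 1)` is reported as a secondary
#' field.  Resampled refits that fail to converge contribute their
#' last-iterate statistic (with a warning); if every refit fails the test
#' aborts.
#'
#' @param data A [design_data()] object with `K >= 1`.
#' @param B Number of resamples (default 1000; 200-500 is often adequate
#'   at the 0.05 level).
#' @param mode `"permutation"` (default) or `"bootstrap"`.
#' @param control A [pql_control()] list.
#' @param seed Optional integer seed for the resampling stream.
#' @param fit Optional precomputed [pql_fit()] of `data`, to avoid
#'   refitting the observed model.
#'
#' @return An object of class `vclrt_perm` with `T_obs`, `T_null`
#'   (length `B`), `B`, `p_value` (plain proportion, ties counted),
#'   `p_value_add_one`, `mode`, `n_nonconverged`, `seed`, and the
#'   observed-fit `lrt` (mixture p-values).
#' @examples
#' set.seed(11)
#' d <- simulate_sim1(n = 150, K = 5, tau2 = 0.3)
#' permutation_test(d, B = 50)
#' @export
permutation_test <- function(data, B = 1000L,
                             mode = c("permutation", "bootstrap"),
                             control = pql_control(), seed = NULL,
                             fit = NULL) {
  data <- as_design(data)
  mode <- match.arg(mode)
  B <- as.integer(B)
  if (B < 1)
    vclrt_stop("B must be a positive integer", "vclrt_invalid_input")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(fit)) fit <- pql_fit(data, control)
  lrt <- lrt_statistic(fit)

  # resampling matrix drawn on the R side so the RNG stream is plain R
  resample <- matrix(0, B, data$n)
  if (mode == "permutation") {
    for (b in seq_len(B)) resample[b, ] <- sample.int(data$n)
  } else {
    null_mu <- suppressWarnings(logistic_irls(data$y, data$X, control))$mu
    for (b in seq_len(B)) resample[b, ] <- rbinom(data$n, 1, null_mu)
    degenerate <- rowSums(resample) %in% c(0, data$n)
    while (any(degenerate)) {
      for (b in which(degenerate)) resample[b, ] <- rbinom(data$n, 1, null_mu)
      degenerate <- rowSums(resample) %in% c(0, data$n)
    }
  }
  res <- perm_lrt_cpp(data$y, data$X, data$Z, resample, mode,
                      control$tau2_init, control$tol, control$max_iter,
                      control$tau2_upper, control$mu_clip, control$n_grid,
                      control$reml)
  if (res$n_nonconverged >= B)
    vclrt_stop("no resampled PQL refit converged", "vclrt_all_nonconverged")
  if (res$n_nonconverged > 0)
    vclrt_warn(sprintf("%d of %d resampled refits did not converge; their last-iterate statistics were kept",
                       res$n_nonconverged, B), "vclrt_nonconvergence")
  n_ge <- sum(res$T_null >= lrt$T)
  structure(list(T_obs = lrt$T, T_null = as.numeric(res$T_null), B = B,
                 p_value = n_ge / B,
                 p_value_add_one = (n_ge + 1) / (B + 1),
                 mode = mode, n_nonconverged = res$n_nonconverged,
                 seed = seed, lrt = lrt, tau2_hat = fit$tau2_hat),
            class = "vclrt_perm")
}

#' @export
print.vclrt_perm <- function(x, ...) {
  cat(sprintf("<vclrt_perm> %s test, B = %d | T_obs = %.4f | p = %.4g (add-one %.4g)\n",
              x$mode, x$B, x$T_obs, x$p_value, x$p_value_add_one))
  invisible(x)
}
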