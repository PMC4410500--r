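#' Tidy a PQL fit into one row per model term
#'
#' Fixed effects first (`effect = "fixed"`), then the SNP BLUPs
#' (`effect = "random"`).
#'
#' @param x A [pql_fit()] object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `effect`, `estimate`.
#' @export
tidy.vclrt_pql <- function(x, ...) {
  xn <- colnames(x$data$X) %||% paste0("x", seq_along(x$alpha_hat))
  zn <- colnames(x$data$Z) %||% paste0("snp", seq_along(x$beta_hat))
  tibble::tibble(term = c(xn, zn),
                 effect = rep(c("fixed", "random"),
                              c(length(x$alpha_hat), length(x$beta_hat))),
                 estimate = c(x$alpha_hat, x$beta_hat))
}

#' One-row model summary of a PQL fit
#'
#' @param x A [pql_fit()] object.
#' @param ... Unused.
#' @return A one-row tibble: `tau2_hat`, `sigma2_hat`, `loglik_alt`,
#'   `loglik_null`, `n_iter`, `converged`, `n`, `K`.
#' @export
glance.vclrt_pql <- function(x, ...) {
  tibble::tibble(tau2_hat = x$tau2_hat, sigma2_hat = x$sigma2_hat,
                 loglik_alt = x$loglik_alt,
                 loglik_null = x$loglik_null, n_iter = x$n_iter,
                 converged = x$converged, n = x$n, K = x$K)
}

#' @export
tidy.vclrt_lrt <- function(x, ...) {
  tibble::tibble(statistic = x$T, tau2_hat = x$tau2_hat,
                 p_mix_50 = x$p_mix_50, p_mix_65 = x$p_mix_65)
}

#' @export
tidy.vclrt_perm <- function(x, ...) {
  tibble::tibble(statistic = x$T_obs, p_value = x$p_value,
                 p_value_add_one = x$p_value_add_one, B = x$B,
                 mode = x$mode, n_nonconverged = x$n_nonconverged)
}

#' @export
tidy.vclrt_score <- function(x, ...) {
  tibble::tibble(statistic = x$Q, p_value = x$p_value, method = x$method,
                 n_eigenvalues = length(x$lambdas))
}

#' Power / type-I-error curves from a rejection table
#'
#' Plots the rejection proportion (with a pointwise normal-approximation
#' Monte-Carlo error band) against sample size, one line per method.
#'
#' @param object A `vclrt_rejection` tibble (possibly several
#'   [run_type1()]/[run_power()] results bound together).
#' @param x_var Column mapped to the x axis (default `"n"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vclrt_rejection <- function(object, x_var = "n", ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[x_var]], y = .data$proportion,
                                   colour = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$proportion - 2 * .data$se, 0),
                                      ymax = pmin(.data$proportion + 2 * .data$se, 1),
                                      fill = .data$method),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = x_var, y = "rejection proportion", colour = "method",
                  fill = "method") +
    ggplot2::theme_minimal()
}
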