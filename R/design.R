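#' Bundle a case-control dataset for SNP-set testing
#'
#' Collects the binary response `y`, the fixed-effects covariate matrix `X`
#' (first column an intercept of ones) and the genotype dosage matrix `Z`
#' (samples by SNPs, additive 0/1/2 coding, though general reals are
#' accepted) into a validated design object consumed by [pql_fit()],
#' [permutation_test()] and [score_statistic()].
#'
#' @param y Binary response vector (0 = control, 1 = case); both classes
#'   must be present.
#' @param X Covariate matrix `n x (p+1)` with an all-ones first column, or
#'   `NULL` for an intercept-only design.  Must have full column rank.
#' @param Z Dosage matrix `n x K`.  `K = 0` (zero-column matrix) is allowed
#'   at construction time; mixed-model fitting requires `K >= 1`.
#'
#' @return An object of class `vclrt_design`: a list with elements `y`,
#'   `X`, `Z`, `n`, `p`, `K`.
#' @examples
#' set.seed(1)
#' d <- simulate_sim1(n = 100, K = 5)
#' d$n; d$K
#' @export
design_data <- function(y, X = NULL, Z = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (!all(y %in% c(0, 1)))
    vclrt_stop("y must contain only 0/1 values", "vclrt_invalid_design")
  if (all(y == 0) || all(y == 1))
    vclrt_stop("y must contain both cases and controls", "vclrt_invalid_design")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n)
    vclrt_stop("nrow(X) must equal length(y)", "vclrt_invalid_design")
  if (any(X[, 1] != 1))
    vclrt_stop("first column of X must be an all-ones intercept",
               "vclrt_invalid_design")
  if (qr(X)$rank < ncol(X))
    vclrt_stop("X is rank deficient", "vclrt_invalid_design")
  if (is.null(Z)) Z <- matrix(0, n, 0)
  Z <- as.matrix(Z)
  if (nrow(Z) != n)
    vclrt_stop("nrow(Z) must equal length(y)", "vclrt_invalid_design")
  structure(list(y = y, X = X, Z = Z, n = n, p = ncol(X) - 1L,
                 K = ncol(Z)),
            class = "vclrt_design")
}

#' @export
print.vclrt_design <- function(x, ...) {
  cat(sprintf("<vclrt_design> n = %d (%d cases), p + 1 = %d covariates, K = %d SNPs\n",
              x$n, sum(x$y), x$p + 1L, x$K))
  invisible(x)
}

as_design <- function(data) {
  if (inherits(data, "vclrt_design")) return(data)
  if (is.list(data) && all(c("y", "X", "Z") %in% names(data)))
    return(design_data(data$y, data$X, data$Z))
  vclrt_stop("expected a vclrt_design (see design_data())", "vclrt_invalid_design")
}
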