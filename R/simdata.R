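#' Correlated additive genotypes from a latent thresholded Gaussian
#'
#' Draws latent rows `G` from a multivariate normal with unit variances
#' and AR-type correlation `rho^|k - k'|` (generated by the exact
#' recursion `G_k = rho G_{k-1} + sqrt(1 - rho^2) eps_k`, O(nK)), then
#' codes dosages `Z = 0` if `G < -c`, `1` if `-c <= G <= c`, `2` if
#' `G > c`.  With `c` the standard-normal third quartile the marginal
#' dosage frequencies are (0.25, 0.50, 0.25), i.e. Hardy-Weinberg with
#' minor allele frequency 0.25, and adjacent SNPs are in linkage
#' disequilibrium governed by `rho`.
#'
#' @param n Number of individuals.
#' @param K Number of SNPs.
#' @param rho Latent base correlation between adjacent SNPs.
#' @param c Threshold; defaults to `qnorm(0.75)`.
#' @return An `n x K` matrix with entries in `{0, 1, 2}`.
#' @export
gen_genotypes_ar <- function(n, K, rho = 0.5, c = qnorm(0.75)) {
  stopifnot(n >= 1, K >= 1, rho > 0, rho < 1)
  G <- matrix(rnorm(n * K), n, K)
  if (K > 1)
    for (k in 2:K) G[, k] <- rho * G[, k - 1] + sqrt(1 - rho^2) * G[, k]
  Z <- (G > -c) + (G > c)
  storage.mode(Z) <- "double"
  colnames(Z) <- paste0("snp", seq_len(K))
  Z
}

#' Simulation covariates: intercept, binary X1, standard-normal X2
#'
#' @param n Number of individuals.
#' @return An `n x 3` matrix with columns `(Intercept)` (all ones),
#'   `X1 ~ Bernoulli(0.5)` and `X2 ~ N(0, 1)`, mutually independent.
#' @export
gen_covariates <- function(n) {
  cbind(`(Intercept)` = rep(1, n), X1 = rbinom(n, 1, 0.5), X2 = rnorm(n))
}

#' Random SNP effects with a shared variance component
#'
#' Dense variant: `beta_k ~ N(0, tau2)` i.i.d. (`tau2 = 0` gives the exact
#' null, all effects zero).
#'
#' @param K Number of SNPs.
#' @param tau2 Variance component.
#' @return Numeric vector of length `K`.
#' @export
gen_effects <- function(K, tau2) {
  stopifnot(K >= 0, tau2 >= 0)
  if (tau2 == 0) return(rep(0, K))
  rnorm(K, 0, sqrt(tau2))
}

#' Sparse (non-normal) SNP effects
#'
#' Selects `m` causal SNPs uniformly at random, gives them i.i.d.
#' `U[low, high]` effects, and sets the rest exactly to zero.  `m = 0`
#' reproduces the exact null.
#'
#' @param K Number of SNPs.
#' @param m Number of causal SNPs (`0 <= m <= K`).
#' @param low,high Uniform effect bounds.
#' @return Numeric vector of length `K`.
#' @export
gen_effects_sparse <- function(K, m, low = 0.60, high = 1.10) {
  stopifnot(K >= 0, m >= 0, m <= K, low <= high)
  beta <- rep(0, K)
  if (m > 0) beta[sample.int(K, m)] <- runif(m, low, high)
  beta
}

#' Binary phenotypes from the logistic model
#'
#' `y_i ~ Bernoulli(expit(x_i' alpha + z_i' beta))` independently.  The
#' default fixed effects `alpha = (-1, -0.5, -0.5)` give the study's
#' baseline `logit(mu) = -(1 + 0.5 X1 + 0.5 X2) + z' beta`.
#'
#' @param X Covariate matrix (columns matching `alpha`).
#' @param Z Dosage matrix (may have zero columns).
#' @param beta SNP effects (length `ncol(Z)`).
#' @param alpha Fixed-effect coefficients.
#' @return Binary vector of length `nrow(X)`.
#' @export
gen_phenotype <- function(X, Z, beta, alpha = c(-1, -0.5, -0.5)) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(alpha))
  eta <- drop(X %*% alpha)
  if (!is.null(Z) && ncol(as.matrix(Z)) > 0) {
    Z <- as.matrix(Z)
    stopifnot(ncol(Z) == length(beta), nrow(Z) == nrow(X))
    eta <- eta + drop(Z %*% beta)
  }
  rbinom(nrow(X), 1, plogis(eta))
}

#' Haplotype-pool genotypes with tunable LD (coalescent stand-in)
#'
#' A configurable generator for genotypes with arbitrary per-site allele
#' frequencies and neighbor-dependent LD, used where a population-genetic
#' simulator would otherwise supply haplotypes.  A pool of
#' `2 * pool_size` haplotypes is built by a Markov copying process on a
#' latent uniform: site 1 uses a fresh `U(0, 1)` draw; at site `k` the
#' latent uniform is copied from site `k - 1` with probability `ld_decay`
#' and redrawn otherwise, and the allele is `1` when the latent uniform is
#' below `maf_k`.  Marginal allele frequencies are therefore exactly
#' `maf`, while inter-site dosage correlation decays like
#' `ld_decay^|k - k'|` (`ld_decay = 0` gives independent sites).
#' Individuals are formed by sampling two haplotypes from the pool with
#' replacement and summing.
#'
#' @param n Number of individuals.
#' @param K Number of SNPs.
#' @param maf Per-site minor allele frequencies in `(0, 0.5]` (recycled).
#' @param ld_decay Copying probability in `[0, 1)`.
#' @param pool_size Number of diploid founders in the pool.
#' @return An `n x K` dosage matrix with entries in `{0, 1, 2}`.
#' @export
gen_haplotype_pool <- function(n, K, maf, ld_decay = 0.8, pool_size = 500) {
  maf <- rep_len(as.numeric(maf), K)
  stopifnot(all(maf > 0), all(maf <= 0.5), ld_decay >= 0, ld_decay < 1,
            n >= 1, K >= 1, pool_size >= 2)
  H <- matrix(0L, 2L * pool_size, K)
  u <- runif(2L * pool_size)
  H[, 1] <- as.integer(u < maf[1])
  if (K > 1) {
    for (k in 2:K) {
      redraw <- runif(2L * pool_size) >= ld_decay
      u[redraw] <- runif(sum(redraw))
      H[, k] <- as.integer(u < maf[k])
    }
  }
  i1 <- sample.int(2L * pool_size, n, replace = TRUE)
  i2 <- sample.int(2L * pool_size, n, replace = TRUE)
  Z <- H[i1, , drop = FALSE] + H[i2, , drop = FALSE]
  storage.mode(Z) <- "double"
  colnames(Z) <- paste0("snp", seq_len(K))
  Z
}

#' Simulate one dataset under the correlated-genotype design
#'
#' The first simulation design end to end: AR-correlated thresholded
#' genotypes ([gen_genotypes_ar()]), covariates ([gen_covariates()]),
#' normal SNP effects `beta_k ~ N(0, tau2)` and logistic phenotypes with
#' baseline `-(1 + 0.5 X1 + 0.5 X2)`.  `tau2 = 0` is the exact null, so
#' type-I-error and power studies share this one code path.
#'
#' @param n Sample size.
#' @param K Number of SNPs.
#' @param tau2 Variance component of the SNP effects.
#' @param rho Latent adjacent-SNP correlation.
#' @param alpha Fixed-effect coefficients for `(1, X1, X2)`.
#' @return A [design_data()] object.
#' @examples
#' set.seed(1)
#' simulate_sim1(n = 200, K = 10, tau2 = 0.15)
#' @export
simulate_sim1 <- function(n, K, tau2 = 0, rho = 0.5,
                          alpha = c(-1, -0.5, -0.5)) {
  X <- gen_covariates(n)
  Z <- gen_genotypes_ar(n, K, rho)
  beta <- gen_effects(K, tau2)
  repeat {
    y <- gen_phenotype(X, Z, beta, alpha)
    if (any(y == 0) && any(y == 1)) break
  }
  design_data(y, X, Z)
}

#' Simulate one dataset with sparse uniform effects (non-normal design)
#'
#' The second simulation design with the haplotype-pool generator standing
#' in for coalescent genotypes: only `m` of the `K` SNPs are causal, with
#' effects drawn `U[low, high]` (so the random effects are not normally
#' distributed).  `m = 0` is the exact null.
#'
#' @param n Sample size.
#' @param K Number of SNPs.
#' @param m Number of causal SNPs.
#' @param maf Per-site minor allele frequencies (recycled).
#' @param ld_decay Haplotype copying probability (LD range).
#' @param low,high Uniform effect bounds.
#' @param alpha Fixed-effect coefficients for `(1, X1, X2)`.
#' @return A [design_data()] object.
#' @export
simulate_sim2_standin <- function(n, K, m = 0, maf = 0.25, ld_decay = 0.8,
                                  low = 0.60, high = 1.10,
                                  alpha = c(-1, -0.5, -0.5)) {
  X <- gen_covariates(n)
  Z <- gen_haplotype_pool(n, K, maf, ld_decay)
  beta <- gen_effects_sparse(K, m, low, high)
  repeat {
    y <- gen_phenotype(X, Z, beta, alpha)
    if (any(y == 0) && any(y == 1)) break
  }
  design_data(y, X, Z)
}
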