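test_that("thresholded latent-AR genotypes have quartile-determined dosage frequencies", {
  set.seed(101)
  Z <- gen_genotypes_ar(1e5, 4)
  expect_true(all(Z %in% c(0, 1, 2)))
  # c = standard-normal third quartile => marginal masses (0.25, 0.50, 0.25)
  for (k in 1:4) {
    f <- tabulate(Z[, k] + 1, 3) / 1e5
    se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / 1e5)
    expect_true(all(abs(f - c(0.25, 0.50, 0.25)) < 3 * se))
  }
})

test_that("adjacent dosage columns match the bivariate-normal threshold oracle", {
  set.seed(102)
  Z <- gen_genotypes_ar(1e5, 2, rho = 0.5)
  r_emp <- cor(Z[, 1], Z[, 2])
  # oracle: threshold two correlated normals directly, 1e6 draws
  g1 <- rnorm(1e6)
  g2 <- 0.5 * g1 + sqrt(1 - 0.25) * rnorm(1e6)
  c0 <- qnorm(0.75)
  z1 <- (g1 > -c0) + (g1 > c0)
  z2 <- (g2 > -c0) + (g2 > c0)
  expect_lt(abs(r_emp - cor(z1, z2)), 0.01)
})

test_that("covariates are intercept, Bernoulli(0.5) and standard normal", {
  set.seed(103)
  X <- gen_covariates(1e5)
  expect_true(all(X[, 1] == 1))
  expect_lt(abs(mean(X[, 2]) - 0.5), 3 * sqrt(0.25 / 1e5))
  # sample variance of N(0,1): SE ~ sqrt(2/n)
  expect_lt(abs(var(X[, 3]) - 1), 3 * sqrt(2 / 1e5))
})

test_that("effect generators honour their null and support contracts", {
  set.seed(104)
  expect_identical(gen_effects(10, 0), rep(0, 10))
  expect_identical(gen_effects_sparse(10, 0), rep(0, 10))
  b <- gen_effects_sparse(8, 8)
  expect_true(all(b >= 0.60 & b <= 1.10))
  b2 <- gen_effects_sparse(10, 3)
  expect_equal(sum(b2 != 0), 3)
  expect_true(all(b2[b2 != 0] >= 0.60 & b2[b2 != 0] <= 1.10))
})

test_that("phenotype generator matches the inverse-logit law", {
  set.seed(105)
  X <- cbind(1, rep(0, 1e5), rep(0, 1e5))
  y <- gen_phenotype(X, NULL, numeric(0))
  expect_true(all(y %in% c(0, 1)))
  p0 <- plogis(-1)
  expect_lt(abs(mean(y) - p0), 3 * sqrt(p0 * (1 - p0) / 1e5))

  # marginal case fraction with random covariates vs numeric integration
  X2 <- gen_covariates(1e5)
  y2 <- gen_phenotype(X2, NULL, numeric(0))
  integrand <- function(x2) plogis(-1 - 0.5 * x2) * dnorm(x2)
  integrand1 <- function(x2) plogis(-1.5 - 0.5 * x2) * dnorm(x2)
  pbar <- 0.5 * integrate(integrand, -Inf, Inf)$value +
    0.5 * integrate(integrand1, -Inf, Inf)$value
  expect_lt(abs(mean(y2) - pbar), 3 * sqrt(pbar * (1 - pbar) / 1e5))
})

test_that("haplotype-pool genotypes hit their allele frequencies and LD limits", {
  set.seed(106)
  maf <- c(0.1, 0.25, 0.4)
  Z <- gen_haplotype_pool(2e4, 3, maf, ld_decay = 0.5, pool_size = 5000)
  expect_true(all(Z %in% c(0, 1, 2)))
  freq <- colMeans(Z) / 2
  # two sampling levels: the finite haplotype pool and the draws from it
  se <- sqrt(maf * (1 - maf) * (1 / 1e4 + 1 / (2 * 2e4)))
  expect_true(all(abs(freq - maf) < 3 * se))

  Z0 <- gen_haplotype_pool(1e5, 4, 0.3, ld_decay = 0, pool_size = 5000)
  cors <- cor(Z0)
  expect_true(all(abs(cors[upper.tri(cors)]) < 0.02))
})

test_that("generators are pure functions of the seed", {
  set.seed(107)
  d1 <- simulate_sim1(n = 50, K = 4, tau2 = 0.2)
  set.seed(107)
  d2 <- simulate_sim1(n = 50, K = 4, tau2 = 0.2)
  expect_identical(d1, d2)

  set.seed(108)
  s1 <- simulate_sim2_standin(n = 50, K = 6, m = 3)
  set.seed(108)
  s2 <- simulate_sim2_standin(n = 50, K = 6, m = 3)
  expect_identical(s1, s2)
})
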