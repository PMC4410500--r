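test_that("logistic IRLS reduces to the logit of the sample mean and matches a Newton oracle", {
  y <- rep(c(0, 1), each = 20)
  X <- matrix(1, 40, 1)
  f <- logistic_irls(y, X)
  expect_equal(f$alpha_hat, 0, tolerance = 1e-10)
  expect_equal(f$mu, rep(0.5, 40), tolerance = 1e-10)

  set.seed(11)
  d <- simulate_sim1(n = 400, K = 3, tau2 = 0)
  f2 <- logistic_irls(d$y, d$X)
  expect_equal(f2$alpha_hat, unname(oracle_logistic_nr(d$y, d$X)),
               tolerance = 1e-8)
})

test_that("degenerate responses raise a separation signal", {
  X <- cbind(1, rnorm(10))
  expect_error(logistic_irls(rep(1, 10), X), class = "vclrt_separation")
  expect_error(logistic_irls(rep(0, 10), X), class = "vclrt_separation")
  # perfectly separating covariate
  y <- rep(c(0, 1), each = 10)
  Xs <- cbind(1, c(rnorm(10, -8), rnorm(10, 8)))
  expect_warning(logistic_irls(y, Xs), class = "vclrt_separation")
})

test_that("PQL with the variance component pinned at zero reduces to ordinary logistic regression", {
  set.seed(12)
  d <- simulate_sim1(n = 200, K = 5, tau2 = 0)
  ctrl <- pql_control(tau2_upper = 1e-12, tau2_init = 0)
  fit <- suppressWarnings(pql_fit(d, ctrl))
  irls <- logistic_irls(d$y, d$X)
  expect_equal(fit$alpha_hat, irls$alpha_hat, tolerance = 1e-6)
  expect_lt(fit$tau2_hat, 1e-10)
})

test_that("the converged tau2 matches a dense-grid plus golden-section oracle", {
  set.seed(13)
  d <- simulate_sim1(n = 200, K = 5, tau2 = 0.2)
  fit <- pql_fit(d)
  expect_true(fit$converged)
  prof <- fit_profile_ll(fit)
  # search the oracle on a window generous around the estimate
  upper <- max(1, 4 * fit$tau2_hat)
  oracle <- oracle_grid_golden_max(prof, upper, n_grid = 1000)
  expect_equal(fit$tau2_hat, oracle$argmax, tolerance = 1e-5)
  expect_equal(fit$loglik_alt, oracle$max, tolerance = 1e-7)
})

test_that("mean tau2 estimates increase with the true variance component", {
  set.seed(14)
  taus <- c(0.1, 0.2, 0.4)
  means <- vapply(taus, function(tau2) {
    est <- replicate(60, {
      d <- simulate_sim1(n = 400, K = 20, tau2 = tau2)
      suppressWarnings(pql_fit(d))$tau2_hat
    })
    mean(est)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("converged fits satisfy the PQL invariants", {
  set.seed(15)
  for (tau2 in c(0, 0.3)) {
    d <- simulate_sim1(n = 150, K = 8, tau2 = tau2)
    fit <- suppressWarnings(pql_fit(d))
    expect_gte(fit$loglik_alt, fit$loglik_null)
    expect_gte(fit$tau2_hat, 0)
    mc <- fit$control$mu_clip
    expect_true(all(fit$mu >= mc & fit$mu <= 1 - mc))
    expect_equal(fit$r_diag, 1 / (fit$mu * (1 - fit$mu)))
  }
})

test_that("the efficient GLS path agrees with dense matrix inversion on small instances", {
  set.seed(16)
  for (i in 1:5) {
    d <- simulate_sim1(n = 50, K = 4, tau2 = 0.3)
    fit <- suppressWarnings(pql_fit(d, pql_control(reml = FALSE)))
    # GLS alpha depends on the variances only through the ratio tau2/sigma2
    a_dense <- oracle_gls_alpha_dense(fit$working_response, d$X, d$Z,
                                      fit$r_diag,
                                      fit$tau2_hat / fit$sigma2_hat)
    expect_equal(fit$alpha_hat, a_dense, tolerance = 1e-8)
  }
})

test_that("an all-zero Z makes the quasi log-likelihood constant in tau2", {
  set.seed(17)
  d <- simulate_sim1(n = 80, K = 3, tau2 = 0)
  fit <- suppressWarnings(pql_fit(d))
  Z0 <- matrix(0, d$n, 3)
  vals <- vapply(c(0, 0.5, 2, 50), function(t2)
    quasi_loglik(fit$working_response, d$X, Z0, fit$r_diag, t2), numeric(1))
  expect_true(all(abs(vals - vals[1]) < 1e-12))
  expect_equal(vals[1],
               quasi_loglik(fit$working_response, d$X, Z0, fit$r_diag, 0))
})
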