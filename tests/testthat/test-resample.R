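test_that("permutation resampling permutes (y, X) jointly and keeps Z fixed", {
  set.seed(41)
  d <- simulate_sim1(n = 60, K = 4, tau2 = 0)
  set.seed(99)
  r <- resample_dataset(d, "permutation")
  set.seed(99)
  idx <- sample.int(d$n)  # reproduce the drawn permutation
  expect_identical(r$y, d$y[idx])
  expect_identical(r$X, d$X[idx, , drop = FALSE])
  expect_identical(r$Z, d$Z)
  # multisets preserved; pairing of y with X rows preserved
  expect_identical(sort(r$y), sort(d$y))
  key0 <- paste(d$y, apply(d$X, 1, paste, collapse = ","))
  key1 <- paste(r$y, apply(r$X, 1, paste, collapse = ","))
  expect_identical(sort(key0), sort(key1))
  # identity permutation reproduces the input exactly
  r_id <- r
  r_id$y[idx] <- r$y; r_id$X[idx, ] <- r$X
  expect_identical(r_id$y, d$y)
  expect_identical(r_id$X, d$X)
})

test_that("bootstrap resampling redraws y from the null fitted probabilities", {
  set.seed(42)
  d <- simulate_sim1(n = 1e5, K = 1, tau2 = 0)
  mu <- rep(0.5, d$n)
  r <- resample_dataset(d, "bootstrap", null_mu = mu)
  expect_identical(r$X, d$X)
  expect_identical(r$Z, d$Z)
  expect_lt(abs(mean(r$y) - 0.5), 3 * sqrt(0.25 / d$n))
  expect_error(resample_dataset(d, "bootstrap"), class = "vclrt_invalid_input")
})

test_that("the Monte-Carlo p-value is the tie-inclusive proportion with an add-one variant", {
  set.seed(43)
  d <- simulate_sim1(n = 120, K = 4, tau2 = 0.4)
  pt <- permutation_test(d, B = 40, seed = 7)
  expect_length(pt$T_null, 40)
  expect_identical(pt$p_value, sum(pt$T_null >= pt$T_obs) / 40)
  expect_identical(pt$p_value_add_one,
                   (sum(pt$T_null >= pt$T_obs) + 1) / 41)
  # counting rule on a fixed null sample: ties counted as "greater or equal"
  T_null <- c(1.2, 3.4, 0.5, 2.2)
  expect_identical(sum(T_null >= 2.2) / 4, 0.5)
  # monotone, step-function behaviour of the proportion rule
  ps <- vapply(c(0, 0.5, 1.2, 2.2, 3.4, 10),
               function(t) sum(pt$T_null >= t) / 40, numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_identical(sum(pt$T_null >= max(pt$T_null) + 1) / 40, 0)
  expect_error(permutation_test(d, B = 0), class = "vclrt_invalid_input")
})

test_that("the permutation test is reproducible under a fixed seed", {
  set.seed(44)
  d <- simulate_sim1(n = 100, K = 5, tau2 = 0.3)
  p1 <- permutation_test(d, B = 30, seed = 5)
  p2 <- permutation_test(d, B = 30, seed = 5)
  expect_identical(p1$T_null, p2$T_null)
  expect_identical(p1$p_value, p2$p_value)
  p3 <- permutation_test(d, B = 30, seed = 6)
  expect_false(identical(p1$T_null, p3$T_null))
})

test_that("bootstrap mode runs and agrees qualitatively with permutation mode", {
  set.seed(45)
  d <- simulate_sim1(n = 120, K = 4, tau2 = 0)
  pp <- permutation_test(d, B = 60, seed = 1)
  pb <- permutation_test(d, B = 60, mode = "bootstrap", seed = 1)
  expect_identical(pb$mode, "bootstrap")
  # same observed statistic, null distributions on a comparable scale
  expect_identical(pp$T_obs, pb$T_obs)
})
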