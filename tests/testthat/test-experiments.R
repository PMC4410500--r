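test_that("run_dataset reports one tidy row per requested method from a single PQL fit", {
  set.seed(51)
  d <- simulate_sim1(n = 150, K = 5, tau2 = 0.3)
  res <- run_dataset(d, methods = c("permutation", "score", "mixture50",
                                    "mixture65"), B = 40, seed = 3)
  expect_s3_class(res, "tbl_df")
  expect_setequal(res$method, c("permutation", "score", "mixture50",
                                "mixture65"))
  # the three LRT-family rows share the statistic of the one PQL fit
  T_vals <- res$statistic[res$method != "score"]
  expect_true(all(T_vals == T_vals[1]))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})

test_that("run_dataset on an all-zero Z yields p = 1 for the score test", {
  set.seed(52)
  y <- c(0, 1, rbinom(48, 1, 0.4))
  d <- design_data(y, cbind(1, rnorm(50)), matrix(0, 50, 4))
  res <- suppressWarnings(run_dataset(d, methods = "score"))
  expect_identical(res$p_value, 1)
})

test_that("a 0-SNP gene falls back to the null logistic fit with a diagnostic", {
  set.seed(53)
  y <- c(0, 1, rbinom(38, 1, 0.4))
  d <- design_data(y, cbind(1, rnorm(40)), NULL)
  expect_warning(res <- run_dataset(d), class = "vclrt_no_snps")
  expect_identical(res$method, "null_logistic")
  expect_true(is.na(res$p_value))
  expect_false(is.null(attr(res, "null_fit")))
})

test_that("experiment runners are reproducible and independent of worker count", {
  t1 <- run_type1("sim1", n = 100, K = 4, n_reps = 6, B = 25,
                  methods = c("score", "mixture50"), master_seed = 9)
  t2 <- run_type1("sim1", n = 100, K = 4, n_reps = 6, B = 25,
                  methods = c("score", "mixture50"), master_seed = 9)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(attr(t1, "replicates")$p_value,
                   attr(t2, "replicates")$p_value)
  t4 <- run_type1("sim1", n = 100, K = 4, n_reps = 6, B = 25,
                  methods = c("score", "mixture50"), master_seed = 9,
                  workers = 2)
  expect_identical(attr(t1, "replicates")$p_value,
                   attr(t4, "replicates")$p_value)
})

test_that("rejection tables are exact counts with binomial standard errors", {
  tab <- run_type1("sim1", n = 100, K = 4, n_reps = 8, B = 25,
                   methods = c("score", "mixture50"),
                   alpha_levels = c(0.05, 1), master_seed = 10)
  expect_true(all(tab$proportion == tab$rejections / tab$n_reps))
  expect_equal(tab$se,
               sqrt(tab$proportion * (1 - tab$proportion) / tab$n_reps))
  # alpha = 1 rejects every replicate whose p-value is below 1; the score
  # p-value is continuous, so every score replicate rejects (the discrete
  # LRT-family p-values have an atom at exactly 1 when T = 0)
  expect_true(all(tab$proportion[tab$alpha == 1 & tab$method == "score"] == 1))
})

test_that("run_power accepts the null configuration as a type-I-error run", {
  tab <- run_power("sim1", n = 100, K = 4, tau2 = 0, n_reps = 4, B = 20,
                   methods = "score", master_seed = 11)
  expect_identical(unique(tab$tau2), 0)
  expect_true(all(tab$proportion >= 0 & tab$proportion <= 1))
})

test_that("the sparse-effect design runs end to end through the study machinery", {
  tab <- run_power("sim2", n = 100, K = 6, m = 3, n_reps = 4, B = 20,
                   methods = c("score", "mixture50"), master_seed = 12)
  expect_identical(unique(tab$m), 3)
  expect_true(all(is.finite(tab$proportion)))
})

test_that("result objects tidy into tibbles and rejection tables autoplot", {
  set.seed(54)
  d <- simulate_sim1(n = 120, K = 4, tau2 = 0.3)
  fit <- pql_fit(d)
  td <- tidy(fit)
  expect_identical(nrow(td), 3L + 4L)
  expect_setequal(unique(td$effect), c("fixed", "random"))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$tau2_hat, fit$tau2_hat)
  expect_s3_class(tidy(lrt_statistic(fit)), "tbl_df")
  expect_s3_class(tidy(score_statistic(d)), "tbl_df")
  pt <- permutation_test(d, B = 20, seed = 1)
  expect_s3_class(tidy(pt), "tbl_df")

  tab <- run_type1("sim1", n = 100, K = 4, n_reps = 4, B = 20,
                   methods = c("score", "mixture50"), master_seed = 13)
  pl <- autoplot(tab)
  expect_s3_class(pl, "ggplot")
})
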