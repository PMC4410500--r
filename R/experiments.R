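#' Run all requested association tests on one dataset
#'
#' Orchestrates the per-gene analysis: one PQL fit of the alternative
#' model supplies the LRT statistic and both chi-square-mixture p-values;
#' the same fit's statistic is the observed value of the permutation
#' test; the score test needs only the null logistic fit.  With a 0-SNP
#' gene (`K = 0`) the mixed-model tests are refused and only the null
#' logistic fit is reported, with a diagnostic.
#'
#' @param data A [design_data()] object.
#' @param methods Subset of
#'   `c("permutation", "score", "mixture50", "mixture65")`.
#' @param B Permutation resamples (used only if `"permutation"` is
#'   requested).
#' @param mode Resampling mode for the permutation method.
#' @param control A [pql_control()] list.
#' @param seed Optional seed applied before resampling.
#' @return A tibble with one row per method: `method`, `statistic`,
#'   `p_value`, `tau2_hat`, `converged`, `n_nonconverged`.  Method
#'   failures are recorded as `NA` rows, not errors.
#' @examples
#' set.seed(5)
#' d <- simulate_sim1(n = 200, K = 5, tau2 = 0.3)
#' run_dataset(d, methods = c("score", "mixture50"), B = 50)
#' @export
run_dataset <- function(data,
                        methods = c("permutation", "score", "mixture50",
                                    "mixture65"),
                        B = 1000L, mode = c("permutation", "bootstrap"),
                        control = pql_control(), seed = NULL) {
  data <- as_design(data)
  methods <- match.arg(methods, several.ok = TRUE)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)

  if (data$K == 0) {
    null_fit <- suppressWarnings(logistic_irls(data$y, data$X, control))
    vclrt_warn("gene has 0 SNPs: mixed-model tests skipped; reporting the null logistic fit only",
               "vclrt_no_snps")
    out <- tibble::tibble(method = "null_logistic", statistic = NA_real_,
                          p_value = NA_real_, tau2_hat = NA_real_,
                          converged = null_fit$converged,
                          n_nonconverged = 0L)
    attr(out, "null_fit") <- null_fit
    return(out)
  }

  rows <- list()
  needs_pql <- any(c("permutation", "mixture50", "mixture65") %in% methods)
  if (needs_pql) {
    fit <- tryCatch(suppressWarnings(pql_fit(data, control)),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      for (m in intersect(methods, c("permutation", "mixture50", "mixture65")))
        rows[[m]] <- tibble::tibble(method = m, statistic = NA_real_,
                                    p_value = NA_real_, tau2_hat = NA_real_,
                                    converged = FALSE, n_nonconverged = 0L)
    } else {
      lrt <- lrt_statistic(fit)
      if ("mixture50" %in% methods)
        rows$mixture50 <- tibble::tibble(method = "mixture50",
                                         statistic = lrt$T,
                                         p_value = lrt$p_mix_50,
                                         tau2_hat = lrt$tau2_hat,
                                         converged = fit$converged,
                                         n_nonconverged = 0L)
      if ("mixture65" %in% methods)
        rows$mixture65 <- tibble::tibble(method = "mixture65",
                                         statistic = lrt$T,
                                         p_value = lrt$p_mix_65,
                                         tau2_hat = lrt$tau2_hat,
                                         converged = fit$converged,
                                         n_nonconverged = 0L)
      if ("permutation" %in% methods) {
        pt <- tryCatch(
          suppressWarnings(permutation_test(data, B = B, mode = mode,
                                            control = control, fit = fit)),
          error = function(e) e)
        rows$permutation <- if (inherits(pt, "error")) {
          tibble::tibble(method = "permutation", statistic = lrt$T,
                         p_value = NA_real_, tau2_hat = lrt$tau2_hat,
                         converged = fit$converged, n_nonconverged = B)
        } else {
          tibble::tibble(method = "permutation", statistic = pt$T_obs,
                         p_value = pt$p_value, tau2_hat = pt$tau2_hat,
                         converged = fit$converged,
                         n_nonconverged = pt$n_nonconverged)
        }
      }
    }
  }
  if ("score" %in% methods) {
    sc <- tryCatch(suppressWarnings(score_statistic(data, control)),
                   error = function(e) e)
    rows$score <- if (inherits(sc, "error")) {
      tibble::tibble(method = "score", statistic = NA_real_,
                     p_value = NA_real_, tau2_hat = NA_real_,
                     converged = FALSE, n_nonconverged = 0L)
    } else {
      tibble::tibble(method = "score", statistic = sc$Q,
                     p_value = sc$p_value, tau2_hat = NA_real_,
                     converged = TRUE, n_nonconverged = 0L)
    }
  }
  dplyr::bind_rows(rows[intersect(methods, names(rows))])
}

# Independent, reproducible per-replicate RNG streams derived from one
# master seed (L'Ecuyer-CMRG), so results do not depend on worker count.
stream_seeds <- function(master_seed, n) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    RNGkind("Mersenne-Twister")
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(as.integer(master_seed %% 2147483647L), kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", globalenv())
  streams <- vector("list", n)
  for (b in seq_len(n)) {
    streams[[b]] <- s
    s <- parallel::nextRNGStream(s)
  }
  streams
}

run_sim_study <- function(design = c("sim1", "sim2"), n, K, tau2 = 0, m = 0,
                          n_reps = 200L, B = 1000L,
                          methods = c("permutation", "score", "mixture50",
                                      "mixture65"),
                          alpha_levels = 0.05, master_seed = 1L,
                          workers = 1L, control = pql_control(),
                          maf = 0.25, ld_decay = 0.8) {
  design <- match.arg(design)
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(n_reps >= 1, all(alpha_levels > 0), all(alpha_levels <= 1))
  streams <- stream_seeds(master_seed, n_reps)

  one_rep <- function(b) {
    assign(".Random.seed", streams[[b]], globalenv())
    d <- if (design == "sim1") simulate_sim1(n, K, tau2)
         else simulate_sim2_standin(n, K, m, maf, ld_decay)
    res <- suppressWarnings(run_dataset(d, methods = methods, B = B,
                                        control = control))
    res$rep <- b
    res
  }
  reps <- if (workers > 1) {
    parallel::mclapply(seq_len(n_reps), one_rep, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(n_reps), one_rep)
  }
  RNGkind("Mersenne-Twister")
  pvals <- dplyr::bind_rows(reps)

  grid <- tidyr::expand_grid(method = methods, alpha = alpha_levels)
  tab <- dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    mth <- grid$method[i]
    al <- grid$alpha[i]
    p <- pvals$p_value[pvals$method == mth]
    nc <- sum(pvals$n_nonconverged[pvals$method == mth] > 0)
    rej <- sum(p < al, na.rm = TRUE)
    nn <- sum(!is.na(p))
    prop <- rej / nn
    tibble::tibble(method = mth, n = n, K = K, tau2 = tau2, m = m,
                   alpha = al, n_reps = nn, rejections = rej,
                   proportion = prop,
                   se = sqrt(prop * (1 - prop) / nn),
                   n_nonconverged = nc)
  }))
  class(tab) <- c("vclrt_rejection", class(tab))
  attr(tab, "replicates") <- pvals
  attr(tab, "study") <- list(design = design, B = B,
                             master_seed = master_seed)
  tab
}

#' Monte-Carlo type-I-error study
#'
#' Draws `n_reps` fresh datasets under the exact null (`tau2 = 0` for the
#' correlated-genotype design, `m = 0` for the sparse-effect design),
#' analyses each with the requested methods, and tabulates the rejection
#' proportion at each significance level with its binomial Monte-Carlo
#' standard error.
#'
#' @param design `"sim1"` (AR-correlated thresholded genotypes, normal
#'   effects) or `"sim2"` (haplotype-pool genotypes, sparse uniform
#'   effects).
#' @param n,K Sample size and number of SNPs per replicate.
#' @param n_reps Number of simulation replicates.
#' @param B Permutation resamples per replicate.
#' @param methods Methods to run (see [run_dataset()]).
#' @param alpha_levels Significance levels.
#' @param master_seed Master seed; each replicate runs on its own RNG
#'   stream derived from it, so results are reproducible at any worker
#'   count.
#' @param workers Parallel workers (forked; 1 = serial).
#' @param control A [pql_control()] list.
#' @param maf,ld_decay Parameters of the haplotype-pool generator
#'   (`design = "sim2"` only).
#' @return A `vclrt_rejection` tibble: one row per method x alpha with
#'   `proportion`, `se`, `rejections`, `n_reps`, `n_nonconverged`.
#'   Per-replicate p-values are kept in `attr(, "replicates")`.
#' @examples
#' run_type1(n = 150, K = 5, n_reps = 10, B = 50,
#'           methods = "score", master_seed = 2)
#' @export
run_type1 <- function(design = c("sim1", "sim2"), n, K, n_reps = 2000L,
                      B = 1000L,
                      methods = c("permutation", "score", "mixture50",
                                  "mixture65"),
                      alpha_levels = 0.05, master_seed = 1L, workers = 1L,
                      control = pql_control(), maf = 0.25, ld_decay = 0.8) {
  run_sim_study(design, n = n, K = K, tau2 = 0, m = 0, n_reps = n_reps,
                B = B, methods = methods, alpha_levels = alpha_levels,
                master_seed = master_seed, workers = workers,
                control = control, maf = maf, ld_decay = ld_decay)
}

#' Monte-Carlo power study
#'
#' As [run_type1()] but with effectful generators: normal effects with
#' variance `tau2` (`design = "sim1"`) or `m` causal SNPs with
#' `U[low, high]` effects (`design = "sim2"`).  Passing `tau2 = 0` (or
#' `m = 0`) is allowed and simply yields a type-I-error run.
#'
#' @inheritParams run_type1
#' @param tau2 Variance component of the SNP effects (`design = "sim1"`).
#' @param m Number of causal SNPs (`design = "sim2"`).
#' @return A `vclrt_rejection` tibble (power = rejection proportion).
#' @export
run_power <- function(design = c("sim1", "sim2"), n, K, tau2 = 0.15, m = 0,
                      n_reps = 1000L, B = 1000L,
                      methods = c("permutation", "score", "mixture50",
                                  "mixture65"),
                      alpha_levels = 0.05, master_seed = 1L, workers = 1L,
                      control = pql_control(), maf = 0.25, ld_decay = 0.8) {
  run_sim_study(design, n = n, K = K, tau2 = tau2, m = m, n_reps = n_reps,
                B = B, methods = methods, alpha_levels = alpha_levels,
                master_seed = master_seed, workers = workers,
                control = control, maf = maf, ld_decay = ld_decay)
}
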