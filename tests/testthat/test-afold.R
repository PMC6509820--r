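test_that("group statistics winsorize outlier replicates at the Tukey fence", {
  m <- rbind(g1 = c(10, 10, 10, 10), g2 = c(10, 10, 10, 100))
  colnames(m) <- paste0("s", 1:4)
  st1 <- polyfold:::group_stats_matrix(m, winsorize = TRUE)
  expect_equal(st1$mu[["g1"]], 10)
  expect_equal(st1$s_obs[["g1"]], 0)
  # type-7 quartiles of (10,10,10,100): Q1 = 10, Q3 = 32.5, fence = 66.25
  expect_equal(st1$mu[["g2"]], mean(c(10, 10, 10, 66.25)))

  st2 <- polyfold:::group_stats_matrix(m, winsorize = FALSE)
  expect_equal(st2$mu[["g2"]], 32.5)

  # m = 1 records SD as missing
  st3 <- polyfold:::group_stats_matrix(m[, 1, drop = FALSE])
  expect_true(all(is.na(st3$s_obs)))

  # tibble interface returns one row per gene per group
  mm <- rbind(m, m)
  rownames(mm) <- paste0("g", 1:4)
  d <- new_design(colnames(mm), c("a", "a", "b", "b"))
  st <- group_stats(mm, d, winsorize = FALSE)
  expect_equal(nrow(st), 8)
  expect_equal(unique(st$m), 2)
  expect_error(group_stats(mm, new_design(c("s1", "s9"), c("a", "b"))),
               "missing from matrix")
})

test_that("the SD trend tracks a known mean-SD law and extrapolates flat", {
  mu <- exp(seq(log(1), log(400), length.out = 500))
  trend <- fit_sd_trend(mu, sqrt(mu), trend_bins = 20)
  expect_lt(max(abs(trend(mu) - sqrt(mu)) / sqrt(mu)), 0.10)
  # flat extrapolation beyond the data
  expect_equal(trend(1e6), trend(max(mu)))
  expect_equal(trend(0), trend(min(mu)))

  const <- fit_sd_trend(mu, rep(3, 500), trend_bins = 10)
  expect_equal(const(c(0, 10, 1e5)), rep(3, 3))

  expect_error(fit_sd_trend(mu[1:5], sqrt(mu[1:5]), trend_bins = 20),
               "reduce trend_bins")
})

test_that("borrowing floors the SD at the trend and applies the replicate penalty", {
  trend4 <- function(mu) rep(4, length(mu))
  tbl <- tibble::tibble(m = c(3, 5, 5, 1), mu = c(10, 10, 10, 10),
                        s_obs = c(0, 10, 1, NA))
  out <- apply_borrowing(tbl, trend4, penalty_on = TRUE)
  expect_equal(out$s_used,
               c(4 * sqrt(1.5), 10 * sqrt(1.25), 4 * sqrt(1.25), 4 * sqrt(2)))
  off <- apply_borrowing(tbl[1:3, ], trend4, penalty_on = FALSE)
  expect_equal(off$s_used, c(4, 10, 4))
})

test_that("the polynomial uncertainty is exact arithmetic in s and mu", {
  expect_equal(uncertainty(2, 4), 3)
  expect_equal(uncertainty(3, 3), 6)
  expect_equal(uncertainty(0, 123), 0)
  # exactness property over a grid
  s <- runif(200, 0, 50)
  mu <- runif(200, 1e-6, 1e4)
  expect_equal(uncertainty(s, mu), s + s^2 / mu, tolerance = 1e-12)
})

test_that("moderated fold changes shrink monotonically to zero in the uncertainty", {
  expect_equal(moderated_lfc(31, 15, 0, 0, 1), 1)
  expect_equal(moderated_lfc(7, 1, 1000, 1000, 1), log2(1008 / 1002))
  expect_equal(moderated_lfc(50, 50, 3, 9, 1), 0)

  eps_grid <- seq(0, 5000, length.out = 100)
  lfc <- moderated_lfc(40, 10, eps_grid, eps_grid, 1)
  expect_true(all(diff(abs(lfc)) < 0))          # strictly shrinking
  expect_true(all(sign(lfc) == 1))              # sign preserved
  expect_lt(abs(lfc[100]), 0.01)                # limit is zero
  raw <- log2((40 + 1) / (10 + 1))
  expect_true(all(abs(lfc) <= raw + 1e-12))     # never exceeds raw
})

test_that("sigma0 modes match their formulas and handle degeneracy", {
  expect_equal(global_sigma0(c(rep(1, 5), rep(-1, 5)), "second_moment"), 1)
  # |lfc| values: six 0.5 and six 1.5, median 1
  expect_equal(global_sigma0(rep(c(0.5, -0.5, 1.5, -1.5), 3), "robust_mad"),
               1 / 0.67448975, tolerance = 1e-9)
  expect_equal(global_sigma0(rep(0, 20), "second_moment"), 0)
  expect_equal(afold_pvalues(c(0, 1), 0), c(1, 1))

  # trimmed_normal recovers the SD of clean normal data and resists
  # contamination by a DE-like tail
  set.seed(23)
  z <- rnorm(20000, sd = 0.2)
  expect_equal(global_sigma0(z, "trimmed_normal"), 0.2, tolerance = 0.01)
  contaminated <- c(z, runif(2000, 0.6, 2) * sample(c(-1, 1), 2000, TRUE))
  expect_lt(global_sigma0(contaminated, "trimmed_normal"), 0.22)
  expect_gt(global_sigma0(contaminated, "second_moment"), 0.3)
})

test_that("p-values follow the zero-centered normal and rank with |lfc|", {
  expect_equal(afold_pvalues(0, 1), 1)
  expect_equal(afold_pvalues(1.959964, 1), 0.05, tolerance = 1e-6)
  expect_equal(afold_pvalues(1, 1), 2 * (1 - pnorm(1)))
})

test_that("BH adjustment agrees with the brute-force step-up oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_bh(c(0.005, 0.011, 0.02, 0.04)),
               c(0.02, 0.022, 0.08 / 3, 0.04))
  expect_equal(adjust_bh(0.37), 0.37)

  set.seed(31)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjust_bh(p), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("run_afold is deterministic, symmetric on duplicated groups, and coherent", {
  sim <- simulate_nb(make_param_table(500, seed = 41), 4, 25, 25, seed = 42)
  fit1 <- run_afold(sim$counts, sim$design, trend_bins = 10)
  fit2 <- run_afold(sim$counts, sim$design, trend_bins = 10)
  expect_identical(fit1$results, fit2$results)
  expect_equal(nrow(fit1$results), nrow(filter_all_zero(sim$counts)))

  # identical pseudo-groups: all moderated lfc zero, all p = 1
  m <- random_counts(80, 3, seed = 43, lambda = 40)
  dup <- cbind(m, m)
  colnames(dup) <- paste0("s", 1:6)
  d <- new_design(colnames(dup), rep(c("a", "b"), each = 3))
  fit_dup <- run_afold(dup, d, trend_bins = 5)
  expect_equal(fit_dup$results$lfc_moderated, rep(0, 80))
  expect_equal(fit_dup$results$pvalue, rep(1, 80))

  # ranking coherence: p-value order is |lfc| order
  res <- fit1$results
  expect_equal(rank(res$pvalue, ties.method = "average"),
               rank(-abs(res$lfc_moderated), ties.method = "average"))
  # moderated never exceeds pseudo-count raw fold change
  expect_true(all(abs(res$lfc_moderated) <= abs(res$lfc_raw) + 1e-12))

  # single-replicate reference group runs through the trend-only path
  d31 <- new_design(paste0("s", 1:4), c("a", "a", "a", "b"))
  fit31 <- run_afold(random_counts(150, 4, seed = 44, lambda = 30), d31,
                     trend_bins = 6)
  expect_true(all(is.finite(fit31$results$lfc_moderated)))
  expect_true(all(fit31$results$uncertainty_alt > 0))
})

test_that("a large null comparison keeps the raw type-I fraction near alpha", {
  params <- make_param_table(12500, seed = 51)
  sim <- simulate_nb(params, 5, 0, 0, seed = 52)
  fit <- run_afold(sim$counts, sim$design)
  expect_lte(type1_error(fit$results$pvalue), 0.07)
  expect_gte(type1_error(fit$results$pvalue), 0.005)
})

test_that("tidy, glance and autoplot expose the fit", {
  sim <- simulate_nb(make_param_table(300, seed = 61), 3, 10, 10, seed = 62)
  fit <- run_afold(sim$counts, sim$design, trend_bins = 8)
  td <- generics::tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("gene_id", "lfc_moderated", "padj") %in% names(td)))
  gl <- generics::glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_genes, nrow(td))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  expect_output(print(fit), "aFold differential expression fit")
})
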