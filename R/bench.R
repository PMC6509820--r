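#' Run the simulation benchmark protocol
#'
#' For each repetition: draw a mean-dispersion table, simulate a two-group
#' negative-binomial data set for the chosen scenario, fit [run_afold()],
#' and score it — Mann-Whitney AUC of true-DE vs non-DE genes ranked by
#' `|lfc_moderated|`, sensitivity and FDR at `padj < 0.1`, and (optionally)
#' the type I error rate on a matched null simulation of the same size with
#' no DE. Scenarios:
#' \describe{
#'   \item{`nb`}{negative-binomial counts, symmetric DE (default
#'     625 up + 625 down of 12,500 genes).}
#'   \item{`nb_outliers`}{as `nb`, plus per-cell random 5-10x outliers at
#'     probability `outlier_prob`.}
#'   \item{`nb_asym`}{all DE in one direction (`n_up = 0`), the regime that
#'     defeats composition-assuming normalization.}
#' }
#'
#' @param scenario One of `"nb"`, `"nb_outliers"`, `"nb_asym"`.
#' @param n_genes Number of genes (default 12500).
#' @param n_per_group Replicates per group (default 5).
#' @param n_up,n_down DE gene counts; defaults 625/625 (`nb_asym`: 0 up,
#'   `n_up + n_down` down).
#' @param reps Repetitions (default 10).
#' @param seed Integer seed; each repetition derives its own sub-seed.
#' @param outlier_prob Per-cell outlier probability for `nb_outliers`
#'   (default 0.05).
#' @param lfc_range Log2 effect-size range (default `c(0.585, 2)`).
#' @param alpha Adjusted-p cutoff for sensitivity/FDR (default 0.1).
#' @param null_rates Also run a matched no-DE simulation per repetition and
#'   record its raw-p type I rate (default `TRUE`).
#' @param ... Passed to [run_afold()] (e.g. `norm`, `pseudo`, `trend_bins`).
#' @return Object of class `afold_bench` with per-repetition metrics; see
#'   [tidy.afold_bench()] and [glance.afold_bench()].
#' @export
#' @examples
#' b <- afold_bench("nb", n_genes = 400, n_per_group = 3, n_up = 20,
#'                  n_down = 20, reps = 2, seed = 1, trend_bins = 10)
#' generics::glance(b)
afold_bench <- function(scenario = c("nb", "nb_outliers", "nb_asym"),
                        n_genes = 12500, n_per_group = 5,
                        n_up = 625, n_down = 625, reps = 10, seed = 1,
                        outlier_prob = 0.05, lfc_range = c(0.585, 2),
                        alpha = 0.1, null_rates = TRUE, ...) {
  scenario <- match.arg(scenario)
  stopifnot(reps >= 1)
  if (scenario == "nb_asym") {
    n_down <- n_up + n_down
    n_up <- 0
  }
  per_rep <- purrr::map_dfr(seq_len(reps), function(r) {
    base <- (seed %% 100000L) * 10000L + r * 7L
    params <- make_param_table(n_genes, seed = base)
    sim <- simulate_nb(params, n_per_group, n_up, n_down,
                       lfc_range = lfc_range, seed = base + 1L)
    counts <- sim$counts
    if (scenario == "nb_outliers") {
      counts <- inject_outliers(counts, prob = outlier_prob,
                                seed = base + 2L)$counts
    }
    fit <- run_afold(counts, sim$design, ...)
    res <- fit$results
    truth <- sim$truth[match(res$gene_id, sim$truth$gene_id), ]
    auc <- roc_auc(abs(res$lfc_moderated), truth$de_flag)$auc
    sf <- sensitivity_fdr(res$padj, truth$de_flag, alpha = alpha)
    t1 <- NA_real_
    if (null_rates) {
      null_sim <- simulate_nb(params, n_per_group, 0, 0, seed = base + 3L)
      null_counts <- null_sim$counts
      if (scenario == "nb_outliers") {
        null_counts <- inject_outliers(null_counts, prob = outlier_prob,
                                       seed = base + 4L)$counts
      }
      null_fit <- run_afold(null_counts, null_sim$design, ...)
      t1 <- type1_error(null_fit$results$pvalue, alpha = 0.05)
    }
    tibble::tibble(rep = r, auc = auc, sensitivity = sf$sensitivity,
                   fdr = sf$fdr, n_called = sf$n_called, type1_rate = t1)
  })
  structure(list(per_rep = per_rep,
                 config = list(scenario = scenario, n_genes = n_genes,
                               n_per_group = n_per_group, n_up = n_up,
                               n_down = n_down, reps = reps, seed = seed,
                               outlier_prob = outlier_prob,
                               lfc_range = lfc_range, alpha = alpha)),
            class = "afold_bench")
}

#' @export
print.afold_bench <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("aFold benchmark: %s, %d genes, n = %d per group, %d reps\n",
              cfg$scenario, cfg$n_genes, cfg$n_per_group, cfg$reps))
  s <- generics::glance(x)
  cat(sprintf("  mean AUC %.3f (SD %.3f)   sensitivity %.3f   FDR %.3f\n",
              s$mean_auc, s$sd_auc, s$mean_sensitivity, s$mean_fdr))
  if (!is.na(s$mean_type1)) {
    cat(sprintf("  mean type I rate on matched null: %.4f\n", s$mean_type1))
  }
  invisible(x)
}

#' Per-repetition benchmark metrics
#' @param x An `afold_bench`.
#' @param ... Unused.
#' @return Tibble with one row per repetition: `auc`, `sensitivity`, `fdr`,
#'   `n_called`, `type1_rate`.
#' @export
tidy.afold_bench <- function(x, ...) x$per_rep

#' One-row benchmark summary
#' @param x An `afold_bench`.
#' @param ... Unused.
#' @return One-row tibble of means and SDs across repetitions.
#' @export
glance.afold_bench <- function(x, ...) {
  p <- x$per_rep
  tibble::tibble(
    scenario = x$config$scenario, reps = nrow(p),
    mean_auc = mean(p$auc), sd_auc = stats::sd(p$auc),
    mean_sensitivity = mean(p$sensitivity),
    mean_fdr = mean(p$fdr, na.rm = TRUE),
    mean_type1 = mean(p$type1_rate)
  )
}

#' Boxplot-style view of benchmark repetitions
#' @param object An `afold_bench`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.afold_bench <- function(object, ...) {
  d <- tidyr::pivot_longer(object$per_rep, -"rep",
                           names_to = "metric", values_to = "value")
  d <- d[!is.na(d$value), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.12, size = 1, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("scenario %s, n = %d per group",
                                  object$config$scenario,
                                  object$config$n_per_group)) +
    ggplot2::theme_minimal()
}
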