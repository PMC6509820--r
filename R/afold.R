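#' Row-wise type-7 quantile of a numeric matrix
#' @param x matrix (rows = genes)
#' @param p single probability
#' @keywords internal
#' @noRd
row_quantile7 <- function(x, p) {
  n <- ncol(x)
  if (n == 1) return(x[, 1])
  sorted <- t(apply(x, 1, sort.int, method = "quick"))
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  sorted[, lo] + (h - lo) * (sorted[, hi] - sorted[, lo])
}

#' Per-gene, per-group mean and SD with outlier winsorization
#'
#' For each gene within each group, values above the Tukey upper fence
#' `Q3 + 1.5 * IQR` (type-7 quartiles over the group's replicates) are capped
#' at the fence before computing the mean and sample SD, provided the group
#' has at least 4 replicates. This keeps a single aberrant replicate from
#' inflating the variance estimate. Groups of size 1 report `s_obs = NA`
#' (the mean-SD trend stands in downstream).
#'
#' @param norm Normalized expression tibble (from [normalize_counts()]) or
#'   named numeric matrix.
#' @param design Design tibble from [new_design()] / [read_design()].
#' @param winsorize Apply the upper-fence cap (default `TRUE`).
#' @return Tibble with columns `gene_id`, `group`, `m`, `mu`, `s_obs`.
#' @export
group_stats <- function(norm, design, winsorize = TRUE) {
  m <- if (is.matrix(norm)) norm else {
    x <- as.matrix(norm[, -1, drop = FALSE])
    rownames(x) <- as.character(norm[[1]])
    x
  }
  if (!all(design$sample_id %in% colnames(m))) {
    stop("design sample_ids missing from matrix", call. = FALSE)
  }
  purrr::map_dfr(unique(design$group), function(g) {
    ids <- design$sample_id[design$group == g]
    if (!length(ids)) stop("group '", g, "' has no samples", call. = FALSE)
    sub <- m[, ids, drop = FALSE]
    st <- group_stats_matrix(sub, winsorize)
    tibble::tibble(gene_id = rownames(m), group = g, m = length(ids),
                   mu = unname(st$mu), s_obs = unname(st$s_obs))
  })
}

group_stats_matrix <- function(x, winsorize = TRUE) {
  n <- ncol(x)
  if (winsorize && n >= 4) {
    q1 <- row_quantile7(x, 0.25)
    q3 <- row_quantile7(x, 0.75)
    fence <- q3 + 1.5 * (q3 - q1)
    x <- pmin(x, fence)
  }
  mu <- rowMeans(x)
  if (n >= 2) {
    s_obs <- sqrt(rowSums((x - mu)^2) / (n - 1))
  } else {
    s_obs <- rep(NA_real_, nrow(x))
  }
  list(mu = mu, s_obs = s_obs)
}

#' Fit the mean-SD trend across genes
#'
#' Bins genes into `trend_bins` equal-count bins of `log(mu + 1)`, takes the
#' per-bin median of the observed SDs, enforces monotone non-decreasing SD in
#' the mean (pool-adjacent-violators), and interpolates linearly between bin
#' medians with flat extrapolation beyond the observed range. The returned
#' function is deterministic and defined for all `mu >= 0`; it supplies a
#' variance floor for genes whose few replicates happen to agree too well.
#'
#' @param mu Vector of per-gene (per-group) means.
#' @param s_obs Matching observed SDs (`NA` allowed; dropped).
#' @param trend_bins Number of bins (>= 3, default 20).
#' @return A function `s_trend(mu)`.
#' @export
fit_sd_trend <- function(mu, s_obs, trend_bins = 20) {
  stopifnot(trend_bins >= 3)
  ok <- !is.na(s_obs) & !is.na(mu) & mu > 0
  mu <- mu[ok]
  s_obs <- s_obs[ok]
  if (length(mu) < trend_bins) {
    stop("only ", length(mu), " usable genes for ", trend_bins,
         " bins; reduce trend_bins", call. = FALSE)
  }
  ord <- order(mu)
  mu <- mu[ord]
  s_obs <- s_obs[ord]
  bin <- ceiling(seq_along(mu) / (length(mu) / trend_bins))
  bin_mu <- tapply(mu, bin, stats::median)
  bin_s <- tapply(s_obs, bin, stats::median)
  # collapse bins that landed on the same median mu (heavily tied data)
  bin_s <- tapply(bin_s, bin_mu, stats::median)
  bin_mu <- as.numeric(names(bin_s))
  bin_s <- as.numeric(bin_s)
  if (length(bin_mu) == 1) {
    val <- bin_s
    return(function(mu) rep(val, length(mu)))
  }
  bin_s <- stats::isoreg(bin_mu, bin_s)$yf
  stats::approxfun(bin_mu, bin_s, rule = 2)
}

#' Working SD after trend borrowing and the small-sample penalty
#'
#' The working SD is the larger of the observed SD and the trend prediction
#' at the gene's mean: under-estimated variances (the classic small-sample
#' failure mode) are floored at what genes of similar expression typically
#' show, while genuinely large variances are kept. With `penalty_on`, groups
#' of `m` replicates additionally pay a factor `sqrt(1 + 1/(m - 1))` for the
#' uncertainty of the SD estimate itself. Groups of size 1 have no observed
#' SD and use the trend value times the two-replicate penalty.
#'
#' @param stats_tbl Tibble from [group_stats()] (columns `m`, `mu`, `s_obs`).
#' @param trend Function from [fit_sd_trend()].
#' @param penalty_on Apply the small-sample penalty (default `TRUE`).
#' @return `stats_tbl` with columns `s_trend` and `s_used` added.
#' @export
apply_borrowing <- function(stats_tbl, trend, penalty_on = TRUE) {
  s_trend <- trend(stats_tbl$mu)
  m <- stats_tbl$m
  lambda <- ifelse(m >= 2 & penalty_on, sqrt(1 + 1 / (m - 1)), 1)
  s_used <- pmax(stats_tbl$s_obs, s_trend) * lambda
  singleton <- m == 1 | is.na(stats_tbl$s_obs)
  s_used[singleton] <- s_trend[singleton] * sqrt(2)
  dplyr::mutate(stats_tbl, s_trend = s_trend, s_used = s_used)
}

#' Polynomial read-count uncertainty
#'
#' The uncertainty of a gene's mean expression is its sample SD plus the
#' propagated error of the SD estimate itself, which scales with the gene's
#' coefficient of variation `s / mu`. Together, `eps = s + s^2 / mu`: a
#' polynomial in the SD whose quadratic term dominates exactly where the CV
#' is large (low expression, high dispersion). A small floor (`1e-8`) on the
#' mean keeps the ratio finite; a zero SD yields zero uncertainty.
#'
#' @param s_used Working SD (vector, >= 0).
#' @param mu Mean (vector, >= 0).
#' @return Uncertainty vector `eps`.
#' @export
uncertainty <- function(s_used, mu) {
  stopifnot(all(s_used >= 0), all(mu >= 0))
  ifelse(s_used == 0, 0, s_used + s_used^2 / pmax(mu, 1e-8))
}

#' Uncertainty-moderated log2 fold change
#'
#' The larger of the two group uncertainties is added, together with the
#' pseudo-count, to both group means before taking the log2 ratio:
#' `log2(mu_alt + eps* + pseudo) - log2(mu_ref + eps* + pseudo)`. The sign
#' always matches the sign of the raw mean difference, the magnitude is
#' non-increasing in the shared uncertainty, and the statistic goes to zero
#' as the uncertainty grows — unreliable ratios are shrunk toward zero while
#' well-measured ones are nearly untouched. With zero uncertainty this is the
#' ordinary pseudo-count fold change.
#'
#' @param mu_alt,mu_ref Group means (>= 0).
#' @param eps_alt,eps_ref Group uncertainties (>= 0).
#' @param pseudo Prior count added to both means (> 0, default 1).
#' @return Moderated log2 fold change vector.
#' @export
moderated_lfc <- function(mu_alt, mu_ref, eps_alt, eps_ref, pseudo = 1) {
  stopifnot(pseudo > 0)
  eps_star <- pmax(eps_alt, eps_ref)
  log2(mu_alt + eps_star + pseudo) - log2(mu_ref + eps_star + pseudo)
}

#' Global spread of moderated fold changes
#'
#' Scale of the zero-centered normal null for moderated fold changes.
#'
#' \describe{
#'   \item{`trimmed_normal` (default)}{zero-mean normal scale fitted by
#'     iterative truncation: starting from the MAD, genes with
#'     `|lfc| > 2.5 * sigma` are set aside, the second moment of the
#'     remainder is corrected for the truncation
#'     (`E[Z^2 | |Z| < 2.5] = 1 - 2 c phi(c) / (2 Phi(c) - 1)`), and the two
#'     steps are repeated to convergence. On null data this recovers the
#'     plain SD; when a sizeable fraction of genes is genuinely DE their
#'     large fold changes fall outside the truncation and do not inflate
#'     the null scale.}
#'   \item{`second_moment`}{SD about zero, `sqrt(mean(lfc^2))` — the literal
#'     global standard deviation of a zero-mean model over all genes.
#'     Inflated by heavy DE (conservative direction).}
#'   \item{`robust_mad`}{`median(|lfc|) / 0.67448975`.}
#' }
#'
#' @param lfc Vector of moderated log2 fold changes (>= 10 finite values).
#' @param mode `"trimmed_normal"` (default), `"second_moment"` or
#'   `"robust_mad"`.
#' @return Scalar `sigma0 >= 0`; zero flags a degenerate (all-zero) fit and
#'   downstream p-values become 1.
#' @export
global_sigma0 <- function(lfc, mode = c("trimmed_normal", "second_moment",
                                        "robust_mad")) {
  mode <- match.arg(mode)
  lfc <- lfc[is.finite(lfc)]
  if (length(lfc) < 10) stop("need >= 10 finite fold changes", call. = FALSE)
  switch(mode,
         second_moment = sqrt(mean(lfc^2)),
         robust_mad = stats::median(abs(lfc)) / 0.67448975,
         trimmed_normal = sigma0_trimmed_normal(lfc))
}

sigma0_trimmed_normal <- function(lfc, cutoff = 2.5, max_iter = 50) {
  s <- stats::median(abs(lfc)) / 0.67448975
  if (s == 0) return(sqrt(mean(lfc^2)))
  # second moment of a standard normal truncated to |z| < cutoff
  corr <- 1 - 2 * cutoff * stats::dnorm(cutoff) /
    (2 * stats::pnorm(cutoff) - 1)
  for (i in seq_len(max_iter)) {
    keep <- abs(lfc) < cutoff * s
    if (!any(keep)) break
    s_new <- sqrt(mean(lfc[keep]^2) / corr)
    if (s_new == 0 || abs(s_new - s) < 1e-12 * s) {
      s <- s_new
      break
    }
    s <- s_new
  }
  s
}

#' Two-sided p-values from the zero-centered normal
#'
#' `p = 2 * (1 - Phi(|lfc| / sigma0))`. Because p is a monotone function of
#' the absolute moderated fold change, ranking genes by p-value and ranking
#' by `|lfc|` are the same ordering.
#'
#' @param lfc Moderated log2 fold changes.
#' @param sigma0 Global spread from [global_sigma0()].
#' @return P-value vector in (0, 1]; all 1 when `sigma0` is 0.
#' @export
afold_pvalues <- function(lfc, sigma0) {
  if (sigma0 <= 0) return(rep(1, length(lfc)))
  2 * stats::pnorm(-abs(lfc) / sigma0)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, delegated to [stats::p.adjust()].
#'
#' @param p P-value vector in `[0, 1]`.
#' @return Adjusted p-values, order-preserving and elementwise `>= p`.
#' @export
adjust_bh <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Fit the aFold differential expression model
#'
#' Runs the full two-group pipeline: drop all-zero genes, compute size
#' factors, normalize, per-group means/SDs with outlier winsorization,
#' mean-SD trend borrowing with small-sample penalty, polynomial uncertainty,
#' moderated log2 fold changes, and significance from a zero-centered normal
#' with the global spread of the moderated fold changes, BH-adjusted.
#' Deterministic given its inputs.
#'
#' @param counts Counts tibble (first column `gene_id`) or named matrix.
#' @param design Design tibble ([new_design()]); or a data frame with
#'   `sample_id` and `group` columns.
#' @param ref Reference group label (denominator of fold changes); defaults
#'   to the design's recorded reference level.
#' @param norm Size-factor method, see [size_factors()]. Default `"qtotal"`.
#' @param pseudo Prior count (> 0, default 1) on the normalized scale.
#' @param penalty Apply the small-sample SD penalty (default `TRUE`).
#' @param winsorize Cap per-gene outlier replicates (default `TRUE`).
#' @param sigma0_mode See [global_sigma0()].
#' @param trend_bins Bins for [fit_sd_trend()] (default 20).
#' @param beta,winsor_fraction,q Passed to [size_factors()].
#' @return An object of class `afold_fit`; see [tidy.afold_fit()],
#'   [glance.afold_fit()], [autoplot.afold_fit()].
#' @export
#' @examples
#' sim <- simulate_nb(make_param_table(300, seed = 1), n_per_group = 4,
#'                    n_up = 15, n_down = 15, seed = 2)
#' fit <- run_afold(sim$counts, sim$design, trend_bins = 10)
#' dplyr::arrange(generics::tidy(fit), padj)
run_afold <- function(counts, design, ref = NULL,
                      norm = c("qtotal", "total", "quartile", "geometric"),
                      pseudo = 1, penalty = TRUE, winsorize = TRUE,
                      sigma0_mode = c("trimmed_normal", "second_moment", "robust_mad"),
                      trend_bins = 20, beta = 1, winsor_fraction = 0.05,
                      q = 0.75) {
  norm <- match.arg(norm)
  sigma0_mode <- match.arg(sigma0_mode)
  design <- new_design(design$sample_id, design$group,
                       reference_level = ref %||% attr(design, "reference_level"))
  lv <- design_levels(design)
  counts <- filter_all_zero(counts)
  m <- as_count_matrix(counts)
  if (!setequal(design$sample_id, colnames(m))) {
    stop("design samples do not match count matrix columns", call. = FALSE)
  }
  m <- m[, design$sample_id, drop = FALSE]

  sf <- size_factors(m, method = norm, beta = beta,
                     winsor_fraction = winsor_fraction, q = q)
  nm <- sweep(m, 2, sf$size_factor[match(colnames(m), sf$sample_id)], "/")

  ref_ids <- design$sample_id[design$group == lv[["ref"]]]
  alt_ids <- design$sample_id[design$group == lv[["alt"]]]
  st_ref <- lapply(group_stats_matrix(nm[, ref_ids, drop = FALSE], winsorize),
                   unname)
  st_alt <- lapply(group_stats_matrix(nm[, alt_ids, drop = FALSE], winsorize),
                   unname)

  pooled_mu <- c(st_ref$mu, st_alt$mu)
  pooled_s <- c(st_ref$s_obs, st_alt$s_obs)
  if (all(is.na(pooled_s))) {
    stop("at least one group needs >= 2 replicates to estimate variability",
         call. = FALSE)
  }
  trend <- fit_sd_trend(pooled_mu, pooled_s, trend_bins)

  used <- function(st, m_grp) {
    tbl <- tibble::tibble(m = m_grp, mu = st$mu, s_obs = st$s_obs)
    apply_borrowing(tbl, trend, penalty_on = penalty)
  }
  b_ref <- used(st_ref, length(ref_ids))
  b_alt <- used(st_alt, length(alt_ids))
  eps_ref <- uncertainty(b_ref$s_used, b_ref$mu)
  eps_alt <- uncertainty(b_alt$s_used, b_alt$mu)

  lfc_raw <- log2(st_alt$mu + pseudo) - log2(st_ref$mu + pseudo)
  lfc_mod <- moderated_lfc(st_alt$mu, st_ref$mu, eps_alt, eps_ref, pseudo)
  sigma0 <- global_sigma0(lfc_mod, sigma0_mode)
  pvalue <- afold_pvalues(lfc_mod, sigma0)
  padj <- adjust_bh(pvalue)

  results <- tibble::tibble(
    gene_id = rownames(m),
    mean_ref = st_ref$mu, mean_alt = st_alt$mu,
    sd_ref = b_ref$s_used, sd_alt = b_alt$s_used,
    uncertainty_ref = eps_ref, uncertainty_alt = eps_alt,
    lfc_raw = lfc_raw, lfc_moderated = lfc_mod,
    pvalue = pvalue, padj = padj
  )
  structure(
    list(results = results, sigma0 = sigma0, size_factors = sf,
         sd_trend = trend,
         reference_level = lv[["ref"]], alt_level = lv[["alt"]],
         n_ref = length(ref_ids), n_alt = length(alt_ids),
         options = list(norm = norm, pseudo = pseudo, penalty = penalty,
                        winsorize = winsorize, sigma0_mode = sigma0_mode,
                        trend_bins = trend_bins, beta = beta,
                        winsor_fraction = winsor_fraction, q = q)),
    class = "afold_fit"
  )
}

#' @export
print.afold_fit <- function(x, ...) {
  cat("aFold differential expression fit\n")
  cat(sprintf("  contrast: %s vs %s (reference)  [n = %d vs %d]\n",
              x$alt_level, x$reference_level, x$n_alt, x$n_ref))
  cat(sprintf("  genes: %d   normalization: %s   sigma0 = %.4g (%s)\n",
              nrow(x$results), x$options$norm, x$sigma0,
              x$options$sigma0_mode))
  cat(sprintf("  genes at padj < 0.05: %d\n", sum(x$results$padj < 0.05)))
  invisible(x)
}

#' Tidy an aFold fit into a per-gene tibble
#'
#' @param x An `afold_fit`.
#' @param ... Unused.
#' @return Tibble with one row per gene: group means, working SDs,
#'   uncertainties, raw and moderated log2 fold change, `pvalue`, `padj`.
#' @export
tidy.afold_fit <- function(x, ...) x$results

#' One-row summary of an aFold fit
#'
#' @param x An `afold_fit`.
#' @param ... Unused.
#' @return One-row tibble: gene count, group sizes, `sigma0`, number of genes
#'   at `padj < 0.05`, normalization method.
#' @export
glance.afold_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$results), n_ref = x$n_ref, n_alt = x$n_alt,
    sigma0 = x$sigma0, n_sig_padj05 = sum(x$results$padj < 0.05),
    norm = x$options$norm
  )
}

#' MA plot of an aFold fit
#'
#' Moderated log2 fold change against mean normalized expression, with genes
#' at `padj < alpha` highlighted.
#'
#' @param object An `afold_fit`.
#' @param alpha Significance threshold for highlighting (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.afold_fit <- function(object, alpha = 0.05, ...) {
  d <- dplyr::mutate(object$results,
                     a = log2((.data$mean_ref + .data$mean_alt) / 2 + 1),
                     significant = .data$padj < alpha)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$a, y = .data$lfc_moderated,
                                  colour = .data$significant)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 mean normalized expression",
                  y = "moderated log2 fold change",
                  colour = sprintf("padj < %g", alpha)) +
    ggplot2::theme_minimal()
}
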