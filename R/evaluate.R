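#' Label genes from a validated truth table
#'
#' A gene is a positive when its validated absolute log2 fold change exceeds
#' `tp_threshold`, a negative when it is below `tn_threshold`, and excluded
#' from evaluation in between — the grey zone where the external assay does
#' not clearly call either way.
#'
#' @param truth Tibble with `gene_id` and `true_log2fc`.
#' @param tp_threshold Positive threshold (default 0.5, log2).
#' @param tn_threshold Negative threshold (default 0.2, log2).
#' @return Tibble with `gene_id` and `label` in
#'   `c("positive", "negative", "excluded")`.
#' @export
label_by_truth <- function(truth, tp_threshold = 0.5, tn_threshold = 0.2) {
  stopifnot(tp_threshold > tn_threshold, tn_threshold >= 0)
  a <- abs(truth$true_log2fc)
  label <- dplyr::case_when(
    a > tp_threshold ~ "positive",
    a < tn_threshold ~ "negative",
    TRUE ~ "excluded"
  )
  if (!any(label == "positive") || !any(label == "negative")) {
    stop("truth thresholds leave no positives or no negatives", call. = FALSE)
  }
  tibble::tibble(gene_id = truth$gene_id, label = label)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    keep <- labels != "excluded"
    out <- rep(NA, length(labels))
    out[keep] <- labels[keep] == "positive"
    return(out)
  }
  stop("labels must be logical or positive/negative/excluded", call. = FALSE)
}

#' ROC curve and Mann-Whitney AUC
#'
#' The AUC is the Mann-Whitney statistic: the probability that a random
#' positive outscores a random negative, ties counting one half. The ROC
#' points sweep every score threshold; the trapezoidal area under them
#' equals the Mann-Whitney value.
#'
#' @param scores Numeric; larger means more confidently differentially
#'   expressed (e.g. `|lfc_moderated|` or `-log10(p)`).
#' @param labels Logical (`TRUE` = positive) or character labels from
#'   [label_by_truth()]; `"excluded"`/`NA` entries are dropped.
#' @return List with `auc` (scalar) and `roc` (tibble `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_binary_labels(labels)
  keep <- !is.na(pos) & is.finite(scores)
  scores <- scores[keep]
  pos <- pos[keep]
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos < 1 || n_neg < 1) stop("need >= 1 positive and >= 1 negative",
                                   call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord])
  fp <- cumsum(!pos[ord])
  last_of_tie <- c(diff(scores[ord]) != 0, TRUE)
  roc <- tibble::tibble(
    fpr = c(0, fp[last_of_tie] / n_neg),
    tpr = c(0, tp[last_of_tie] / n_pos)
  )
  list(auc = auc, roc = roc)
}

#' One-sided z-test for an AUC difference
#'
#' Tests `auc1 > auc2` using the Hanley-McNeil variance for each curve,
#' `V = [A(1-A) + (P-1)(Q1 - A^2) + (N-1)(Q2 - A^2)] / (P N)` with
#' `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`, treating the two curves as
#' independent. The caller applies multiplicity adjustment across
#' comparisons.
#'
#' @param auc1,auc2 AUC values in `[0, 1]`.
#' @param n_pos,n_neg Numbers of positive and negative genes (>= 2).
#' @return One-sided p-value for `auc1 > auc2`.
#' @export
auc_ztest <- function(auc1, auc2, n_pos, n_neg) {
  stopifnot(auc1 >= 0, auc1 <= 1, auc2 >= 0, auc2 <= 1,
            n_pos >= 2, n_neg >= 2)
  hm_var <- function(a) {
    q1 <- a / (2 - a)
    q2 <- 2 * a^2 / (1 + a)
    (a * (1 - a) + (n_pos - 1) * (q1 - a^2) + (n_neg - 1) * (q2 - a^2)) /
      (n_pos * n_neg)
  }
  v <- hm_var(auc1) + hm_var(auc2)
  if (v <= 0) {
    if (auc1 == auc2) return(0.5)
    return(if (auc1 > auc2) 0 else 1)
  }
  stats::pnorm((auc1 - auc2) / sqrt(v), lower.tail = FALSE)
}

#' Sensitivity and FDR at an adjusted-p cutoff
#'
#' Genes with `padj < alpha` are called. Sensitivity is the fraction of true
#' DE genes called; FDR is the fraction of calls that are not true DE.
#' With no calls the FDR is undefined and reported as `NaN`.
#'
#' @param padj Adjusted p-values.
#' @param de_flag Logical truth per gene.
#' @param alpha Cutoff (default 0.1).
#' @return Tibble with `sensitivity`, `fdr`, `n_called`.
#' @export
sensitivity_fdr <- function(padj, de_flag, alpha = 0.1) {
  stopifnot(length(padj) == length(de_flag))
  if (!any(de_flag)) stop("no true DE genes; sensitivity undefined",
                          call. = FALSE)
  called <- padj < alpha
  tibble::tibble(
    sensitivity = sum(called & de_flag) / sum(de_flag),
    fdr = if (any(called)) sum(called & !de_flag) / sum(called) else NaN,
    n_called = sum(called)
  )
}

#' Empirical FDR against an external truth labelling
#'
#' `eFDR = FP / (TP + FP)` over called genes, where TP/FP status comes from
#' [label_by_truth()]; genes labelled `"excluded"` are dropped from both
#' numerator and denominator. `NaN` when no non-excluded gene is called.
#'
#' @param calls Character vector of called gene identifiers.
#' @param labels Tibble from [label_by_truth()].
#' @return Scalar eFDR.
#' @export
efdr <- function(calls, labels) {
  hit <- labels[labels$gene_id %in% calls & labels$label != "excluded", ]
  if (!nrow(hit)) return(NaN)
  sum(hit$label == "negative") / nrow(hit)
}

#' Type I error rate on a null comparison
#'
#' Fraction of genes with raw (unadjusted) p-value below `alpha` in a
#' comparison that contains no true differential expression.
#'
#' @param pvalues Raw p-values.
#' @param alpha Cutoff (default 0.05).
#' @return Scalar rate in `[0, 1]`.
#' @export
type1_error <- function(pvalues, alpha = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  mean(pvalues < alpha)
}

#' Root-mean-square deviation between observed and expected fold changes
#'
#' Used against reference fold changes with known truth (spike-in mixing
#' ratios, validated qRT-PCR panels).
#'
#' @param observed,expected Aligned finite log2 fold-change vectors.
#' @return Scalar RMSD.
#' @export
rmsd <- function(observed, expected) {
  stopifnot(length(observed) == length(expected), length(observed) > 0,
            all(is.finite(observed)), all(is.finite(expected)))
  sqrt(mean((observed - expected)^2))
}

#' Type I error over random null splits of replicate samples
#'
#' Samples from a single condition are repeatedly partitioned at random into
#' two pseudo-groups of `group_size`; any p-value below the cutoff is then a
#' false rejection. Reports the per-split type I rate of [run_afold()].
#'
#' @param counts Counts tibble or named matrix of replicates from one
#'   condition.
#' @param group_size Samples per pseudo-group.
#' @param n_splits Number of random splits.
#' @param seed Integer seed; splits are deterministic given it.
#' @param alpha Raw-p cutoff (default 0.05).
#' @param ... Passed to [run_afold()].
#' @return Tibble with `split`, `type1_rate`.
#' @export
null_split_eval <- function(counts, group_size, n_splits, seed, alpha = 0.05,
                            ...) {
  m <- as_count_matrix(counts)
  if (ncol(m) < 2 * group_size) {
    stop("need at least ", 2 * group_size, " replicate columns", call. = FALSE)
  }
  splits <- with_seed(seed, {
    lapply(seq_len(n_splits), function(i) sample(colnames(m), 2 * group_size))
  })
  rates <- vapply(splits, function(ids) {
    design <- new_design(ids, rep(c("g1", "g2"), each = group_size),
                         reference_level = "g1")
    fit <- run_afold(m[, ids, drop = FALSE], design, ...)
    type1_error(fit$results$pvalue, alpha)
  }, numeric(1))
  tibble::tibble(split = seq_len(n_splits), type1_rate = rates)
}

#' Plot a ROC curve
#'
#' @param roc Tibble of `fpr`, `tpr` from [roc_auc()], or the list it
#'   returns.
#' @return A ggplot object.
#' @export
plot_roc <- function(roc) {
  if (is.list(roc) && !is.data.frame(roc) && !is.null(roc$roc)) roc <- roc$roc
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
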