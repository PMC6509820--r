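#' Per-sample coefficient of variation of the count distribution
#'
#' The CV of a sample's count distribution across genes is invariant to
#' sequencing depth (multiplying every count in a sample by a scalar leaves
#' it unchanged) but responds to genuine differential expression, which makes
#' the distribution more or less dispersed. This is the signal qtotal uses to
#' correct library totals.
#'
#' Counts are first converted to proportions of the column sum. The largest
#' `winsor_fraction` of proportions is capped at the `1 - winsor_fraction`
#' quantile before taking SD/mean, so a handful of extremely high-count genes
#' cannot dominate the estimate. Quantiles use linear interpolation between
#' order statistics (type 7); SD uses the n - 1 divisor.
#'
#' @param counts Counts tibble or named matrix.
#' @param winsor_fraction Fraction of top proportions to winsorize,
#'   in `[0, 0.5)`. Default 0.05.
#' @return Tibble with columns `sample_id`, `cv`.
#' @export
sample_cv <- function(counts, winsor_fraction = 0.05) {
  m <- as_count_matrix(counts)
  if (nrow(m) < 3) stop("CV needs at least 3 genes", call. = FALSE)
  stopifnot(winsor_fraction >= 0, winsor_fraction < 0.5)
  totals <- colSums(m)
  if (any(totals <= 0)) {
    stop("zero column sum in sample(s): ",
         paste(colnames(m)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  cv <- vapply(seq_len(ncol(m)), function(j) {
    p <- m[, j] / totals[j]
    if (winsor_fraction > 0) {
      cap <- stats::quantile(p, 1 - winsor_fraction, type = 7, names = FALSE)
      p <- pmin(p, cap)
    }
    stats::sd(p) / mean(p)
  }, numeric(1))
  tibble::tibble(sample_id = colnames(m), cv = cv)
}

rescale_geomean <- function(f) f / exp(mean(log(f)))

sf_tibble <- function(sample_ids, raw, method) {
  tibble::tibble(sample_id = sample_ids,
                 size_factor = unname(rescale_geomean(raw)),
                 method = method)
}

#' Per-sample size factors
#'
#' Computes one positive scale factor per sample, rescaled so the factors
#' have geometric mean 1 (normalized values stay on the counts scale).
#' Normalized expression is `count / size_factor`.
#'
#' Methods:
#' \describe{
#'   \item{`total`}{factors proportional to column sums (library totals).}
#'   \item{`quartile`}{factors proportional to the per-sample sum of counts
#'     at or below that sample's `q` quantile of its nonzero counts
#'     (default upper quartile), discarding the highest-count genes that
#'     dominate totals.}
#'   \item{`geometric`}{median-of-ratios: per-gene reference is the geometric
#'     mean across samples (over genes nonzero in every sample), and the
#'     factor is the median ratio of counts to that reference.}
#'   \item{`qtotal`}{CV-corrected totals, `T_s * (CV_ref / CV_s)^beta` with
#'     `CV_s` from [sample_cv()] and `CV_ref` the median CV across samples.
#'     A sample whose count distribution is more dispersed than typical
#'     (e.g. because many genes are up-regulated in it) has its apparent
#'     library size discounted. `beta = 0` reduces exactly to `total`.}
#' }
#'
#' @param counts Counts tibble or named matrix.
#' @param method One of `"qtotal"`, `"total"`, `"quartile"`, `"geometric"`.
#' @param beta Strength of the CV correction for qtotal (>= 0, default 1).
#' @param winsor_fraction Winsorization used inside [sample_cv()].
#' @param q Quantile for the quartile method, in (0, 1); default 0.75.
#' @return Tibble with columns `sample_id`, `size_factor`, `method`;
#'   geometric mean of `size_factor` is 1.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = paste0("g", 1:4),
#'                          a = c(10, 5, 0, 25), b = c(20, 10, 0, 50))
#' size_factors(counts, method = "total")
size_factors <- function(counts,
                         method = c("qtotal", "total", "quartile", "geometric"),
                         beta = 1, winsor_fraction = 0.05, q = 0.75) {
  method <- match.arg(method)
  m <- as_count_matrix(counts)
  switch(method,
    total = size_factors_total(m),
    quartile = size_factors_quartile(m, q),
    geometric = size_factors_geometric(m),
    qtotal = size_factors_qtotal(m, beta, winsor_fraction)
  )
}

size_factors_total <- function(m) {
  totals <- colSums(m)
  if (any(totals <= 0)) {
    stop("zero column sum in sample(s): ",
         paste(colnames(m)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  sf_tibble(colnames(m), totals, "total")
}

size_factors_quartile <- function(m, q = 0.75) {
  stopifnot(q > 0, q < 1)
  raw <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    nz <- x[x > 0]
    if (!length(nz)) {
      stop("sample '", colnames(m)[j], "' has no nonzero counts", call. = FALSE)
    }
    cut <- stats::quantile(nz, q, type = 7, names = FALSE)
    sum(x[x <= cut])
  }, numeric(1))
  if (any(raw <= 0)) {
    stop("quartile sum is zero in sample(s): ",
         paste(colnames(m)[raw <= 0], collapse = ", "), call. = FALSE)
  }
  sf_tibble(colnames(m), raw, "quartile")
}

size_factors_geometric <- function(m) {
  everywhere <- rowSums(m > 0) == ncol(m)
  if (!any(everywhere)) {
    stop("no gene has nonzero counts in every sample; geometric method undefined",
         call. = FALSE)
  }
  sub <- m[everywhere, , drop = FALSE]
  ref <- exp(rowMeans(log(sub)))
  raw <- apply(sub / ref, 2, stats::median)
  sf_tibble(colnames(m), raw, "geometric")
}

size_factors_qtotal <- function(m, beta = 1, winsor_fraction = 0.05) {
  stopifnot(beta >= 0)
  totals <- colSums(m)
  if (any(totals <= 0)) {
    stop("zero column sum in sample(s): ",
         paste(colnames(m)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  if (beta == 0) {
    out <- size_factors_total(m)
    out$method <- "qtotal"
    return(out)
  }
  cv <- sample_cv(m, winsor_fraction)$cv
  if (any(cv == 0)) {
    stop("degenerate sample(s) with zero CV: ",
         paste(colnames(m)[cv == 0], collapse = ", "), call. = FALSE)
  }
  cv_ref <- stats::median(cv)
  sf_tibble(colnames(m), totals * (cv_ref / cv)^beta, "qtotal")
}

#' Normalize a count matrix by size factors
#'
#' Divides each sample's counts by its size factor. With all factors equal
#' to 1 the output equals the input.
#'
#' @param counts Counts tibble or named matrix.
#' @param sf Size-factor tibble from [size_factors()] (columns `sample_id`,
#'   `size_factor`).
#' @return Tibble in the counts layout holding normalized (real-valued)
#'   expression.
#' @export
normalize_counts <- function(counts, sf) {
  m <- as_count_matrix(counts)
  if (!setequal(colnames(m), sf$sample_id)) {
    stop("size-factor sample_ids do not match the count matrix", call. = FALSE)
  }
  f <- sf$size_factor[match(colnames(m), sf$sample_id)]
  stopifnot(all(f > 0))
  norm <- sweep(m, 2, f, "/")
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                   tibble::as_tibble(norm))
}
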