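#' Run code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so simulator calls are
#' reproducible without perturbing the session stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Baseline mean-dispersion table for the benchmark simulator
#'
#' Emulates the marginal structure of deeply sequenced human RNA-seq:
#' baseline means `mu0` are log-normal (median ~30 on the count scale,
#' `log10` SD 0.8, truncated to `[0.5, 1e5]`) and negative-binomial
#' dispersions follow the familiar decreasing trend
#' `phi = (0.05 + 2 / mu0) * noise` with log-normal multiplicative noise
#' (log-SD 0.5), truncated to `[0.01, 5]`: lowly expressed genes are
#' strongly overdispersed, highly expressed ones approach the Poisson-plus-
#' biological-CV floor. Any empirical two-column `(mu0, phi)` table can be
#' used in place of this generator.
#'
#' @param n_genes Number of genes (>= 100).
#' @param seed Integer seed; the table is deterministic given it.
#' @return Tibble with columns `gene_id`, `mu0`, `phi`.
#' @export
make_param_table <- function(n_genes, seed) {
  stopifnot(n_genes >= 100)
  with_seed(seed, {
    mu0 <- 10^stats::rnorm(n_genes, mean = 1.5, sd = 0.8)
    mu0 <- pmin(pmax(mu0, 0.5), 1e5)
    noise <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 0.5)
    phi <- (0.05 + 2 / mu0) * noise
    phi <- pmin(pmax(phi, 0.01), 5)
    tibble::tibble(gene_id = sprintf("gene_%05d", seq_len(n_genes)),
                   mu0 = mu0, phi = phi)
  })
}

#' Simulate a two-group negative-binomial count matrix
#'
#' Draws counts gene-by-gene from a negative binomial with variance
#' `mu + phi * mu^2`. A random subset of genes is differentially expressed:
#' `n_up` genes have their group-B mean multiplied by `2^lfc` and `n_down`
#' by `2^-lfc`, with `lfc` uniform on `lfc_range` (default 1.5x to 4x).
#' Each sample's means are additionally scaled by a library-size factor
#' uniform on `libsize_range`, so no two libraries have identical depth.
#' Setting `n_up = 0` (or `n_down = 0`) produces the asymmetric designs
#' under which composition-assuming normalizations break down.
#'
#' @param params Tibble from [make_param_table()] (columns `gene_id`, `mu0`,
#'   `phi`).
#' @param n_per_group Replicates per group.
#' @param n_up,n_down Numbers of up-/down-regulated genes (sum <= genes).
#' @param lfc_range Log2 effect-size range, default `c(0.585, 2)`.
#' @param libsize_range Library-size factor range, default `c(0.7, 1.4)`.
#' @param seed Integer seed; output is deterministic given it.
#' @return List with `counts` (tibble, samples `A1..`, `B1..`), `design`
#'   (reference level `"A"`), and `truth` (tibble `gene_id`, `de_flag`,
#'   `true_log2fc`).
#' @export
simulate_nb <- function(params, n_per_group, n_up, n_down,
                        lfc_range = c(0.585, 2), libsize_range = c(0.7, 1.4),
                        seed) {
  g <- nrow(params)
  if (n_up + n_down > g) stop("n_up + n_down exceeds the number of genes",
                              call. = FALSE)
  stopifnot(n_per_group >= 1, all(lfc_range > 0), all(libsize_range > 0))
  with_seed(seed, {
    de_idx <- sample.int(g, n_up + n_down)
    up_idx <- de_idx[seq_len(n_up)]
    down_idx <- setdiff(de_idx, up_idx)
    lfc <- numeric(g)
    lfc[up_idx] <- stats::runif(n_up, lfc_range[1], lfc_range[2])
    lfc[down_idx] <- -stats::runif(n_down, lfc_range[1], lfc_range[2])

    n_s <- 2 * n_per_group
    lib <- stats::runif(n_s, libsize_range[1], libsize_range[2])
    mu_a <- params$mu0
    mu_b <- params$mu0 * 2^lfc
    mu_mat <- cbind(
      matrix(mu_a, g, n_per_group),
      matrix(mu_b, g, n_per_group)
    ) * rep(lib, each = g)

    size <- 1 / pmax(params$phi, 1e-12)
    counts <- matrix(
      stats::rnbinom(g * n_s, mu = as.vector(mu_mat),
                     size = rep(size, n_s)),
      g, n_s
    )
    storage.mode(counts) <- "double"
    rownames(counts) <- params$gene_id
    colnames(counts) <- c(paste0("A", seq_len(n_per_group)),
                          paste0("B", seq_len(n_per_group)))
    design <- new_design(colnames(counts),
                         rep(c("A", "B"), each = n_per_group),
                         reference_level = "A")
    truth <- tibble::tibble(gene_id = params$gene_id,
                            de_flag = lfc != 0, true_log2fc = lfc)
    list(counts = counts_as_tibble(counts), design = design, truth = truth)
  })
}

#' Inject random multiplicative outliers
#'
#' Each matrix cell is independently selected with probability `prob`; a
#' selected count is replaced by `round(count * U)` with `U` uniform on
#' `factor_range` (default 5-10x). This is the classic single-replicate
#' corruption that wrecks naive sample-variance estimates.
#'
#' @param counts Counts tibble or named matrix.
#' @param prob Per-cell selection probability (default 0.05).
#' @param factor_range Multiplier range, default `c(5, 10)`.
#' @param seed Integer seed.
#' @return List with `counts` (tibble) and `outlier_mask` (logical matrix,
#'   genes x samples).
#' @export
inject_outliers <- function(counts, prob = 0.05, factor_range = c(5, 10),
                            seed) {
  stopifnot(prob >= 0, prob <= 1)
  m <- as_count_matrix(counts)
  with_seed(seed, {
    mask <- matrix(stats::runif(length(m)) < prob, nrow(m), ncol(m),
                   dimnames = dimnames(m))
    if (any(mask)) {
      u <- stats::runif(sum(mask), factor_range[1], factor_range[2])
      m[mask] <- round(m[mask] * u)
    }
    list(counts = counts_as_tibble(m), outlier_mask = mask)
  })
}

#' Spike differential expression into a null comparison
#'
#' Starting from a comparison of samples drawn from one condition (no true
#' DE), a random fraction `frac_de` of genes has its counts in the
#' non-reference group multiplied by `2^lfc` (rounded), with `lfc` drawn with
#' replacement from `lfc_source` — e.g. an empirical set of validated fold
#' changes. The result is a data set with known partial DE on a real noise
#' background.
#'
#' @param counts Counts tibble or named matrix (a null comparison).
#' @param design Design tibble; the non-reference group receives the spikes.
#' @param frac_de Fraction of genes to perturb, in (0, 1).
#' @param lfc_source Non-empty vector of log2 fold changes to draw from.
#' @param seed Integer seed.
#' @return List with `counts` (tibble) and `truth` (tibble `gene_id`,
#'   `de_flag`, `true_log2fc`).
#' @export
spike_de <- function(counts, design, frac_de, lfc_source, seed) {
  stopifnot(frac_de > 0, frac_de < 1)
  if (!length(lfc_source)) stop("lfc_source is empty", call. = FALSE)
  m <- as_count_matrix(counts)
  lv <- design_levels(design)
  alt_ids <- design$sample_id[design$group == lv[["alt"]]]
  with_seed(seed, {
    n_de <- round(frac_de * nrow(m))
    de_idx <- sample.int(nrow(m), n_de)
    lfc <- numeric(nrow(m))
    lfc[de_idx] <- sample(lfc_source, n_de, replace = TRUE)
    m[de_idx, alt_ids] <- round(m[de_idx, alt_ids] * 2^lfc[de_idx])
    truth <- tibble::tibble(gene_id = rownames(m),
                            de_flag = seq_len(nrow(m)) %in% de_idx,
                            true_log2fc = lfc)
    list(counts = counts_as_tibble(m), truth = truth)
  })
}
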