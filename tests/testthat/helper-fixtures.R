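# small in-code fixtures shared across tests

tiny_counts <- function() {
  tibble::tibble(
    gene_id = paste0("g", 1:6),
    s1 = c(10, 0, 25, 3, 100, 0),
    s2 = c(12, 0, 30, 1, 90, 0),
    s3 = c(8, 2, 28, 0, 110, 1),
    s4 = c(11, 1, 26, 2, 95, 0)
  )
}

tiny_design <- function() {
  polyfold::new_design(paste0("s", 1:4), c("ctl", "ctl", "trt", "trt"),
                       reference_level = "ctl")
}

random_counts <- function(g, s, seed, lambda = 30) {
  set.seed(seed)
  m <- matrix(rpois(g * s, lambda), g, s,
              dimnames = list(paste0("g", seq_len(g)),
                              paste0("s", seq_len(s))))
  storage.mode(m) <- "double"
  m
}

# O(m^2) literal Benjamini-Hochberg step-up, independent of p.adjust
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  padj_sorted <- vapply(seq_len(m), function(k) {
    min(vapply(k:m, function(j) min(1, p[ord[j]] * m / j), numeric(1)))
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- padj_sorted
  out
}

# O(P*N) pairwise Mann-Whitney AUC oracle
auc_brute <- function(scores, positive) {
  ps <- scores[positive]
  ns <- scores[!positive]
  tot <- 0
  for (x in ps) tot <- tot + sum(x > ns) + 0.5 * sum(x == ns)
  tot / (length(ps) * length(ns))
}
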