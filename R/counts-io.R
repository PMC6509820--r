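#' Coerce a counts table to a validated integer matrix
#'
#' Internal canonical representation: genes in rows, samples in columns,
#' dimnames carrying the identifiers. Accepts the user-facing tibble layout
#' (first column `gene_id`, remaining columns one per sample) or a numeric
#' matrix with row and column names.
#'
#' @param counts A data frame whose first column holds gene identifiers, or a
#'   named numeric matrix.
#' @return Integer-valued numeric matrix with unique dimnames.
#' @keywords internal
#' @noRd
as_count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    m <- counts
    if (is.null(rownames(m)) || is.null(colnames(m))) {
      stop("count matrix must carry gene rownames and sample colnames", call. = FALSE)
    }
  } else if (is.data.frame(counts)) {
    if (ncol(counts) < 3) {
      stop("need a gene_id column plus at least two sample columns", call. = FALSE)
    }
    gene_ids <- as.character(counts[[1]])
    m <- as.matrix(counts[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- gene_ids
  } else {
    stop("`counts` must be a data frame or a matrix", call. = FALSE)
  }
  validate_count_matrix(m)
  m
}

validate_count_matrix <- function(m) {
  if (nrow(m) < 1 || ncol(m) < 2) {
    stop("count matrix needs >= 1 gene and >= 2 samples", call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(m)[duplicated(rownames(m))])[1:min(3, sum(duplicated(rownames(m))))],
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "), call. = FALSE)
  }
  if (anyNA(m)) stop("count matrix contains missing values", call. = FALSE)
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at gene '%s', sample '%s'",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]), call. = FALSE)
  }
  if (any(abs(m - round(m)) > 1e-8)) {
    bad <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at gene '%s', sample '%s'; counts are not rounded silently",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]), call. = FALSE)
  }
  invisible(m)
}

#' Turn a count matrix back into the user-facing tibble layout
#' @keywords internal
#' @noRd
counts_as_tibble <- function(m) {
  dplyr::bind_cols(
    tibble::tibble(gene_id = rownames(m)),
    tibble::as_tibble(m)
  )
}

#' Read a gene-by-sample count matrix
#'
#' Reads a counts table with genes as rows and samples as columns. The
#' canonical dialect is TSV with a header row of sample identifiers and the
#' gene identifier in the first column; CSV is accepted by extension or
#' explicit `format`. MatrixMarket sparse input (`.mtx`) expects sidecar
#' files `<path>.genes` and `<path>.samples` holding one identifier per line.
#' Entries must be non-negative integers; fractional or negative values are
#' rejected rather than rounded.
#'
#' @param path Path to the counts file.
#' @param format One of `"auto"` (by extension), `"tsv"`, `"csv"`, `"mtx"`.
#' @return A tibble with first column `gene_id` and one numeric column per
#'   sample, in file order.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_counts(tibble::tibble(gene_id = c("g1", "g2"), a = c(3, 0), b = c(1, 8)), tf)
#' read_counts(tf)
read_counts <- function(path, format = c("auto", "tsv", "csv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", mtx = "mtx", "tsv")
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "mtx") {
    gene_file <- paste0(path, ".genes")
    sample_file <- paste0(path, ".samples")
    if (!file.exists(gene_file) || !file.exists(sample_file)) {
      stop("mtx input needs sidecar files ", gene_file, " and ", sample_file,
           call. = FALSE)
    }
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(gene_file)
    colnames(m) <- readLines(sample_file)
  } else {
    delim <- if (format == "csv") "," else "\t"
    tbl <- readr::read_delim(path, delim = delim, comment = "#",
                             show_col_types = FALSE, progress = FALSE)
    names(tbl)[1] <- "gene_id"
    nonnum <- names(tbl)[-1][!vapply(tbl[-1], is.numeric, logical(1))]
    if (length(nonnum)) {
      stop("non-numeric count column(s): ", paste(nonnum, collapse = ", "),
           call. = FALSE)
    }
    m <- as.matrix(tbl[, -1, drop = FALSE])
    rownames(m) <- as.character(tbl[[1]])
  }
  validate_count_matrix(m)
  counts_as_tibble(m)
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]: the round trip reproduces the matrix exactly.
#'
#' @param counts Counts tibble or named matrix (see [read_counts()]).
#' @param path Output path.
#' @param format As in [read_counts()].
#' @param header Optional character vector written as leading `#` comment
#'   lines (ignored for mtx).
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("auto", "tsv", "csv", "mtx"),
                         header = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", mtx = "mtx", "tsv")
  }
  m <- as_count_matrix(counts)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    writeLines(rownames(m), paste0(path, ".genes"))
    writeLines(colnames(m), paste0(path, ".samples"))
    return(invisible(path))
  }
  delim <- if (format == "csv") "," else "\t"
  if (!is.null(header)) {
    writeLines(paste0("# ", header), path)
    readr::write_delim(counts_as_tibble(m), path, delim = delim, append = TRUE,
                       col_names = TRUE)
  } else {
    readr::write_delim(counts_as_tibble(m), path, delim = delim)
  }
  invisible(path)
}

#' Read a two-group design table
#'
#' A design CSV has columns `sample_id` and `group` with exactly two group
#' levels. The reference level (denominator of every fold change) defaults to
#' the first level in file order.
#'
#' @param path Path to the design CSV (TSV accepted by extension).
#' @param reference_level Optional reference group label.
#' @return A tibble with columns `sample_id`, `group`, carrying the reference
#'   level in attribute `"reference_level"`.
#' @export
read_design <- function(path, reference_level = NULL) {
  delim <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(tbl))) {
    stop("design table needs columns sample_id and group", call. = FALSE)
  }
  new_design(tbl$sample_id, tbl$group, reference_level)
}

#' Construct and validate a two-group design
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param group Group label per sample; exactly two levels.
#' @param reference_level Reference group label; defaults to the first label
#'   in order of appearance.
#' @return Design tibble (`sample_id`, `group`) with attribute
#'   `"reference_level"`.
#' @export
new_design <- function(sample_ids, group, reference_level = NULL) {
  sample_ids <- as.character(sample_ids)
  group <- as.character(group)
  if (length(sample_ids) != length(group)) {
    stop("sample_ids and group must have equal length", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample_id in design", call. = FALSE)
  }
  levels <- unique(group)
  if (length(levels) != 2) {
    stop("design must have exactly two group levels, got: ",
         paste(levels, collapse = ", "), call. = FALSE)
  }
  if (is.null(reference_level)) reference_level <- levels[1]
  if (!reference_level %in% levels) {
    stop("reference_level '", reference_level, "' is not a group label",
         call. = FALSE)
  }
  out <- tibble::tibble(sample_id = sample_ids, group = group)
  attr(out, "reference_level") <- reference_level
  out
}

design_levels <- function(design) {
  ref <- attr(design, "reference_level")
  if (is.null(ref)) ref <- design$group[1]
  c(ref = ref, alt = setdiff(unique(design$group), ref))
}

#' Drop genes with zero counts in every sample
#'
#' Genes with zero counts across all samples carry no information for either
#' normalization or testing and are removed before analysis. Gene order is
#' preserved; applying the filter twice is a no-op.
#'
#' @param counts Counts tibble or named matrix.
#' @return Filtered counts tibble.
#' @export
filter_all_zero <- function(counts) {
  m <- as_count_matrix(counts)
  keep <- rowSums(m) > 0
  if (!any(keep)) stop("empty matrix after filtering: all genes are zero",
                       call. = FALSE)
  counts_as_tibble(m[keep, , drop = FALSE])
}

#' Read a truth table of validated log2 fold changes
#'
#' Truth tables pair gene identifiers with externally validated log2 fold
#' changes (e.g. qRT-PCR panels) and optionally a known DE flag, used to
#' label genes for ROC and empirical-FDR evaluation.
#'
#' @param path TSV/CSV with columns `gene_id`, `true_log2fc` and optionally
#'   `de_flag`.
#' @return Tibble with those columns.
#' @export
read_truth <- function(path) {
  delim <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  tbl <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "true_log2fc") %in% names(tbl))) {
    stop("truth table needs columns gene_id and true_log2fc", call. = FALSE)
  }
  if (anyDuplicated(tbl$gene_id)) stop("duplicate gene_id in truth table",
                                       call. = FALSE)
  if (!all(is.finite(tbl$true_log2fc))) stop("non-finite true_log2fc",
                                             call. = FALSE)
  tbl
}

result_columns <- c("gene_id", "mean_ref", "mean_alt", "lfc_raw",
                    "lfc_moderated", "uncertainty_ref", "uncertainty_alt",
                    "pvalue", "padj")

#' Write a differential expression result table
#'
#' Writes the per-gene table as TSV with a fixed column order
#' (`gene_id`, `mean_ref`, `mean_alt`, `lfc_raw`, `lfc_moderated`,
#' `uncertainty_ref`, `uncertainty_alt`, `pvalue`, `padj`). Numbers are
#' written with enough digits that a read-back reproduces them to at least
#' 10 significant digits.
#'
#' @param res An `afold_fit` object or its [tidy()] tibble.
#' @param path Output path.
#' @param header Optional character vector of leading `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_results <- function(res, path, header = NULL) {
  if (inherits(res, "afold_fit")) res <- generics::tidy(res)
  missing_cols <- setdiff(result_columns, names(res))
  if (length(missing_cols)) {
    stop("result table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- res[, result_columns]
  lines <- character(0)
  if (!is.null(header)) lines <- paste0("# ", header)
  body <- vapply(seq_len(nrow(out)), function(i) {
    paste(c(out$gene_id[i],
            formatC(unlist(out[i, -1]), format = "g", digits = 12)),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, paste(result_columns, collapse = "\t"), body), path)
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path Path to the results TSV.
#' @return Result tibble.
#' @export
read_results <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  missing_cols <- setdiff(result_columns, names(tbl))
  if (length(missing_cols)) {
    stop("not a polyfold result table; missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tbl
}
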