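#' Counts per million
#'
#' Library-size normalization: each column is scaled so that it sums to 10^6.
#'
#' @param counts Non-negative genes x samples matrix.
#' @return Linear-scale CPM matrix of the same shape.
#' @export
compute_cpm <- function(counts) {
  check_matrix(counts, "counts", integer_counts = TRUE)
  lib <- colSums(counts)
  if (any(lib == 0))
    stop2("zero library size for sample(s): ",
          paste(colnames(counts)[lib == 0], collapse = ", "))
  sweep(counts, 2, lib / 1e6, "/")
}

#' Filter genes by expression in both groups
#'
#' Keeps genes with CPM above `cpm_threshold` in at least
#' `min_samples_per_group` samples of *every* group, the filter applied
#' before differential expression. Gene order is preserved.
#'
#' @param counts Genes x samples count matrix.
#' @param groups Two-level grouping (factor or character) aligned with the
#'   columns of `counts`.
#' @param cpm_threshold CPM cutoff (exclusive).
#' @param min_samples_per_group Minimum qualifying samples per group.
#' @return The filtered count matrix.
#' @export
filter_expressed <- function(counts, groups, cpm_threshold = 0.05,
                             min_samples_per_group = 3L) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop2("exactly two groups required")
  if (length(groups) != ncol(counts))
    stop2("groups must align with the columns of counts")
  tab <- table(groups)
  if (any(tab < min_samples_per_group))
    stop2("group(s) smaller than min_samples_per_group: ",
          paste(names(tab)[tab < min_samples_per_group], collapse = ", "))
  cpm <- compute_cpm(counts)
  pass <- cpm > cpm_threshold
  keep <- rep(TRUE, nrow(counts))
  for (lev in levels(groups)) {
    keep <- keep &
      rowSums(pass[, groups == lev, drop = FALSE]) >= min_samples_per_group
  }
  counts[keep, , drop = FALSE]
}

#' Log2 CPM expression
#'
#' `log2(cpm + pseudocount)` with the transform recorded in the
#' `transform_tag` attribute; the log-scale expression used throughout the
#' downstream analyses.
#'
#' @param counts Genes x samples count matrix.
#' @param pseudocount Added to CPM before the log (default 1).
#' @export
log2_cpm <- function(counts, pseudocount = 1) {
  x <- log2(compute_cpm(counts) + pseudocount)
  attr(x, "transform_tag") <- "log2cpm"
  x
}

#' Two-group differential expression
#'
#' A transparent stand-in for count-model DE: per-gene Welch t test on
#' `log2(cpm + 1)` with Benjamini-Hochberg adjustment. The fold change is
#' the log2 ratio of pseudocounted group-mean CPM, positive when the gene is
#' higher in the non-reference group. Designed to yield a ranked signature
#' and an FDR-controlled gene list, not to replicate any particular count
#' model's shrinkage.
#'
#' @param counts Filtered genes x samples count matrix.
#' @param groups Two-level grouping aligned with columns.
#' @param ref Reference group level; defaults to the first factor level.
#'   `log2fc > 0` means higher in the other (test) group.
#' @return Data frame with columns `gene`, `log2fc`, `stat`, `p`, `padj`.
#' @export
de_test <- function(counts, groups, ref = NULL) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop2("exactly two groups required")
  if (length(groups) != ncol(counts))
    stop2("groups must align with the columns of counts")
  ref <- ref %||% levels(groups)[1]
  if (!ref %in% levels(groups)) stop2("unknown reference level: ", ref)
  other <- setdiff(levels(groups), ref)
  a_idx <- which(groups == ref); b_idx <- which(groups == other)
  if (length(a_idx) < 2 || length(b_idx) < 2)
    stop2("each group needs at least 2 samples")
  cpm <- compute_cpm(counts)
  w <- row_welch(log2(cpm + 1), a_idx, b_idx)
  log2fc <- log2((rowMeans(cpm[, b_idx, drop = FALSE]) + 1) /
                 (rowMeans(cpm[, a_idx, drop = FALSE]) + 1))
  data.frame(gene = rownames(counts), log2fc = log2fc, stat = w$stat,
             p = w$p, padj = bh_adjust(w$p), row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; output is in input order and clipped to 1.
#'
#' @param p Vector of p values in \[0, 1\].
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop2("p values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hierarchical clustering of samples on z-scored expression
#'
#' Rows (genes) are z-scored across samples with the sample (n-1) standard
#' deviation (constant rows become all-zero), samples are compared by
#' Euclidean distance, and the tree is built with average linkage. Columns
#' are pre-sorted lexicographically by sample ID so that equal-height merges
#' resolve deterministically.
#'
#' @param expr Log-scale genes x samples matrix.
#' @param genes Optional gene subset (all must be present).
#' @return List with `hclust` (the tree), `order` (leaf order indices into
#'   the sorted samples) and `labels` (sample IDs in leaf order).
#' @export
cluster_samples <- function(expr, genes = NULL) {
  check_matrix(expr, "expression")
  if (ncol(expr) < 2) stop2("need at least 2 samples to cluster")
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(expr))
    if (length(missing))
      stop2("genes absent from expression: ",
            paste(utils::head(missing, 5), collapse = ", "))
    expr <- expr[genes, , drop = FALSE]
  }
  expr <- expr[, order(colnames(expr)), drop = FALSE]
  z <- zscore_rows(expr)
  hc <- stats::hclust(stats::dist(t(z), method = "euclidean"),
                      method = "average")
  list(hclust = hc, order = hc$order, labels = colnames(expr)[hc$order])
}

# per-gene z-score across samples; sd = 0 rows -> all zeros
zscore_rows <- function(x) {
  mu <- rowMeans(x)
  sd <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  z <- (x - mu) / sd
  z[sd == 0, ] <- 0
  z
}
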