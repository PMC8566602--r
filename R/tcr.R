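# frequency-vector primitives ------------------------------------------------

# Shannon entropy (natural log) of a frequency vector
shannon_entropy <- function(f) {
  f <- f[f > 0]
  -sum(f * log(f))
}

# Gini index by the sorted cumulative form of the mean-absolute-difference
# definition G = sum_ij |f_i - f_j| / (2 n^2 fbar); O(n log n)
gini <- function(f) {
  if (any(f < 0)) stop2("negative frequencies")
  n <- length(f)
  if (n == 1) return(0)
  s <- sort(f)
  2 * sum(seq_len(n) * s) / (n * sum(s)) - (n + 1) / n
}

#' Per-sample repertoire diversity metrics
#'
#' Summarizes a clonotype table into per-sample diversity statistics.
#' Frequencies are `f_k = count_k / sum(counts)`; `entropy` is Shannon's
#' `H = -sum f_k ln f_k`; `entropy_norm = H / ln(n)` (evenness); the
#' clonality index is `C = 1 - H / ln(n)` (0 = maximally diverse,
#' 1 = monoclonal). A single-clone repertoire takes the distributional
#' limit `H = 0`, `C = 1` (the ratio is 0/0 there); such samples are
#' flagged in the `single_clone` column. Both unnormalized and normalized
#' entropy are reported. The Gini index and clonal-space occupancy columns
#' come from [gini_index()] and [clonal_occupancy()].
#'
#' @param clonotypes Clonotype table (`sample_id`, `clonotype_key`,
#'   `count`); duplicate (sample, key) rows are aggregated by summing.
#' @param bin_edges Passed to [clonal_occupancy()].
#' @return Data frame per sample: `sample_id`, `richness`, `entropy`,
#'   `entropy_norm`, `clonality`, `gini`, `single_clone`, and one
#'   `occ_*` column per occupancy bin.
#' @export
repertoire_metrics <- function(clonotypes,
                               bin_edges = c(0, 1e-5, 1e-4, 1e-3, 1e-2, 1)) {
  tab <- validate_clonotypes(clonotypes)
  occ <- clonal_occupancy(tab, bin_edges)
  rows <- lapply(split(tab$count, tab$sample_id), function(cnt) {
    f <- cnt / sum(cnt)
    n <- length(f)
    h <- shannon_entropy(f)
    if (n >= 2) {
      en <- h / log(n); cl <- 1 - en
    } else {
      en <- 0; cl <- 1   # limit convention, flagged below
    }
    data.frame(richness = n, entropy = h, entropy_norm = en, clonality = cl,
               gini = gini(f), single_clone = n == 1)
  })
  out <- cbind(data.frame(sample_id = names(rows)), do.call(rbind, rows))
  rownames(out) <- NULL
  merge(out, occ, by = "sample_id", sort = TRUE)
}

#' Per-sample Gini index of clone frequencies
#'
#' `G = sum_ij |f_i - f_j| / (2 n^2 mean(f))` over each sample's clone
#' frequencies: 0 for a perfectly even repertoire, approaching 1 under
#' extreme clonal dominance.
#'
#' @inheritParams repertoire_metrics
#' @return Data frame `sample_id`, `gini`.
#' @export
gini_index <- function(clonotypes) {
  tab <- validate_clonotypes(clonotypes)
  g <- vapply(split(tab$count, tab$sample_id),
              function(cnt) gini(cnt / sum(cnt)), numeric(1))
  data.frame(sample_id = names(g), gini = unname(g), row.names = NULL)
}

#' Clonal-space occupancy
#'
#' Fraction of total repertoire mass (sum of `f_k`) carried by clones whose
#' frequency falls in each bin. Default bins
#' `(0, 1e-5], (1e-5, 1e-4], (1e-4, 1e-3], (1e-3, 1e-2], (1e-2, 1]` are
#' labelled rare / small / medium / large / hyperexpanded; the edges used
#' are recorded in the `bin_edges` attribute. Per sample the fractions
#' partition the repertoire and sum to 1.
#'
#' @inheritParams repertoire_metrics
#' @param bin_edges Strictly increasing edges starting at 0 and ending at 1.
#' @return Data frame: `sample_id` plus one `occ_<label>` column per bin.
#' @export
clonal_occupancy <- function(clonotypes,
                             bin_edges = c(0, 1e-5, 1e-4, 1e-3, 1e-2, 1)) {
  tab <- validate_clonotypes(clonotypes)
  if (length(bin_edges) < 2 || is.unsorted(bin_edges, strictly = TRUE) ||
      bin_edges[1] != 0 || bin_edges[length(bin_edges)] != 1)
    stop2("bin_edges must be strictly increasing from 0 to 1")
  labels <- if (length(bin_edges) == 6)
    c("rare", "small", "medium", "large", "hyperexpanded")
  else paste0("bin", seq_len(length(bin_edges) - 1))
  rows <- lapply(split(tab$count, tab$sample_id), function(cnt) {
    f <- cnt / sum(cnt)
    bin <- cut(f, bin_edges, labels = labels, include.lowest = FALSE)
    vapply(labels, function(l) sum(f[bin == l]), numeric(1))
  })
  out <- do.call(rbind, rows)
  colnames(out) <- paste0("occ_", labels)
  out <- cbind(data.frame(sample_id = rownames(out)), as.data.frame(out))
  rownames(out) <- NULL
  attr(out, "bin_edges") <- bin_edges
  out
}
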