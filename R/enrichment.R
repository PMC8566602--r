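#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Genes are ordered by decreasing signature score (ties broken
#' lexicographically by gene symbol). Walking down the list, a set member at
#' position i increments the running sum by `|s_i|^weight_p` divided by the
#' summed weights of all members, and a non-member decrements it by
#' `1/(N - N_hits)`. The enrichment score is the signed maximum deviation of
#' the running sum from zero.
#'
#' @param sig Named numeric vector: the ranked signature (e.g. DE t
#'   statistics), names are gene symbols.
#' @param set Character vector of member genes (or a single element of a GMT
#'   list).
#' @param weight_p Weighting exponent; 1 is the classic weighted statistic,
#'   0 the unweighted KS.
#' @return List with `es`, `running` (the full running-sum profile in ranked
#'   order), `ranked_genes`, `hits` (logical in ranked order) and
#'   `leading_edge`.
#' @export
enrichment_score <- function(sig, set, weight_p = 1) {
  rs <- ranked_signature(sig)
  set <- unique(unlist(set))
  hit <- names(rs) %in% set
  if (!any(hit)) stop2("empty intersection between signature and gene set")
  if (all(hit)) stop2("gene set covers the whole signature; no misses to score")
  wabs <- abs(rs)^weight_p
  denom_hit <- sum(wabs[hit])
  if (denom_hit == 0) stop2("all member weights are zero at this weight_p")
  incr <- ifelse(hit, wabs / denom_hit, -1 / sum(!hit))
  running <- cumsum(incr)
  i <- which.max(abs(running))
  es <- running[i]
  le <- if (es >= 0) names(rs)[seq_len(i)][hit[seq_len(i)]]
        else names(rs)[i:length(rs)][hit[i:length(rs)]]
  list(es = unname(es), running = unname(running),
       ranked_genes = names(rs), hits = hit, leading_edge = le)
}

# decreasing order, lexicographic gene-symbol tie-break
ranked_signature <- function(sig) {
  if (is.null(names(sig))) stop2("signature must be a named numeric vector")
  if (anyDuplicated(names(sig))) stop2("duplicated genes in signature")
  if (any(!is.finite(sig))) stop2("signature scores must be finite")
  sig[order(-sig, names(sig))]
}

# ES from sorted hit positions only; O(k) per permutation
es_from_positions <- function(pos, wabs, n) {
  k <- length(pos)
  cw <- cumsum(wabs[pos])
  w_tot <- cw[k]
  if (w_tot == 0) return(0)
  miss <- 1 / (n - k)
  i <- seq_len(k)
  r_after <- cw / w_tot - (pos - i) * miss
  r_before <- c(0, cw[-k]) / w_tot - (pos - i) * miss
  hi <- max(r_after); lo <- min(r_before, 0)
  if (hi >= -lo) hi else lo
}

#' Gene set enrichment with permutation significance
#'
#' Computes the weighted-KS enrichment score and calibrates it by
#' permutation. In `gene_set` mode (default) the member labels are
#' re-drawn uniformly from the signature; in `phenotype` mode the group
#' labels of the expression matrix are shuffled and the Welch-t signature
#' recomputed per permutation. The normalized enrichment score divides the
#' observed ES by the mean magnitude of same-sign permuted ES, and the
#' nominal p value is the (add-one) fraction of same-sign permuted ES at
#' least as extreme.
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of permutations (>= 100).
#' @param perm_mode `"gene_set"` or `"phenotype"`.
#' @param seed Integer seed; results are reproducible given it.
#' @param expr,groups Required for `phenotype` mode: counts-derived log
#'   expression matrix and two-level grouping (>= 3 samples per group).
#' @return List of class `gsea_result`: `es`, `nes`, `p_nominal`,
#'   `leading_edge`, `n_hits`, `perm_mode`, `n_perm`.
#' @export
gsea <- function(sig, set, n_perm = 1000L, perm_mode = c("gene_set", "phenotype"),
                 seed = 1L, weight_p = 1, expr = NULL, groups = NULL) {
  perm_mode <- match.arg(perm_mode)
  if (n_perm < 100) stop2("n_perm must be >= 100")
  obs <- enrichment_score(sig, set, weight_p)
  rs <- ranked_signature(sig)
  wabs <- abs(rs)^weight_p
  n <- length(rs); k <- sum(obs$hits)
  es_perm <- with_seed(seed, {
    if (perm_mode == "gene_set") {
      vapply(seq_len(n_perm), function(j)
        es_from_positions(sort.int(sample.int(n, k)), wabs, n), numeric(1))
    } else {
      if (is.null(expr) || is.null(groups))
        stop2("phenotype mode needs expr and groups")
      groups <- as.factor(groups)
      if (nlevels(groups) != 2L) stop2("exactly two groups required")
      if (min(table(groups)) < 3)
        stop2("phenotype permutation needs >= 3 samples per group; ",
              "use perm_mode = \"gene_set\"")
      set <- unique(unlist(set))
      vapply(seq_len(n_perm), function(j) {
        g <- sample(groups)
        w <- row_welch(expr, which(g == levels(g)[1]),
                       which(g == levels(g)[2]))
        st <- w$stat; names(st) <- rownames(expr)
        enrichment_score(st, set, weight_p)$es
      }, numeric(1))
    }
  })
  same <- es_perm[sign(es_perm) == sign(obs$es) & es_perm != 0]
  if (obs$es == 0 || length(same) == 0) {
    nes <- NA_real_; p <- NA_real_
  } else {
    nes <- obs$es / mean(abs(same))
    p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
  }
  structure(list(es = obs$es, nes = nes, p_nominal = p,
                 leading_edge = obs$leading_edge, n_hits = k,
                 perm_mode = perm_mode, n_perm = n_perm),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA: ES = %.4f, NES = %.3f, nominal p = %.4g (%d hits, %d %s permutations)\n",
              x$es, x$nes, x$p_nominal, x$n_hits, x$n_perm, x$perm_mode))
  invisible(x)
}

#' GSEA over a gene-set collection with sign-stratified FDR
#'
#' Runs [gsea()] for every set and adds a BH `fdr_q` computed separately
#' within the positive-ES and negative-ES classes, mirroring the
#' sign-stratified normalization of the desktop implementation at small
#' scale. Sets with no overlap are skipped with a warning.
#'
#' @inheritParams gsea
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @return Data frame: `set`, `size`, `es`, `nes`, `p_nominal`, `fdr_q`.
#' @export
gsea_collection <- function(sig, sets, n_perm = 1000L,
                            perm_mode = "gene_set", seed = 1L, weight_p = 1,
                            expr = NULL, groups = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  rows <- lapply(names(sets), function(nm) {
    res <- tryCatch(
      gsea(sig, sets[[nm]], n_perm = n_perm, perm_mode = perm_mode,
           seed = seed, weight_p = weight_p, expr = expr, groups = groups),
      error = function(e) NULL)
    if (is.null(res)) {
      warning("skipping set with no usable overlap: ", nm, call. = FALSE)
      return(NULL)
    }
    data.frame(set = nm, size = res$n_hits, es = res$es, nes = res$nes,
               p_nominal = res$p_nominal)
  })
  out <- do.call(rbind, rows)
  out$fdr_q <- NA_real_
  for (s in c(-1, 1)) {
    idx <- which(sign(out$es) == s & !is.na(out$p_nominal))
    if (length(idx)) out$fdr_q[idx] <- bh_adjust(out$p_nominal[idx])
  }
  out[order(out$p_nominal), , drop = FALSE]
}

#' Single-sample gene-set score
#'
#' The mean, over member genes, of the per-gene z-score across samples: the
#' convention used for the cell-cycle and immune-infiltrate per-sample
#' scores. Constant genes contribute zero.
#'
#' @param expr Log-scale genes x samples matrix.
#' @param set Character vector of member genes (at least one present).
#' @return Named numeric vector of per-sample scores.
#' @export
signature_score <- function(expr, set) {
  check_matrix(expr, "expression")
  set <- unique(unlist(set))
  present <- intersect(set, rownames(expr))
  if (!length(present)) stop2("no member genes present in expression matrix")
  z <- zscore_rows(expr[present, , drop = FALSE])
  colMeans(z)
}
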