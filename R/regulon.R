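#' Single-sample regulon activity
#'
#' Rank-based analytic enrichment of a transcription factor's targets in one
#' sample's expression profile. Within each sample, genes are rank
#' transformed across genes and mapped to standard-normal quantile scores
#' `z_g = qnorm((rank - 0.5) / N)` (ties mid-ranked), so activity is
#' invariant to any monotone per-sample transform of expression. The
#' activity of a regulon with target modes `m_t` (sign of regulation) and
#' likelihoods `w_t` (confidence) is the weighted sum
#' `A = sum(w_t * m_t * z_t) / sqrt(sum(w_t^2))`, a two-tail simplification
#' that preserves sign, weighting and the rank basis of the full
#' three-tail estimator.
#'
#' @param expr Log-scale genes x samples matrix.
#' @param regulons Regulon edge table (`tf`, `target`, `mode`,
#'   `likelihood`), e.g. from [read_regulons()].
#' @param tfs Optional subset of TFs to score (default: all in the table).
#' @param min_targets Minimum targets present in `expr` for a regulon to be
#'   scored (default 10).
#' @return Numeric TFs x samples activity matrix.
#' @export
regulon_activity <- function(expr, regulons, tfs = NULL, min_targets = 10L) {
  check_matrix(expr, "expression")
  regulons <- validate_regulons(regulons)
  tfs <- tfs %||% unique(regulons$tf)
  if (!length(tfs)) stop2("empty regulon collection")
  z <- rank_normal_by_sample(expr)
  out <- matrix(NA_real_, length(tfs), ncol(expr),
                dimnames = list(tfs, colnames(expr)))
  for (tf in tfs) {
    e <- regulons[regulons$tf == tf & regulons$target %in% rownames(expr), ]
    if (nrow(e) < min_targets)
      stop2("regulon ", tf, " has ", nrow(e),
            " targets in the expression matrix; needs >= ", min_targets)
    out[tf, ] <- apply(z[e$target, , drop = FALSE], 2, area_score,
                       mode = e$mode, likelihood = e$likelihood)
  }
  out
}

# weighted two-tail combination of target quantile scores
area_score <- function(z, mode, likelihood) {
  sum(likelihood * mode * z) / sqrt(sum(likelihood^2))
}

# per-sample rank -> standard normal quantile transform (ties mid-ranked)
rank_normal_by_sample <- function(expr) {
  n <- nrow(expr)
  apply(expr, 2, function(x) stats::qnorm((rank(x, ties.method = "average") - 0.5) / n))
}

#' Master-regulator ranking on a group-contrast signature
#'
#' Applies the same weighted-sum activity to a ranked differential
#' signature (e.g. per-gene Welch t statistics, rank-normal transformed
#' across genes) and attaches a two-sided permutation p value obtained by
#' shuffling the gene labels of the signature.
#'
#' @param sig Named numeric vector: group-contrast statistics per gene.
#' @param regulons Regulon edge table.
#' @param n_perm Label permutations per regulon.
#' @param seed Integer seed.
#' @param min_targets Minimum targets present in the signature.
#' @return Data frame ranked by decreasing activity: `tf`, `n_targets`,
#'   `activity`, `p`.
#' @export
master_regulators <- function(sig, regulons, n_perm = 1000L, seed = 1L,
                              min_targets = 10L) {
  regulons <- validate_regulons(regulons)
  tfs <- unique(regulons$tf)
  if (!length(tfs)) stop2("empty regulon collection")
  if (is.null(names(sig))) stop2("signature must be a named numeric vector")
  n <- length(sig)
  z <- stats::qnorm((rank(sig, ties.method = "average") - 0.5) / n)
  names(z) <- names(sig)
  rows <- with_seed(seed, lapply(tfs, function(tf) {
    e <- regulons[regulons$tf == tf & regulons$target %in% names(sig), ]
    if (nrow(e) < min_targets)
      stop2("regulon ", tf, " has ", nrow(e),
            " targets in the signature; needs >= ", min_targets)
    wm <- e$likelihood * e$mode
    denom <- sqrt(sum(e$likelihood^2))
    a <- sum(wm * z[e$target]) / denom
    a_perm <- vapply(seq_len(n_perm), function(j)
      sum(wm * z[sample.int(n, nrow(e))]) / denom, numeric(1))
    p <- (1 + sum(abs(a_perm) >= abs(a))) / (1 + n_perm)
    data.frame(tf = tf, n_targets = nrow(e), activity = a, p = p)
  }))
  out <- do.call(rbind, rows)
  out[order(-out$activity), , drop = FALSE]
}

#' Composite postpartum signature score
#'
#' Adds the single-sample activities of the immune-exhaustion and E2F1
#' regulons and subtracts the TP53 and ESR1 activities:
#' `P = A_exhaustion + A_E2F1 - A_TP53 - A_ESR1`. Higher P captures the
#' postpartum phenotype (proliferative, immune-exhausted, with reduced p53
#' and estrogen-receptor signaling).
#'
#' @param scores Samples x scores matrix or data frame of per-sample
#'   activities (columns named by score).
#' @param keys Length-4 character vector naming, in order, the exhaustion,
#'   E2F1, TP53 and ESR1 score columns.
#' @return Named numeric vector of per-sample composite scores.
#' @export
ppbc_composite <- function(scores,
                           keys = c("exhaustion", "E2F1", "TP53", "ESR1")) {
  if (is.data.frame(scores)) scores <- as.matrix(scores)
  if (length(keys) != 4) stop2("keys must name 4 score columns")
  absent <- setdiff(keys, colnames(scores))
  if (length(absent))
    stop2("missing score column(s): ", paste(absent, collapse = ", "))
  if (any(!is.finite(scores[, keys])))
    stop2("composite inputs must be finite for every sample")
  p <- scores[, keys[1]] + scores[, keys[2]] - scores[, keys[3]] - scores[, keys[4]]
  stats::setNames(as.numeric(p), rownames(scores))
}
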