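# shared fixture builders and independent oracles

make_counts <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% rownames(m) %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% colnames(m) %||% sprintf("s%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a counts matrix whose CPM is exactly `cpm` (library size 1e6 per sample)
counts_from_cpm <- function(cpm, ...) {
  m <- make_counts(cpm, ...)
  pad <- 1e6 - colSums(m)
  stopifnot(all(pad >= 0))
  rbind(m, make_counts(matrix(pad, 1), genes = "filler",
                       samples = colnames(m)))
}

clono_table <- function(counts, sample = "s1") {
  data.frame(sample_id = sample,
             clonotype_key = sprintf("%s-K%03d", sample, seq_along(counts)),
             count = counts)
}

# O(n^2) pairwise-sum Gini oracle
gini_pairwise <- function(f) {
  n <- length(f)
  sum(abs(outer(f, f, "-"))) / (2 * n^2 * mean(f))
}

# brute-force average-linkage agglomeration on a distance matrix; returns
# merge heights in merge order
avg_linkage_heights <- function(d) {
  m <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL; bh <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- mean(m[clusters[[i]], clusters[[j]], drop = FALSE])
        if (h < bh) { bh <- h; best <- c(j, i) }
      }
    }
    heights <- c(heights, bh)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# plain running-sum weighted-KS ES, an independent re-derivation used as
# oracle for the optimized implementation
es_bruteforce <- function(sig, set, weight_p = 1) {
  ord <- order(-sig, names(sig))
  s <- sig[ord]
  hit <- names(s) %in% set
  w <- abs(s)^weight_p
  run <- numeric(length(s))
  cur <- 0
  for (i in seq_along(s)) {
    cur <- cur + if (hit[i]) w[i] / sum(w[hit]) else -1 / sum(!hit)
    run[i] <- cur
  }
  run[which.max(abs(run))]
}
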