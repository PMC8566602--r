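# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' @keywords internal
check_matrix <- function(x, what = "matrix", integer_counts = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop2(what, " must be a numeric matrix (genes x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop2(what, " must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop2(what, " has duplicated gene identifiers")
  if (anyDuplicated(colnames(x)))
    stop2(what, " has duplicated sample identifiers")
  if (integer_counts) {
    if (any(x < 0)) stop2(what, " contains negative counts")
    if (any(!is.finite(x))) stop2(what, " contains non-finite counts")
  }
  invisible(x)
}

# evaluate `code` with a temporary RNG state seeded at `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a sub-stream seed from a master seed; keeps within 32-bit range so
# the counts / clonotype / survival sections can be regenerated independently.
stream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 2147483647 + stream * 1000003) %% 2147483647)
}

# two-group Welch t on rows of a matrix; returns list(mean_a, mean_b, stat,
# df, p). Zero pooled standard error with equal means -> stat 0, p 1.
row_welch <- function(x, a_idx, b_idx) {
  na <- length(a_idx); nb <- length(b_idx)
  xa <- x[, a_idx, drop = FALSE]; xb <- x[, b_idx, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  stat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  zero <- se2 == 0
  stat[zero & mb == ma] <- 0
  stat[zero & mb != ma] <- sign(mb - ma)[zero & mb != ma] * Inf
  df[zero] <- na + nb - 2
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  p[zero & mb == ma] <- 1
  list(mean_a = ma, mean_b = mb, stat = stat, df = df, p = p)
}
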