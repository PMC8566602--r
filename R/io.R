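#' Read and write gene-level count matrices
#'
#' Counts are stored as tab-separated text with a header row of sample IDs and
#' the first column holding gene symbols, the layout produced by
#' [simulate_cohort()] and consumed by the preprocessing functions.
#'
#' @param path Path to a TSV file.
#' @return For `read_counts`, a numeric genes x samples matrix with gene
#'   rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  check_matrix(m, "counts", integer_counts = TRUE)
  m
}

#' @rdname read_counts
#' @param x Genes x samples matrix.
#' @export
write_counts <- function(x, path) {
  check_matrix(x, "counts")
  df <- data.frame(gene = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write sample metadata
#'
#' Comma-separated sample annotations: `sample_id`, grouping columns such as
#' `parity`, `er_status`, `study`, `age_at_diagnosis`, and survival columns
#' `time` (months) and `event` (0/1).
#'
#' @param path Path to a CSV file.
#' @export
read_meta <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_meta
#' @param meta Data frame of sample annotations.
#' @export
write_meta <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write GMT gene-set collections
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`, then
#' member gene symbols (lines may have differing lengths).
#'
#' @param path Path to a `.gmt` file.
#' @return For `read_gmt`, a named list of character vectors of member genes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) stop2("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop2("duplicated gene-set names in GMT")
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param description Optional per-set description (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  desc <- rep_len(description, length(sets))
  lines <- mapply(function(nm, d, members) {
    paste(c(nm, d, members), collapse = "\t")
  }, names(sets), desc, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read and write regulon networks
#'
#' A regulon collection is a long-format table: one row per TF-target edge
#' with columns `tf`, `target`, `mode` (sign of regulation in \[-1, 1\]) and
#' `likelihood` (confidence weight in (0, 1\]).
#'
#' @param path Path to a TSV file.
#' @export
read_regulons <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_regulons(df)
}

#' @rdname read_regulons
#' @param regulons Regulon edge table.
#' @export
write_regulons <- function(regulons, path) {
  validate_regulons(regulons)
  utils::write.table(regulons, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
validate_regulons <- function(df) {
  need <- c("tf", "target", "mode", "likelihood")
  if (!all(need %in% names(df)))
    stop2("regulon table needs columns: ", paste(need, collapse = ", "))
  if (any(df$mode < -1 | df$mode > 1)) stop2("regulon mode outside [-1, 1]")
  if (any(df$likelihood <= 0 | df$likelihood > 1))
    stop2("regulon likelihood outside (0, 1]")
  if (anyDuplicated(df[, c("tf", "target")]))
    stop2("duplicated (tf, target) pairs in regulon table")
  df
}

#' Read and write clonotype tables
#'
#' AIRR-compatible long table with columns `sample_id`, `clonotype_key`
#' (a V-CDR3nt-J composite string) and `count` (a positive duplicate count).
#' Duplicate (sample, key) rows are aggregated by summing counts on read.
#'
#' @param path Path to a TSV file.
#' @export
read_clonotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (all(c("v_call", "junction", "j_call") %in% names(df)) &&
      !"clonotype_key" %in% names(df)) {
    df$clonotype_key <- paste(df$v_call, df$junction, df$j_call, sep = "-")
  }
  if ("duplicate_count" %in% names(df) && !"count" %in% names(df))
    df$count <- df$duplicate_count
  validate_clonotypes(df[, c("sample_id", "clonotype_key", "count")])
}

#' @rdname read_clonotypes
#' @param clonotypes Clonotype table.
#' @export
write_clonotypes <- function(clonotypes, path) {
  validate_clonotypes(clonotypes)
  utils::write.table(clonotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @keywords internal
validate_clonotypes <- function(df) {
  need <- c("sample_id", "clonotype_key", "count")
  if (!all(need %in% names(df)))
    stop2("clonotype table needs columns: ", paste(need, collapse = ", "))
  if (any(df$count < 1)) stop2("clonotype counts must be >= 1")
  # aggregate duplicate (sample, key) rows by summing counts
  agg <- stats::aggregate(count ~ sample_id + clonotype_key, df, sum)
  agg[order(agg$sample_id, -agg$count, agg$clonotype_key), , drop = FALSE]
}

#' Read and write long-format score tables
#'
#' Per-sample named scores (regulon activities, signature scores, composite)
#' are stored long (`sample`, `score_name`, `value`) and used wide
#' (samples x score names) in memory.
#'
#' @param path Path to a TSV file.
#' @return For `read_scores`, a numeric samples x scores matrix.
#' @export
read_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "score_name", "value")
  if (!all(need %in% names(df)))
    stop2("score table needs columns: ", paste(need, collapse = ", "))
  samples <- unique(df$sample); scores <- unique(df$score_name)
  m <- matrix(NA_real_, length(samples), length(scores),
              dimnames = list(samples, scores))
  m[cbind(match(df$sample, samples), match(df$score_name, scores))] <- df$value
  m
}

#' @rdname read_scores
#' @param scores Samples x scores numeric matrix with dimnames.
#' @export
write_scores <- function(scores, path) {
  stopifnot(is.matrix(scores), !is.null(rownames(scores)),
            !is.null(colnames(scores)))
  df <- data.frame(sample = rep(rownames(scores), ncol(scores)),
                   score_name = rep(colnames(scores), each = nrow(scores)),
                   value = as.vector(scores))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
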