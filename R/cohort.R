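#' Collapse microarray probes to gene symbols
#'
#' Per gene, the arithmetic mean over all probes mapping to it; probes with
#' no mapping (absent from the map, `NA` or empty gene) are dropped, the
#' count recorded in the `n_unmapped` attribute.
#'
#' @param expr Probes x samples matrix with probe rownames.
#' @param probe_map Data frame with columns `probe`, `gene`.
#' @return Genes x samples matrix.
#' @export
collapse_probes <- function(expr, probe_map) {
  check_matrix(expr, "probe expression")
  if (!all(c("probe", "gene") %in% names(probe_map)))
    stop2("probe_map needs columns probe, gene")
  probe_map <- probe_map[!is.na(probe_map$gene) & nzchar(probe_map$gene), ]
  if (anyDuplicated(probe_map$probe)) stop2("duplicated probes in map")
  gene <- probe_map$gene[match(rownames(expr), probe_map$probe)]
  keep <- !is.na(gene)
  if (!any(keep)) stop2("no probes map to genes")
  collapsed <- rowsum(expr[keep, , drop = FALSE], gene[keep]) /
    as.vector(table(gene[keep])[sort(unique(gene[keep]))])
  attr(collapsed, "n_unmapped") <- sum(!keep)
  collapsed
}

#' Merge studies with per-study location-scale standardization
#'
#' Cross-study batch harmonization by standardization: the gene space is
#' intersected across studies, and within each study every gene is centered
#' and scaled to unit variance (sample sd) before the matrices are joined.
#' This removes additive and multiplicative per-study effects exactly — the
#' no-shrinkage limit of empirical-Bayes batch correction — at the cost of
#' also removing genuine cross-study location differences; genes constant
#' within a study are set to 0 there and reported in `flagged`.
#'
#' @param studies Named list of genes x samples matrices (>= 2 studies
#'   sharing >= 1 gene; sample IDs must be unique across studies).
#' @return List: `expr` (merged genes x samples matrix), `batch` (study
#'   label per sample), `flagged` (per-study constant genes).
#' @export
merge_standardize <- function(studies) {
  stopifnot(is.list(studies), length(studies) >= 2, !is.null(names(studies)))
  genes <- Reduce(intersect, lapply(studies, rownames))
  if (!length(genes)) stop2("empty gene intersection across studies")
  flagged <- list()
  std <- lapply(names(studies), function(s) {
    x <- studies[[s]][genes, , drop = FALSE]
    mu <- rowMeans(x)
    sd <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
    z <- (x - mu) / sd
    if (any(sd == 0)) {
      z[sd == 0, ] <- 0
      flagged[[s]] <<- genes[sd == 0]
    }
    z
  })
  expr <- do.call(cbind, std)
  if (anyDuplicated(colnames(expr)))
    stop2("sample IDs must be unique across studies")
  batch <- rep(names(studies), vapply(studies, ncol, 1L))
  names(batch) <- colnames(expr)
  list(expr = expr, batch = batch, flagged = flagged)
}

#' Filter a cohort on age, outcome availability and ER status
#'
#' Young women's breast cancer selection: retains samples whose age at
#' diagnosis satisfies the age rule (default `<= 45`; set
#' `inclusive = FALSE` for the strict `< 45` reading), optionally requiring
#' non-missing survival time/event and a given ER status. The rule applied
#' is recorded in attributes; an empty result triggers a warning, not an
#' error.
#'
#' @param meta Sample metadata with `age_at_diagnosis` and, as needed,
#'   `time`, `event`, `er_status` columns.
#' @param max_age Age cutoff in years (default 45).
#' @param inclusive Use `age <= max_age` (default) rather than `<`.
#' @param require_outcome Drop samples with missing `time` or `event`.
#' @param er_status Optional ER status value to match (e.g. "positive").
#' @return The filtered metadata; attributes `age_rule` and `attrition`
#'   (per-study sample counts before/after).
#' @export
filter_cohort <- function(meta, max_age = 45, inclusive = TRUE,
                          require_outcome = FALSE, er_status = NULL) {
  if (!"age_at_diagnosis" %in% names(meta))
    stop2("meta needs an age_at_diagnosis column")
  keep <- if (inclusive) meta$age_at_diagnosis <= max_age
          else meta$age_at_diagnosis < max_age
  keep[is.na(keep)] <- FALSE
  if (require_outcome) {
    if (!all(c("time", "event") %in% names(meta)))
      stop2("require_outcome needs time and event columns")
    keep <- keep & !is.na(meta$time) & !is.na(meta$event)
  }
  if (!is.null(er_status)) {
    if (!"er_status" %in% names(meta)) stop2("meta has no er_status column")
    keep <- keep & !is.na(meta$er_status) & meta$er_status == er_status
  }
  out <- meta[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("cohort filter returned no samples", call. = FALSE)
  attr(out, "age_rule") <- paste0("age ", if (inclusive) "<= " else "< ", max_age)
  if ("study" %in% names(meta)) {
    before <- table(meta$study)
    after <- table(factor(out$study, levels = names(before)))
    attr(out, "attrition") <- data.frame(study = names(before),
                                         n_before = as.vector(before),
                                         n_after = as.vector(after))
  }
  out
}
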