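#' Load a PAM50 centroid panel
#'
#' Returns the packaged centroid table as a 50-gene x 5-subtype matrix with
#' a `groups` attribute assigning each gene to a biological block
#' (proliferation / er / her2 / basal / other) used for the continuous
#' proliferation, ER and HER2 scores. The packaged panel is *synthetic*: it
#' reproduces the structure of the published subtype centroids (proliferation
#' genes high in Basal and LumB, the ER block high in luminal subtypes,
#' ERBB2/GRB7 high in Her2) over the 50 PAM50 gene symbols, not the
#' published values; supply your own table for real data.
#'
#' @param path Optional path to a custom centroid TSV with columns `gene`,
#'   `luma`, `lumb`, `her2`, `basal`, `normal` and optionally `group`.
#' @return Genes x subtypes numeric matrix (subtype columns `LumA`, `LumB`,
#'   `Her2`, `Basal`, `Normal`) with a `groups` attribute.
#' @export
pam50_centroids <- function(path = NULL) {
  path <- path %||% system.file("extdata", "pam50_centroids_synthetic.tsv",
                                package = "ppbcsig", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "luma", "lumb", "her2", "basal", "normal")
  if (!all(need %in% names(df)))
    stop2("centroid table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene)) stop2("duplicated genes in centroid table")
  m <- as.matrix(df[, c("luma", "lumb", "her2", "basal", "normal")])
  dimnames(m) <- list(df$gene, c("LumA", "LumB", "Her2", "Basal", "Normal"))
  if ("group" %in% names(df))
    attr(m, "groups") <- stats::setNames(df$group, df$gene)
  m
}

#' Nearest-centroid PAM50 subtype assignment
#'
#' Each sample's profile over the centroid panel genes is compared with
#' every subtype centroid by Spearman correlation and assigned the argmax
#' subtype. Spearman makes the call invariant to any strictly monotone
#' per-sample transform of expression, which is what makes single-sample
#' use across platforms defensible. Exact correlation ties are flagged and
#' resolved to the lexicographically first subtype.
#'
#' @param expr Log-scale genes x samples matrix.
#' @param centroids Centroid matrix from [pam50_centroids()] (or compatible).
#' @param min_overlap Minimum panel genes required in `expr` (default 40).
#' @return Data frame: `sample`, `subtype`, `tied` (comma-joined tied
#'   subtypes or `NA`), one `cor_*` column per centroid, and — when the
#'   panel carries gene groups — continuous `score_proliferation`,
#'   `score_er`, `score_her2` (mean expression of the group's genes).
#' @export
pam50_assign <- function(expr, centroids, min_overlap = 40L) {
  check_matrix(expr, "expression")
  genes <- intersect(rownames(centroids), rownames(expr))
  if (length(genes) < min_overlap)
    stop2("only ", length(genes), " centroid panel genes present; needs >= ",
          min_overlap)
  ex <- expr[genes, , drop = FALSE]
  ce <- centroids[genes, , drop = FALSE]
  cors <- stats::cor(ex, ce, method = "spearman")
  subtype <- character(ncol(ex)); tied <- rep(NA_character_, ncol(ex))
  for (i in seq_len(nrow(cors))) {
    best <- colnames(cors)[cors[i, ] == max(cors[i, ])]
    if (length(best) > 1) tied[i] <- paste(sort(best), collapse = ",")
    subtype[i] <- sort(best)[1]
  }
  out <- data.frame(sample = colnames(ex), subtype = subtype, tied = tied,
                    row.names = NULL)
  colnames(cors) <- paste0("cor_", colnames(cors))
  out <- cbind(out, as.data.frame(cors, row.names = NULL))
  grp <- attr(centroids, "groups")
  if (!is.null(grp)) {
    for (g in c("proliferation", "er", "her2")) {
      gg <- intersect(names(grp)[grp == g], rownames(expr))
      if (length(gg))
        out[[paste0("score_", g)]] <-
          colMeans(expr[gg, , drop = FALSE])
    }
  }
  attr(out, "correlation") <- "spearman"
  out
}

# 21-gene recurrence score panel: 16 targets + 5 reference genes, with the
# published group coefficients and floors (from the recurrence-score
# publications the assay derives from; the +10 reference normalization is
# the only equation restated here).
oncotype_genes <- list(
  reference = c("ACTB", "GAPDH", "GUSB", "RPLP0", "TFRC"),
  her2 = c(GRB7 = 0.9, ERBB2 = 0.1),
  er = c(ESR1 = 0.8, PGR = 1.2, BCL2 = 1, SCUBE2 = 1),
  proliferation = c("MKI67", "AURKA", "BIRC5", "CCNB1", "MYBL2"),
  invasion = c("MMP11", "CTSV"),
  single = c("CD68", "GSTM1", "BAG1"))

#' Pseudo 21-gene recurrence score
#'
#' Computes a research-grade analogue of the 21-gene recurrence score from
#' expression values. Per sample, each target gene is normalized as
#' `g' = g - mean(reference genes) + 10`; group scores are then
#' `HER2 = 0.9*GRB7 + 0.1*ERBB2` (floored at 8),
#' `ER = (0.8*ESR1 + 1.2*PGR + BCL2 + SCUBE2)/4`,
#' `proliferation = mean(MKI67, AURKA, BIRC5, CCNB1, MYBL2)` (floored at
#' 6.5), `invasion = mean(MMP11, CTSV)`; and the unscaled score is
#' `RS_u = 0.47*HER2 - 0.34*ER + 1.04*proliferation + 0.10*invasion +
#' 0.05*CD68 - 0.08*GSTM1 - 0.07*BAG1`, rescaled to
#' `RS = 20*(RS_u - 6.7)` and clipped to \[0, 100\]. The reference
#' normalization makes RS invariant to adding a constant to every gene.
#'
#' @param expr Genes x samples expression matrix. With
#'   `expr_scale = "linear"` values are `log2(x + 1)` transformed first;
#'   the scale used is recorded in the result's `expr_scale` attribute.
#' @param expr_scale `"log2"` (default) or `"linear"`.
#' @return Data frame per sample: the four group scores, the three single
#'   genes, `rs_unscaled` and `rs`.
#' @export
oncotype_rs <- function(expr, expr_scale = c("log2", "linear")) {
  expr_scale <- match.arg(expr_scale)
  check_matrix(expr, "expression")
  if (expr_scale == "linear") expr <- log2(expr + 1)
  og <- oncotype_genes
  targets <- c(names(og$her2), names(og$er), og$proliferation, og$invasion,
               og$single)
  absent <- setdiff(c(og$reference, targets), rownames(expr))
  if (length(absent))
    stop2("missing recurrence-score gene(s): ", paste(absent, collapse = ", "))
  ref_mean <- colMeans(expr[og$reference, , drop = FALSE])
  norm <- sweep(expr[targets, , drop = FALSE], 2, ref_mean, "-") + 10
  her2 <- pmax(colSums(norm[names(og$her2), , drop = FALSE] * og$her2), 8)
  er <- colSums(norm[names(og$er), , drop = FALSE] * og$er) / 4
  prolif <- pmax(colMeans(norm[og$proliferation, , drop = FALSE]), 6.5)
  invasion <- colMeans(norm[og$invasion, , drop = FALSE])
  rs_u <- 0.47 * her2 - 0.34 * er + 1.04 * prolif + 0.10 * invasion +
    0.05 * norm["CD68", ] - 0.08 * norm["GSTM1", ] - 0.07 * norm["BAG1", ]
  rs <- pmin(pmax(20 * (rs_u - 6.7), 0), 100)
  out <- data.frame(sample = colnames(expr), her2_group = her2,
                    er_group = er, proliferation_group = prolif,
                    invasion_group = invasion, cd68 = norm["CD68", ],
                    gstm1 = norm["GSTM1", ], bag1 = norm["BAG1", ],
                    rs_unscaled = rs_u, rs = rs, row.names = NULL)
  attr(out, "expr_scale") <- expr_scale
  out
}

#' Hierarchical clustering on a gene panel
#'
#' Restricts the expression matrix to a gene panel (e.g. the Mammaprint or
#' PAM50 gene lists) and delegates to [cluster_samples()] (z-score rows,
#' Euclidean distance, average linkage).
#'
#' @param expr Log-scale genes x samples matrix.
#' @param panel Character vector of panel genes; genes absent from `expr`
#'   are dropped, an empty intersection is an error.
#' @export
panel_cluster <- function(expr, panel) {
  genes <- intersect(panel, rownames(expr))
  if (!length(genes)) stop2("no panel genes present in expression matrix")
  cluster_samples(expr, genes = genes)
}
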