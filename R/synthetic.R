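#' Configuration for the synthetic PPBC/NPBC cohort generator
#'
#' Bundles and validates every parameter of the simulators. Defaults emulate
#' the study design the pipeline targets: an FFPE bulk RNA-seq cohort of 7
#' nulliparous (NPBC) and 9 postpartum (PPBC) ER+ young-women's breast
#' cancers, with cell-cycle and immunity programs up-regulated in PPBC,
#' ESR1-like and TP53-like regulon targets down-regulated, a T-cell
#' repertoire that is richer but more clonally expanded in PPBC, and
#' proportional-hazards survival driven by the planted composite signature.
#'
#' @param n_samples_per_group Integer vector of length 1 or 2: samples in
#'   (NPBC, PPBC). A single value is used for both groups.
#' @param n_genes Number of genes simulated.
#' @param nb_dispersion Shared negative-binomial size parameter (larger =
#'   less overdispersed).
#' @param library_size_mean Mean sequencing depth per sample; realized
#'   library sizes are log-normal with CV 0.2 so CPM differs from raw counts.
#' @param program_effect_log2fc Planted log2 fold change for the designated
#'   programs and planted regulons (PPBC relative to NPBC).
#' @param n_regulons Number of regulons emitted (>= 3; the first three are
#'   the planted E2F1-like, ESR1-like and TP53-like regulons).
#' @param targets_per_regulon Targets per regulon.
#' @param clone_alpha Power-law exponent of NPBC clone frequencies.
#' @param clone_alpha_shift Added to `clone_alpha` for PPBC samples (heavier
#'   tail, i.e. more clonal).
#' @param n_clones_per_group Integer vector of length 1 or 2: underlying
#'   clonotype richness in (NPBC, PPBC).
#' @param clone_reads TCR reads sampled per repertoire.
#' @param surv_beta Log hazard ratio per unit composite score.
#' @param baseline_hazard Baseline hazard per month.
#' @param censor_horizon_months Administrative censoring time (months).
#' @param seed Master seed; counts, clonotypes and survival each use an
#'   independent stream derived from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples_per_group = c(7L, 9L),
                       n_genes = 5000L,
                       nb_dispersion = 10,
                       library_size_mean = 1e6,
                       program_effect_log2fc = 2,
                       n_regulons = 10L,
                       targets_per_regulon = 40L,
                       clone_alpha = 1.5,
                       clone_alpha_shift = 0.15,
                       n_clones_per_group = c(300L, 1000L),
                       clone_reads = 20000L,
                       surv_beta = log(2),
                       baseline_hazard = 0.01,
                       censor_horizon_months = 180,
                       seed = 1L) {
  n_samples_per_group <- as.integer(rep_len(n_samples_per_group, 2L))
  n_clones_per_group <- as.integer(rep_len(n_clones_per_group, 2L))
  cfg <- list(n_samples_per_group = n_samples_per_group,
              n_genes = as.integer(n_genes),
              nb_dispersion = nb_dispersion,
              library_size_mean = library_size_mean,
              program_effect_log2fc = program_effect_log2fc,
              n_regulons = as.integer(n_regulons),
              targets_per_regulon = as.integer(targets_per_regulon),
              clone_alpha = clone_alpha,
              clone_alpha_shift = clone_alpha_shift,
              n_clones_per_group = n_clones_per_group,
              clone_reads = as.integer(clone_reads),
              surv_beta = surv_beta,
              baseline_hazard = baseline_hazard,
              censor_horizon_months = censor_horizon_months,
              seed = as.integer(seed))
  if (any(cfg$n_samples_per_group < 1)) stop2("n_samples_per_group must be >= 1")
  if (cfg$n_genes < 1) stop2("n_genes must be >= 1")
  if (cfg$nb_dispersion <= 0) stop2("nb_dispersion must be > 0")
  if (cfg$library_size_mean <= 0) stop2("library_size_mean must be > 0")
  if (cfg$n_regulons < 3) stop2("n_regulons must be >= 3 (planted regulons)")
  if (cfg$targets_per_regulon < 1) stop2("targets_per_regulon must be >= 1")
  if (cfg$clone_alpha <= 0) stop2("clone_alpha must be > 0")
  if (any(cfg$n_clones_per_group < 1)) stop2("n_clones_per_group must be >= 1")
  if (cfg$clone_reads < 1) stop2("clone_reads must be >= 1")
  if (cfg$baseline_hazard <= 0) stop2("baseline_hazard must be > 0")
  if (cfg$censor_horizon_months < 0) stop2("censor_horizon_months must be >= 0")
  needed <- 100L + cfg$n_regulons * cfg$targets_per_regulon
  if (cfg$n_genes < needed + 100L)
    stop2("n_genes too small for the planted layout; need at least ",
          needed + 100L)
  class(cfg) <- "sim_config"
  cfg
}

# planted gene layout: fixed blocks so truth is reconstructable from cfg
sim_layout <- function(cfg) {
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  t <- cfg$targets_per_regulon
  cc <- genes[1:50]                      # cell-cycle-like program
  imm <- genes[51:100]                   # immunity-like program
  exh <- imm[1:25]                       # exhaustion subset of immunity
  at <- 100L
  reg_targets <- lapply(seq_len(cfg$n_regulons), function(i)
    genes[(at + (i - 1L) * t + 1L):(at + i * t)])
  tf_names <- c("E2F1", "ESR1", "TP53",
                if (cfg$n_regulons > 3)
                  sprintf("TF%02d", seq_len(cfg$n_regulons - 3L)))
  names(reg_targets) <- tf_names
  list(genes = genes, cell_cycle = cc, immunity = imm, exhaustion = exh,
       reg_targets = reg_targets)
}

#' Simulate a full synthetic PPBC/NPBC cohort
#'
#' Draws negative-binomial counts (shared size `nb_dispersion`, per-gene
#' baseline means log-normal with meanlog 4 and sdlog 1.5, library sizes
#' log-normal around `library_size_mean` with CV 0.2), plants the group
#' structure described in [sim_config()], and attaches clonotype tables and
#' survival outcomes. Program genes and planted-regulon targets are driven by
#' per-sample latent activities (group shift of `program_effect_log2fc` on
#' the log2 scale plus N(0, 0.3) noise), so regulon targets co-vary within a
#' sample as real regulons do. Output is byte-identical for identical
#' configurations.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `counts` (genes x samples integer matrix),
#'   `meta` (sample annotations incl. simulated survival), `gene_sets`
#'   (named list incl. `cell_cycle`, `immunity`, `exhaustion` and random
#'   null sets), `regulons` (edge table; TFs `E2F1`, `ESR1`, `TP53` are the
#'   planted ones), `clonotypes`, and `truth` (planted per-gene effects,
#'   latent activities, the per-sample planted composite and the true
#'   hazard coefficient `beta`).
#' @export
simulate_cohort <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop2("cfg must be a sim_config object")
  lay <- sim_layout(cfg)
  n1 <- cfg$n_samples_per_group[1]; n2 <- cfg$n_samples_per_group[2]
  n <- n1 + n2
  samples <- sprintf("S%03d", seq_len(n))
  parity <- rep(c("NPBC", "PPBC"), c(n1, n2))
  lfc <- cfg$program_effect_log2fc

  out <- with_seed(stream_seed(cfg$seed, 1L), {
    mu0 <- stats::rlnorm(cfg$n_genes, meanlog = 4, sdlog = 1.5)
    names(mu0) <- lay$genes
    lib_sd <- sqrt(log(1 + 0.2^2))
    lib <- stats::rlnorm(n, log(cfg$library_size_mean) - lib_sd^2 / 2, lib_sd)

    # regulon edge table: planted TFs are pure activators (mode +1) so their
    # planted shifts are sign-coherent; null TFs mix modes.
    edges <- do.call(rbind, lapply(names(lay$reg_targets), function(tf) {
      tg <- lay$reg_targets[[tf]]
      mode <- if (tf %in% c("E2F1", "ESR1", "TP53")) rep(1, length(tg))
              else sample(c(-1, 1), length(tg), replace = TRUE)
      data.frame(tf = tf, target = tg, mode = mode,
                 likelihood = stats::runif(length(tg), 0.5, 1))
    }))

    # latent per-sample activities: planted shift for the named programs /
    # regulons in PPBC, zero elsewhere; sd 0.3 biological noise.
    is_pp <- as.numeric(parity == "PPBC")
    latent_act <- function(shift) stats::rnorm(n, shift * is_pp, 0.3)
    act <- rbind(cell_cycle = latent_act(lfc),
                 immunity   = latent_act(lfc),
                 E2F1       = latent_act(lfc),
                 ESR1       = latent_act(-lfc),
                 TP53       = latent_act(-lfc))
    if (cfg$n_regulons > 3) {
      null_act <- t(vapply(seq_len(cfg$n_regulons - 3L),
                           function(i) latent_act(0), numeric(n)))
      rownames(null_act) <- sprintf("TF%02d", seq_len(cfg$n_regulons - 3L))
      act <- rbind(act, null_act)
    }
    colnames(act) <- samples

    # per-gene x per-sample log2 fold over baseline
    logfold <- matrix(0, cfg$n_genes, n, dimnames = list(lay$genes, samples))
    logfold[lay$cell_cycle, ] <- rep(act["cell_cycle", ], each = 50)
    logfold[lay$immunity, ] <- rep(act["immunity", ], each = 50)
    for (tf in names(lay$reg_targets)) {
      e <- edges[edges$tf == tf, ]
      logfold[e$target, ] <- logfold[e$target, ] +
        (e$mode * e$likelihood) %o% act[tf, ]
    }

    mus <- mu0 * 2^logfold
    mus <- sweep(mus, 2, colSums(mus) / lib, "/")
    counts <- matrix(stats::rnbinom(length(mus), mu = mus,
                                    size = cfg$nb_dispersion),
                     cfg$n_genes, n, dimnames = dimnames(mus))

    # gene sets: planted programs plus null sets drawn from all genes
    gene_sets <- list(cell_cycle = lay$cell_cycle, immunity = lay$immunity,
                      exhaustion = lay$exhaustion)
    for (i in 1:5)
      gene_sets[[sprintf("null_set_%02d", i)]] <- sample(lay$genes, 50)

    truth_genes <- rbind(
      data.frame(gene = lay$cell_cycle, program = "cell_cycle",
                 planted_log2fc = lfc),
      data.frame(gene = lay$immunity, program = "immunity",
                 planted_log2fc = lfc))
    for (tf in c("E2F1", "ESR1", "TP53")) {
      s <- if (tf == "E2F1") lfc else -lfc
      e <- edges[edges$tf == tf, ]
      truth_genes <- rbind(truth_genes,
        data.frame(gene = e$target, program = paste0("regulon_", tf),
                   planted_log2fc = e$mode * e$likelihood * s))
    }
    list(counts = counts, edges = edges, act = act, gene_sets = gene_sets,
         truth_genes = truth_genes)
  })

  meta <- data.frame(sample_id = samples, parity = parity,
                     er_status = "positive", study = "synthetic_cohort",
                     age_at_diagnosis = with_seed(
                       stream_seed(cfg$seed, 4L),
                       sample(28:45, n, replace = TRUE)))

  # planted composite drives survival: exhaustion (immunity latent) + E2F1
  # - TP53 - ESR1
  comp <- out$act["immunity", ] + out$act["E2F1", ] -
    out$act["TP53", ] - out$act["ESR1", ]
  surv <- simulate_survival(comp, cfg)
  meta$time <- surv$time[match(meta$sample_id, surv$sample_id)]
  meta$event <- surv$event[match(meta$sample_id, surv$sample_id)]

  clono <- simulate_clonotypes(cfg, parity = parity, samples = samples)

  list(counts = out$counts, meta = meta, gene_sets = out$gene_sets,
       regulons = out$edges, clonotypes = clono,
       truth = list(genes = out$truth_genes, latent = out$act,
                    composite = comp, beta = cfg$surv_beta))
}

#' Simulate T-cell clonotype tables
#'
#' Per sample, clone frequencies follow a discrete power law over clone
#' ranks, `f_k` proportional to `k^-alpha`, and observed counts are a
#' multinomial draw of `clone_reads` reads. PPBC samples use more underlying
#' clones and a heavier tail (`clone_alpha + clone_alpha_shift`) so expected
#' observed richness is higher while expected normalized entropy is lower
#' (more clonal), matching the repertoire contrast the pipeline looks for.
#'
#' @param cfg A [sim_config()].
#' @param parity Optional character vector of group labels ("NPBC"/"PPBC");
#'   defaults to the config's group sizes.
#' @param samples Optional sample IDs aligned with `parity`.
#' @return A clonotype table (`sample_id`, `clonotype_key`, `count`).
#' @export
simulate_clonotypes <- function(cfg, parity = NULL, samples = NULL) {
  if (!inherits(cfg, "sim_config")) stop2("cfg must be a sim_config object")
  if (is.null(parity))
    parity <- rep(c("NPBC", "PPBC"), cfg$n_samples_per_group)
  if (is.null(samples)) samples <- sprintf("S%03d", seq_along(parity))
  with_seed(stream_seed(cfg$seed, 2L), {
    rows <- lapply(seq_along(samples), function(i) {
      pp <- parity[i] == "PPBC"
      n_clones <- cfg$n_clones_per_group[if (pp) 2L else 1L]
      alpha <- cfg$clone_alpha + if (pp) cfg$clone_alpha_shift else 0
      p <- seq_len(n_clones)^(-alpha); p <- p / sum(p)
      cnt <- stats::rmultinom(1, cfg$clone_reads, p)[, 1]
      keep <- cnt > 0
      data.frame(sample_id = samples[i],
                 clonotype_key = sprintf("TRBV%02d-C%06d-TRBJ%d",
                                         (which(keep) %% 30L) + 1L,
                                         which(keep),
                                         (which(keep) %% 13L) + 1L),
                 count = cnt[keep])
    })
    validate_clonotypes(do.call(rbind, rows))
  })
}

#' Simulate survival outcomes from a composite score
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(surv_beta * score)` and administratively censored
#' at `censor_horizon_months`.
#'
#' @param scores Named numeric vector of per-sample scores (names = sample
#'   IDs), or a single-column samples x scores matrix.
#' @param cfg A [sim_config()]; `surv_beta`, `baseline_hazard`,
#'   `censor_horizon_months` and `seed` are used.
#' @return Data frame `sample_id`, `time` (months), `event` (1 = death).
#' @export
simulate_survival <- function(scores, cfg) {
  if (!inherits(cfg, "sim_config")) stop2("cfg must be a sim_config object")
  if (is.matrix(scores)) {
    nm <- rownames(scores); scores <- scores[, 1]; names(scores) <- nm
  }
  if (is.null(names(scores)))
    names(scores) <- sprintf("S%03d", seq_along(scores))
  if (anyDuplicated(names(scores))) stop2("one score per sample required")
  with_seed(stream_seed(cfg$seed, 3L), {
    haz <- cfg$baseline_hazard * exp(cfg$surv_beta * scores)
    t <- stats::rexp(length(scores), rate = haz)
    event <- as.integer(t <= cfg$censor_horizon_months)
    t <- pmin(t, cfg$censor_horizon_months)
    data.frame(sample_id = names(scores), time = t, event = event,
               row.names = NULL)
  })
}

#' Write a simulated cohort to plain-text files
#'
#' Emits `counts.tsv`, `meta.csv`, `genesets.gmt`, `regulons.tsv`,
#' `clonotypes.tsv` and `truth.tsv` into `dir`.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @export
write_sim_output <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  write_meta(sim$meta, file.path(dir, "meta.csv"))
  write_gmt(sim$gene_sets, file.path(dir, "genesets.gmt"))
  write_regulons(sim$regulons, file.path(dir, "regulons.tsv"))
  write_clonotypes(sim$clonotypes, file.path(dir, "clonotypes.tsv"))
  utils::write.table(sim$truth$genes, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
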