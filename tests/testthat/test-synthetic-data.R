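test_that("sim_config validates its parameters", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(n_samples_per_group = 0), "n_samples_per_group")
  expect_error(sim_config(clone_alpha = -1), "clone_alpha")
  expect_error(sim_config(baseline_hazard = 0), "baseline_hazard")
  expect_error(sim_config(n_genes = 300), "n_genes")
  expect_error(simulate_cohort(list()), "sim_config")
})

test_that("simulate_cohort is byte-identical under a fixed seed", {
  cfg <- sim_config(n_samples_per_group = c(4, 4), n_genes = 600,
                    targets_per_regulon = 15, n_clones_per_group = c(50, 80),
                    clone_reads = 2000, seed = 42)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("simulated cohorts are internally consistent", {
  cfg <- sim_config(n_samples_per_group = c(5, 6), n_genes = 700,
                    targets_per_regulon = 20, n_clones_per_group = c(60, 90),
                    clone_reads = 3000, seed = 7)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$truth$genes$gene %in% rownames(sim$counts)))
  expect_true(all(sim$regulons$target %in% rownames(sim$counts)))
  expect_true(all(unlist(sim$gene_sets) %in% rownames(sim$counts)))
  expect_identical(colnames(sim$counts), sim$meta$sample_id)
  # clone frequencies are a partition per sample
  freq_sums <- tapply(sim$clonotypes$count, sim$clonotypes$sample_id,
                      function(cnt) sum(cnt / sum(cnt)))
  expect_equal(as.vector(freq_sums), rep(1, nrow(sim$meta)), tolerance = 1e-9)
})

test_that("no planted effect leaves group log-ratios centered on zero", {
  cfg <- sim_config(n_samples_per_group = 50, program_effect_log2fc = 0,
                    n_genes = 700, targets_per_regulon = 20,
                    n_clones_per_group = c(30, 30), clone_reads = 1000,
                    seed = 8)
  sim <- simulate_cohort(cfg)
  cpm <- compute_cpm(sim$counts)
  pp <- sim$meta$parity == "PPBC"
  lr <- log2((rowMeans(cpm[, pp]) + 1) / (rowMeans(cpm[, !pp]) + 1))
  expect_lt(abs(mean(lr)), 0.1)
})

test_that("planted program genes show the configured fold change", {
  cfg <- sim_config(n_samples_per_group = 20, program_effect_log2fc = 2,
                    seed = 9)
  sim <- simulate_cohort(cfg)
  cpm <- compute_cpm(sim$counts)
  pp <- sim$meta$parity == "PPBC"
  prog <- sim$truth$genes$gene[sim$truth$genes$program %in%
                                 c("cell_cycle", "immunity")]
  lr <- log2((rowMeans(cpm[prog, pp]) + 1) / (rowMeans(cpm[prog, !pp]) + 1))
  expect_lt(abs(mean(lr) - 2), 0.3)
})

test_that("degenerate clonotype settings behave as limits", {
  one <- sim_config(n_clones_per_group = 1, clone_reads = 500, seed = 1,
                    n_samples_per_group = c(2, 2))
  tab <- simulate_clonotypes(one)
  per <- split(tab, tab$sample_id)
  expect_true(all(vapply(per, nrow, 1L) == 1))
  expect_true(all(tab$count == 500))

  # alpha ~ 0 approaches a uniform repertoire: clonality near zero
  unif <- sim_config(clone_alpha = 1e-9, clone_alpha_shift = 0,
                     n_clones_per_group = 200, clone_reads = 2e5,
                     n_samples_per_group = c(3, 3), seed = 2)
  met <- repertoire_metrics(simulate_clonotypes(unif))
  expect_true(all(met$clonality < 0.02))
})

test_that("sampled Gini matches a large-draw Monte-Carlo oracle", {
  cfg <- sim_config(clone_alpha = 1.5, clone_alpha_shift = 0,
                    n_clones_per_group = 1000, clone_reads = 20000,
                    n_samples_per_group = c(5, 5), seed = 3)
  g <- mean(gini_index(simulate_clonotypes(cfg))$gini)
  # oracle: independent 10^6-draw multinomial repertoires
  p <- (1:1000)^(-1.5); p <- p / sum(p)
  set.seed(99)
  oracle <- mean(replicate(5, {
    cnt <- rmultinom(1, 1e6, p)[, 1]; cnt <- cnt[cnt > 0]
    gini_pairwise(cnt / sum(cnt))
  }))
  expect_lt(abs(g - oracle), 0.05)
})

test_that("PPBC repertoires are richer but less even by construction", {
  cfg <- sim_config(n_samples_per_group = c(8, 8), seed = 5)
  tab <- simulate_clonotypes(cfg)
  met <- repertoire_metrics(tab)
  grp <- ifelse(met$sample_id %in% sprintf("S%03d", 1:8), "NPBC", "PPBC")
  expect_gt(mean(met$richness[grp == "PPBC"]),
            mean(met$richness[grp == "NPBC"]))
  expect_lt(mean(met$entropy_norm[grp == "PPBC"]),
            mean(met$entropy_norm[grp == "NPBC"]))
})

test_that("simulate_survival follows the planted hazard model", {
  cfg0 <- sim_config(censor_horizon_months = 0, seed = 4,
                     n_samples_per_group = c(3, 3))
  s0 <- simulate_survival(setNames(rnorm(6), sprintf("x%d", 1:6)), cfg0)
  expect_true(all(s0$time == 0))
  expect_true(all(s0$event == 0))

  # true HR = 2 between score 1 and score 0 arms, no censoring
  cfg <- sim_config(surv_beta = log(2), baseline_hazard = 0.01,
                    censor_horizon_months = Inf, seed = 6)
  scores <- setNames(rep(c(0, 1), each = 500), sprintf("p%04d", 1:1000))
  sv <- simulate_survival(scores, cfg)
  lr <- logrank(sv$time, sv$event, factor(scores[sv$sample_id],
                                          levels = c(1, 0)))
  expect_gt(lr$hr, 1.6)
  expect_lt(lr$hr, 2.5)

  expect_error(simulate_survival(setNames(c(1, 2), c("a", "a")), cfg),
               "one score per sample")
})

test_that("null survival scores give a calibrated log-rank test", {
  # beta = 0: median-split HR CI should cover 1 in most replicates
  set.seed(123)
  cover <- 0
  for (r in 1:100) {
    cfg <- sim_config(surv_beta = 0, baseline_hazard = 0.02,
                      censor_horizon_months = 120, seed = 1000 + r)
    scores <- setNames(rnorm(60), sprintf("q%03d", 1:60))
    sv <- simulate_survival(scores, cfg)
    if (sum(sv$event) == 0) next
    split <- median_split(scores)[sv$sample_id]
    lr <- logrank(sv$time, sv$event, split)
    if (lr$hr_ci95[1] <= 1 && 1 <= lr$hr_ci95[2]) cover <- cover + 1
  }
  expect_gte(cover, 90)
})

test_that("write_sim_output round-trips through the plain-text formats", {
  cfg <- sim_config(n_samples_per_group = c(3, 3), n_genes = 600,
                    targets_per_regulon = 12, n_clones_per_group = c(20, 30),
                    clone_reads = 500, seed = 10)
  sim <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_sim_output(sim, dir)
  expect_equal(read_counts(file.path(dir, "counts.tsv")), sim$counts)
  expect_equal(read_meta(file.path(dir, "meta.csv"))$sample_id,
               sim$meta$sample_id)
  expect_equal(read_gmt(file.path(dir, "genesets.gmt")), sim$gene_sets)
  regs <- read_regulons(file.path(dir, "regulons.tsv"))
  expect_equal(regs$target, sim$regulons$target)
  expect_equal(regs$likelihood, sim$regulons$likelihood, tolerance = 1e-9)
})
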