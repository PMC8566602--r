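# ppbcsig

Transcriptomic characterization of **postpartum breast cancer (PPBC)**
versus **nulliparous breast cancer (NPBC)** in ER+ young women, and a
composite regulon signature for survival stratification.

Breast cancer arising within a few years of childbirth carries worse
prognosis than comparable nulliparous disease. `ppbcsig` implements, as a
tested R pipeline, the analyses used to characterize that difference from
bulk RNA-seq counts and to turn it into a prognostic score:

* **Preprocessing / DE** — CPM normalization, expression filtering
  (CPM > 0.05 in ≥ 3 samples of every group), per-gene Welch t on
  `log2(cpm+1)` with Benjamini–Hochberg FDR, z-score/Euclidean/average-
  linkage sample clustering.
* **Enrichment** — weighted Kolmogorov–Smirnov GSEA: hits increment the
  running sum by `|s|^p / Σ_hits |s|^p`, misses by `−1/(N−N_hits)`;
  ES = signed max deviation; permutation NES and nominal p. Single-sample
  gene-set scores as mean per-gene z.
* **Regulons** — single-sample TF activity
  `A = Σ_t w_t m_t z_t / sqrt(Σ_t w_t²)` over rank-normal gene scores
  `z = Φ⁻¹((rank−½)/N)`, master-regulator ranking with permutation p, and
  the composite signature `P = A_exhaustion + A_E2F1 − A_TP53 − A_ESR1`.
* **Subtype scores** — PAM50 nearest-centroid assignment (Spearman) and a
  pseudo 21-gene recurrence score (`g′ = g − mean(reference) + 10`,
  published group coefficients and floors, `RS = 20(RS_u − 6.7)` clipped
  to [0, 100]).
* **TCR repertoire** — richness, Shannon entropy `H = −Σ f_k ln f_k`,
  clonality `C = 1 − H/ln n`, Gini index, clonal-space occupancy.
* **Survival** — Kaplan–Meier, log-rank (Mantel–Cox) with O/E hazard ratio
  `(O_A/E_A)/(O_B/E_B)`, median-split stratification, 15-year follow-up
  truncation.
* **Cohort assembly** — probe→gene collapsing, per-study location-scale
  standardization, young-age (≤ 45) / outcome / ER filtering.
* **Synthetic data** — a seeded generator (`simulate_cohort()`) producing
  counts, metadata, gene sets, regulons, clonotypes and survival with the
  planted structure the analysis assumes, so the full pipeline runs
  offline.

See `vignettes/ppbc-pipeline.Rmd` for the model details, parameter
conventions and known limitations.

## Worked example

```r
library(ppbcsig)

cfg <- sim_config(seed = 7)            # 7 NPBC + 9 PPBC, 5000 genes
sim <- simulate_cohort(cfg)

counts <- filter_expressed(sim$counts, sim$meta$parity)
de     <- de_test(counts, sim$meta$parity, ref = "NPBC")
expr   <- log2_cpm(counts)

act    <- regulon_activity(expr, sim$regulons)
scores <- cbind(t(act),
                exhaustion = signature_score(expr, sim$gene_sets$exhaustion))
comp   <- ppbc_composite(scores)

logrank(sim$meta$time, sim$meta$event, median_split(comp)[sim$meta$sample_id])
```

This prints (seed 7):

```
kept 4992 of 5000 genes; 219 DEGs at FDR 0.1
Log-rank (Mantel-Cox): chi2 = 15.1547, p = 9.905e-05
HR (hi vs lo) = 4.6697 [95% CI 1.2911, 16.8898]
O/E: hi 8/2.8220, lo 8/13.1780
```

The filter keeps genes expressed in both parity groups; the differential
test recovers the planted cell-cycle/immunity programs; the composite
score — exhaustion and E2F1 activity up, TP53 and ESR1 down — is higher in
the signature-"hi" arm, which has ~4.7-fold the event rate of the "lo"
arm by the O/E hazard-ratio convention, with the two-tailed log-rank p
shown. Repertoire metrics come from the same object:

```r
head(repertoire_metrics(sim$clonotypes)[, c("sample_id", "richness",
                                            "entropy", "clonality")], 3)
#>   sample_id richness  entropy clonality
#> 1      S001      289 2.741454 0.5161935
#> 2      S002      283 2.723245 0.5176210
#> 3      S003      278 2.712943 0.5179236
```

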