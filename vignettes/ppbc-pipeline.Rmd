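---
title: "Methods: the postpartum breast cancer signature pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the postpartum breast cancer signature pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppbcsig)
```

## The scientific problem

Breast cancer diagnosed within a few years of childbirth (postpartum breast
cancer, PPBC) has worse outcomes than clinically similar cancer in
nulliparous women (NPBC), even within ER+ disease diagnosed at the same
young age. `ppbcsig` implements a transcriptomic pipeline for
characterizing that difference from bulk RNA-seq counts and for building a
composite prognostic score from it:

1. CPM filtering and two-group differential expression (Welch t on
   `log2(cpm+1)`, Benjamini--Hochberg FDR);
2. weighted Kolmogorov--Smirnov gene-set enrichment with permutation
   NES/nominal p, and single-sample gene-set scores (cell-cycle,
   immune-infiltrate, exhaustion);
3. single-sample transcription-factor regulon activities and a composite
   signature `P = A_exhaustion + A_E2F1 - A_TP53 - A_ESR1`;
4. PAM50 nearest-centroid subtyping and a pseudo 21-gene recurrence score;
5. TCR repertoire diversity (Shannon entropy, clonality, Gini,
   clonal-space occupancy);
6. Kaplan--Meier / log-rank median-split survival stratification with
   15-year truncation;
7. multi-study cohort assembly (probe collapsing, per-study
   standardization, young-age/outcome filtering).

A seeded synthetic-data generator emulates the statistical structure of
such a cohort so that every stage is testable offline. The exported
functions and this vignette are the interface; every file format the
pipeline consumes or emits (counts TSV, metadata CSV, GMT, regulon TSV,
AIRR-style clonotype TSV, long score tables) has a reader/writer pair.

## Differential expression: a deliberate simplification

The DE stage is a transparent stand-in for count-model machinery: genes are
kept when CPM exceeds 0.05 in at least three samples of *every* group, and
each gene is tested by a Welch t on `log2(cpm + 1)`, with the fold change
taken from pseudocounted group-mean CPM. The goal downstream is a ranked
signature (the t statistics feed GSEA and the master-regulator ranking) and
an FDR-controlled gene list — not replication of any specific shrinkage
estimator. Consequences: no dispersion sharing across genes, hence somewhat
less power at very small n than a count model would give, and fold-change
estimates that are compressed for weakly expressed genes by the
pseudocount. Both FDR thresholds in common use for such data (0.1, and the
stricter 0.01 with |log2FC| > 1) are exposed as plain parameters of the
caller's choosing; neither is hard-coded.

Variance-stabilized expression is likewise approximated by `log2(cpm + 1)`,
recorded in the matrix's `transform_tag` attribute.

## Enrichment scores

`enrichment_score()` is the classic weighted KS statistic: genes ordered by
decreasing signature score (ties broken lexicographically by symbol, so
results are reproducible), hits increment by `|s|^p` normalized over member
weights, misses decrement by `1/(N - N_hits)`, and the ES is the signed
maximum deviation of the running sum. `gsea()` calibrates it by
permutation. The default permutation mode resamples gene-set labels rather
than phenotypes: with cohorts of ~16 samples, phenotype permutation has too
few distinct relabelings to estimate small p values, so gene-set
permutation is the default and phenotype mode (>= 3 samples per group,
Welch signature recomputed per shuffle) is available by flag. NES divides
the observed ES by the mean magnitude of same-sign permuted ES; when no
same-sign permutations exist the NES and p are reported as missing rather
than extrapolated. Nominal p uses the add-one permutation convention, so it
is never exactly zero.

Single-sample gene-set scores are the mean per-gene z-score over member
genes. This is the simplest reproducible convention for "single sample
score"; a rank-based alternative (ssGSEA-style) would be monotone-invariant
but less interpretable as a standardized mean, and is intentionally not the
default. Constant genes contribute zero rather than NaN.

## Regulon activity and the composite signature

`regulon_activity()` rank-transforms each sample's profile across genes to
standard-normal quantile scores `z = qnorm((rank - 0.5)/N)` and combines a
regulon's targets as `A = sum(w * m * z) / sqrt(sum(w^2))`, with `m` the
mode of regulation in `[-1, 1]` and `w` the confidence weight in `(0, 1]`.
This is a two-tail simplification of the three-tail mode-weighted
estimator used by full regulon-inference suites: it preserves the sign
convention, the confidence weighting and the rank basis — the properties
the composite score depends on — while dropping implementation-specific
interaction terms. Activities are therefore comparable across samples and
invariant to monotone per-sample transforms and to uniform rescaling of
the weights. The minimum regulon size defaults to 10 targets present in
the matrix.

The composite score adds the immune-exhaustion and E2F1 activities and
subtracts TP53 and ESR1. The exhaustion component is a gene set, not a TF
regulon; it is scored by the same machinery with `m = +1`, `w = 1` for all
members (equivalently, `signature_score()` over the exhaustion set is
accepted wherever a score column named `exhaustion` is expected).
Unstandardized activities are used in the composite; because the four
components share the `1/sqrt(sum(w^2))` scaling they are on comparable
scales, and any common additive offset cancels in the signed sum.

## Subtype scores

PAM50 assignment is nearest-centroid by Spearman correlation (robust to
platform scale; verified invariant to strictly monotone per-sample
transforms). Exact ties are flagged and resolved to the lexicographically
first subtype. The packaged centroid panel is **synthetic**: it spans the
50 PAM50 gene symbols with subtype-like block structure (proliferation
genes high in Basal/LumB, the ER block high in luminals, ERBB2/GRB7 high
in Her2) and is intended for tests and demonstrations; for real data,
supply the published centroid table via `pam50_centroids(path = ...)`. At
least 40 panel genes must be present after intersection.

The pseudo recurrence score uses the published 21-gene equations: per
sample, target genes are normalized by subtracting the mean of the five
reference genes and adding 10; group scores are combined with coefficients
+0.47 (HER2 group, floored at 8), -0.34 (ER), +1.04 (proliferation,
floored at 6.5), +0.10 (invasion), +0.05 (CD68), -0.08 (GSTM1), -0.07
(BAG1); and `RS = 20*(RS_u - 6.7)` clipped to [0, 100]. Which expression
scale feeds the equations is a flag (`expr_scale`, default `"log2"`) and
is recorded in the output, since the choice changes the numeric scores
but not the reference-normalization invariance.

## TCR repertoire metrics

Frequencies are per-sample clone fractions. Shannon entropy uses natural
logs; clonality is `C = 1 - H/ln(n)`. For a single-clone repertoire the
formula is 0/0; the distributional limit `H = 0, C = 1` is used and the
sample is flagged (`single_clone`). Because "normalized Shannon entropy"
is used ambiguously in the repertoire literature, both `entropy` and
`entropy_norm = H/ln n` are emitted. The Gini index uses the mean-absolute-difference definition
(computed via sorted cumulative sums, with an O(n^2) pairwise oracle in the
tests). Clonal-space occupancy reports the fraction of repertoire *mass*
per frequency bin; default edges `(0, 1e-5, 1e-4, 1e-3, 1e-2, 1]` labelled
rare/small/medium/large/hyperexpanded are configurable and recorded in the
output attributes.

One caution surfaced by the property tests: splitting a clone into two
equal halves strictly increases H, but need **not** decrease clonality,
because the `ln(n)` denominator grows as well — near-uniform repertoires
are counterexamples. Conclusions about clonality should therefore rest on
the index itself, not on intuition about clone splitting.

## Survival analysis

`km_estimate()` is the product-limit estimator with tied events handled in
one risk-set step. `logrank()` is the Mantel--Cox test with hypergeometric
variance; the hazard ratio is the observed/expected ratio
`(O_A/E_A)/(O_B/E_B)` — the "log-rank HR" convention of survival-plotting
software, which is the convention matched by published median-split HRs —
with `exp(log HR ± 1.96*sqrt(1/E_A + 1/E_B))` as the 95% CI. A fitted
proportional-hazards coefficient would be the alternative; the O/E form is
primary here because it is the one the figures it supports use. Median
splits send ties at the median to "lo", so "hi" is strictly above the
median; 214 distinct scores split 107/107. Fifteen-year analyses truncate
follow-up at 180 months (`truncate_followup()`), censoring beyond-horizon
events; truncation is idempotent and optional.

## Multi-study assembly

Probes collapse to genes by arithmetic mean. Cross-study harmonization is
per-study location-scale standardization on the intersected gene space:
within each study every gene is centered and scaled to unit variance. This
removes additive and multiplicative batch effects exactly — it is the
no-shrinkage limit of empirical-Bayes batch correction — but also removes
genuine cross-study location signal, which is the documented cost of not
shipping a full empirical-Bayes implementation. Genes constant within a
study are set to zero there and flagged. The young-women age rule is a
parameter (`<= 45` by default, strict `< 45` available) because both
readings appear in practice; the rule applied and per-study attrition are
recorded in attributes, never chosen silently.

## The synthetic cohort generator

`simulate_cohort()` emulates the cohort structure the pipeline assumes,
with defaults fixed at study-like conditions:

* 7 NPBC + 9 PPBC samples, 5000 genes; negative-binomial counts with
  shared size 10; per-gene baseline means log-normal (meanlog 4, sdlog
  1.5), giving a bulk-RNA-seq-like dynamic range; library sizes log-normal
  around 10^6 with CV 0.2, so CPM genuinely differs from raw counts.
* Planted biology: 50 cell-cycle-like and 50 immunity-like program genes
  (25 of the latter forming the exhaustion set) shifted up in PPBC by
  `program_effect_log2fc` (default 2); planted regulons E2F1 (targets up),
  ESR1 and TP53 (targets down), each with 40 targets, modes +1 and
  likelihood ~ U(0.5, 1); effects are driven by per-sample latent
  activities (group shift + N(0, 0.3)), so targets co-vary within samples
  as real regulons do. The planted blocks are sized so that the
  composition bias CPM introduces when one group gains library mass stays
  near -0.1 log2 units; the effect-size defaults are conventional choices,
  as no fitted estimates exist for this biology.
* Clonotypes: discrete power-law frequencies over clone ranks with 20000
  reads per sample; NPBC uses 300 clones at exponent 1.5, PPBC 1000 clones
  at 1.65. A heavier tail alone *reduces* observed richness at finite read
  depth, so the PPBC richness advantage is carried by the larger clone
  count; these defaults give PPBC repertoires that are richer (~417 vs
  ~284 observed clonotypes) yet less even (normalized entropy ~0.40 vs
  ~0.48), the contrast the analysis expects.
* Survival: exponential times with hazard `lambda0 * exp(beta * score)`
  driven by the latent planted composite, `beta = ln 2` per unit and
  `lambda0 = 0.01`/month by default, administratively censored at 180
  months.

Each artifact section (counts, clonotypes, survival) draws from its own
RNG stream derived from the master seed, so sections can be regenerated
independently, and the whole output is byte-identical under a fixed
configuration.

What the generator does **not** emulate: FFPE degradation artifacts,
GC/length bias, correlated gene-gene noise beyond the planted latent
factors, realistic V(D)J sequence structure, or non-proportional hazards.
Passing tests therefore demonstrate that the algorithms recover known
structure under the stated model, not that the biological conclusions of
any particular cohort reproduce.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at deliberately modest sizes
chosen as adequate for their purpose: 5000-gene cohorts at 16--214 samples,
1000-permutation GSEA, 200-replicate null calibrations, and n = 500/group
survival simulations — enough for the calibration bands asserted (e.g.
type-I fraction in [0.03, 0.07] at 2000 null genes) without excess.
Degenerate inputs follow explicit conventions throughout: zero-variance
genes z-score to 0; sd-0 rows cluster at distance contributions of 0;
empty gene-set intersections, zero library sizes, zero events and
all-equal medians are errors naming the offender; dendrogram ties resolve
by lexicographic sample order; ranked-signature ties resolve by gene
symbol.
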