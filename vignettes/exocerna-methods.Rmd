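---
title: "Methods: ceRNA network biomarker analysis with exocerna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network biomarker analysis with exocerna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exocerna)
```

## The analysis

exocerna implements a competing-endogenous-RNA (ceRNA) biomarker workflow
for small two-arm transcriptomic studies, of the kind used to search plasma
exosomes for diagnostic markers of first-episode psychosis: a handful of
cases and matched controls, per-class expression tables for lncRNA, miRNA
and mRNA, externally predicted miRNA target tables, an annotation-set
collection and a scored protein-protein interaction (PPI) edge list.

The ceRNA hypothesis is directional: a lncRNA that sponges a miRNA
de-represses that miRNA's mRNA targets, so along a true lncRNA-miRNA-mRNA
axis the miRNA should move *opposite* to both partners between groups. The
pipeline operationalizes this in six steps.

1. **Differential expression.** Per feature, the log2 fold change is
   computed from pseudocount-shifted group means of the raw abundances and
   a two-sample pooled-variance Student's t-test is applied to
   log2(value + pseudocount). A feature is differentially expressed when
   it clears the conjunctive gate |log2FC| >= 1 (fold change >= 2 in either
   direction) *and* p <= 0.05, both boundaries inclusive. No
   multiple-testing correction enters the gate; a Benjamini–Hochberg column
   is emitted for transparency. This mirrors common raw-p filtering in
   small-n exosome studies and is a deliberate, documented choice, not a
   statistical recommendation.
2. **Directional network construction** (`build_cerna_network`). For the
   "up-miRNA" polarity: intersect the targets of up-regulated miRNAs with
   the down-regulated lncRNAs, reverse-identify the miRNAs that still hit
   that overlap (set A); repeat against down-regulated mRNAs (set B); the
   network's miRNAs are A ∩ B, and lncRNA/mRNA nodes are retained only
   while linked to a surviving miRNA, so no node is isolated. Edges are
   exactly the input target pairs among retained nodes. The mirrored
   polarity (down-miRNA, up-partners) is built the same way. This
   construction is provably equivalent to enumerating all admissible
   (lncRNA, miRNA, mRNA) triples directly, and the test suite checks that
   equivalence against a brute-force enumerator on a thousand random
   instances.
3. **Clinical correlation.** Partial Pearson correlation of each network
   feature's log2 expression with the PANSS positive, negative, general
   psychopathology and total scores, controlling age, sex (0/1) and
   education by least-squares residualization; p from
   t = r sqrt(df/(1-r^2)), df = n - 2 - k. Computed on cases only, since
   controls carry no PANSS scores.
4. **Over-representation analysis** (`ora`). Hypergeometric upper-tail test
   of the network mRNAs against any GMT collection, with the expressed mRNA
   set — not the genome — as the background universe, the defensible choice
   when the assay defines what could have been observed. Significance is
   raw p < 0.05 (strict), again mirroring field practice.
5. **PPI hubs.** The scored PPI edge list is filtered to edges strictly
   above 0.4 (the conventional medium-confidence score cut) with both
   endpoints among the network mRNAs; hubs are ranked by plain degree —
   the "connection count" hub notion — with lexicographic tie-breaks.
6. **ROC diagnostics.** Single-marker AUC is the Mann–Whitney pair-winning
   probability with ties credited one half; the empirical ROC curve's
   trapezoidal area equals it exactly. A lncRNA-miRNA-mRNA axis is pooled
   into one score by in-sample logistic regression on standardized
   features; the linear predictor is the combined marker. Orientation is
   fixed a priori (higher score = case) and AUCs below 0.5 are reported
   as-is, never flipped — a down-regulated miRNA legitimately shows an AUC
   near 0.

## The synthetic-data generator

Because the original raw data and external target databases are not
shipped, every downstream stage is exercised on simulated inputs with known
ground truth. `sim_config()` defaults encode the emulated study design:
10 cases and 10 controls, balanced sex (5/5 per arm), age ~ N(34, 12²) and
education ~ N(10.4, 3.4²) with no group shift, and PANSS subscores driven
by a shared latent severity factor calibrated so totals centre near 75.6
with SD ≈ 18.6 and respect the subscale floors (7/7/16); the total is the
exact sum of the three subscores.

Expression is log-normal: Gaussian on the log2 scale around a per-feature
baseline drawn from U(5, 10), exponentiated. Planted triplets shift the
miRNA by -`planted_log2fc` and its lncRNA/mRNA partners by
+`planted_log2fc` (default 2, with noise SD 0.5 — an effect size at which
a per-feature t-test at n = 10/10 has power ≈ 1, so recovery failures
indicate pipeline defects rather than sampling noise). Planted target
edges are always present; background edges appear independently with
probability `background_target_density`. Planted lncRNAs and mRNAs are
clinically linked: their case-sample log2 noise is mixed with the
empirically standardized PANSS total so the within-case correlation is
approximately `clinical_link_r` (default 0.8, matching the strength of the
severity correlations such an analysis reports for its lead lncRNA) while
the marginal noise SD stays `noise_sigma`, leaving DE behaviour untouched.
miRNAs carry no clinical link. The first annotation term concentrates the
planted mRNAs; the planted mRNAs are additionally wired as a
high-confidence PPI clique (scores U(0.6, 0.95)) over a sparse background.

What the generator does *not* emulate: sequencing counts and their
mean-variance relationship (abundances are emitted already normalized,
since the upstream normalization of the emulated assay is unreported),
library-size artefacts, batch effects, correlated background features, and
medication or longitudinal structure. Passing tests therefore demonstrate
the pipeline's logic and calibration under its own assumptions, not
robustness to real sequencing pathologies.

## Numerical and design choices

* **Pooled vs Welch t.** Default is the pooled-variance Student's t
  (df = n1 + n2 - 2), the textbook "Student's t-test"; Welch is available
  by flag. The demographic-table reproductions (p = 0.9124 for age,
  0.5227 for education at the published means/SDs) only hold under the
  pooled form.
* **Pseudocount 1.0** before the log2 transform; fold changes come from
  means of raw abundances shifted by the same pseudocount. At the
  simulated abundance scale (2^5–2^10) the transform is effectively
  linear, so t-test calibration is preserved (verified by the null
  Kolmogorov–Smirnov and binomial-calibration tests).
* **Chi-square without continuity correction** by default; a zero
  statistic yields p = 1 under either setting.
* **Perfect separation** in the logistic combiner — common at n = 10/10
  with strong markers — triggers a deterministic ridge-stabilized fit
  (fixed lambda = 0.1 on standardized features) with a logged notice.
  Duplicated (aliased) feature columns contribute zero coefficients, so a
  triplet of three identical features reproduces the single-marker AUC
  exactly. An optional leave-one-out mode gives the honest out-of-sample
  combined AUC; the in-sample AUC is the default because it matches how
  multi-marker panels are conventionally reported in this literature, and
  that optimism is precisely why the package documents both.
* **Ties.** AUC credits tied case-control pairs one half; ROC curves sweep
  unique score values, so ties produce diagonal segments whose trapezoid
  still equals the pair-counting AUC to machine precision. Hub ranking
  breaks degree ties lexicographically and says so.
* **Degenerate inputs.** Zero-variance t-tests, empty queries or
  universes, rank-deficient covariates (reported with the collinear column
  name), single-class labels and missing features all raise informative
  errors rather than propagating NaN.

## Problem sizes in the checks

The test suite and the acceptance script recompute everything at
simulation sizes chosen to keep each property statistically decisive:
brute-force ceRNA equivalence on 1000+ random instances of up to ~10
features per class; AUC pair-counting on all case-control pairs at
n <= 12; hypergeometric enumeration over complete query draws at universe
sizes <= 15; planted-triplet recovery over 100 independent seeds at the
default effect size; the combined-vs-single AUC ordering over 200 seeds at
a deliberately moderate effect (planted log2FC 1, noise SD 1, a
standardized effect of 1) — at the default strong effect both AUCs
saturate at 1 and the strict ordering would be vacuous; and null DE
calibration over 2400 features against binomial 99% bounds around 0.05.

## Limitations

Raw-p filtering at n = 10/10, in-sample combined AUCs, and
degree-as-the-only-hub-metric are faithful to the emulated workflow, not
best practice; the BH columns, the leave-one-out flag and the exported
per-stage tables exist so a user can apply stricter conventions without
re-implementing anything. Target-prediction quality is out of scope: the
network can only be as good as the interaction tables supplied to it.
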