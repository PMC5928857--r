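---
title: "Methods: TiME subtyping, neoantigen abundance and outcome association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TiME subtyping, neoantigen abundance and outcome association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timeatlas)
```

`timeatlas` chains five stages: simulation of a cohort with planted
structure, single-cell subtyping, neoantigen calling and quantification,
dual-level signature derivation, and outcome association. This vignette
documents the models behind each stage, the defaults and why they were
chosen, and the limits of what the synthetic cohorts can establish.

## The single-cell subtyping model

Mass-cytometry intensities are modeled on the arcsinh scale
(`asinh(x / cofactor)`); the cofactor defaults to 5, the mass-cytometry
convention (for fluorescence data a larger cofactor, ~150, would be
appropriate). The transform is recorded on the event table so it cannot be
applied twice.

Density-dependent downsampling estimates each cell's local density within
its own sample as the inverse median distance to its `k = 15` nearest
neighbours, then keeps cells with probability `min(1, target / density)`,
where the target is the `target_fraction` quantile of that sample's density
distribution. This thins dense regions toward a common local density while
retaining rare populations, and drops presumed debris below the
`outlier_quantile` (default 1%) density. The implementation computes exact
pairwise distances per sample, which is quadratic in cells per sample; it
is intended for the ~10^2–10^4 cells per sample this package targets, not
for millions of events. Keep/drop draws are seeded per sample from a hash
of the sample identifier, so each sample's kept set is independent of the
other samples and of row order.

Clustering of the pooled, downsampled events uses seeded k-means with
`k = 500` by default, on the lineage-marker subset only (activation and
checkpoint markers are reserved for differential statistics, following
SPADE practice). k-means was chosen over an agglomerative variant because
it is deterministic under a seed, fast at this scale, and directly
oracle-testable on separable mixtures. Every original cell — not just the
downsampled subset — is then mapped to its nearest centroid, so node
medians and per-sample node fractions describe the full data and the
fractions of each sample sum to 1 exactly. `k` is a request: the realized
number of non-empty nodes is reported and can be smaller, which is why the
node count is surfaced as data rather than assumed.

Phenotype annotation uses 15 gating-style definitions (hi/lo marker
requirements) over the panel. The representative (landmark) node of a
phenotype is the node that satisfies every gate requirement relative to
across-node midpoint cutpoints with the best standardized margin; gate
markers that do not vary across nodes are uninformative and treated as
satisfied. Remaining nodes inherit the phenotype of the representative in
their average-linkage cluster (nearest representative on ties or
representative-free clusters). With `strict = TRUE` an unsatisfiable gate
errors, naming the phenotype; the pipeline runs with `strict = FALSE`
because small synthetic cohorts can lack a pure node for a rare phenotype.

Subtype discovery clusters samples by average-linkage on
1 − Pearson correlation of node-fraction profiles, cut at two. The cluster
with the larger mean fraction of partially exhausted
(PD-1⁺CTLA-4⁺) CD8⁺ T-cell nodes is labeled subtype I ("good" TiME); this
orientation rule is content-based, so sample order cannot flip the
semantics.

The Z ratio summarizes differential activation: features are z-scored
across all samples in the comparison, and each feature's group-mean
difference is divided by the SD of all such differences *in that
comparison*. The SD's scope is per comparison (the alternative — pooling
across several comparisons — is not implemented because the statistic is
defined relative to its own comparison here). |Z| ≥ 1.96 is flagged, the
two-sided standard-normal 5% point. Constant features are dropped with a
warning rather than silently producing NaN.

## The neoantigen model

A missense catalog is built from `gene + p.XposY` rows; non-missense and
malformed rows are dropped with a logged count, and duplicates across
sources are collapsed keeping all source tags. Each mutation defines a
29-residue window (14 flanking residues each side, clipped at the protein
termini — clipping preserves every enumerable sub-peptide, the reason
truncation was preferred over discarding near-terminus mutations). The
reference residue is checked against the catalog and a mismatch is a hard
error: a wrong reference would silently shift every candidate peptide.

Candidates are all mutation-spanning substrings of class-legal lengths
(8–14 for MHC-I, 15 for MHC-II), emitted once per (sequence, length). A
full 29-mer with a centered mutation yields 77 class-I and 15 class-II
candidates.

Binding prediction is a pluggable seam: any function
`(peptides, alleles) → percentile ranks in (0, 100]` can stand behind
`predict_ranks()`. The bundled `toy_rank_predictor()` is a deterministic
string hash mapped onto `(background_floor, 100]` with planted overrides.
The background floor defaults to 10 — above every binding threshold — so
that in synthetic cohorts the planted binder set is exactly the callable
set; lowering the floor to 0 makes background binders possible and turns
exact-recovery tests into statistical ones.

Tier rules are nested and follow the ≤/> boundary semantics exactly:
class I potential ⇔ mutant ≤ 2 and wild type > 2, high ⇔ mutant ≤ 1
within potential; class II uses 10 and 5. "Neoantigen" for counting and
averaging includes both intermediate and high tiers by default
(`tier = "potential"`), configurable to high-only.

A detected peptide is assigned to a mutation when its sequence occurs in
that mutation's mutant window at a position spanning the mutated residue;
the binding assessment then uses the window's candidates, so detection
(what the instrument saw) and binding (what the mutation can present) are
linked at the mutation level. A call is one (mutation, class, sample) row
carrying the best tier, the supporting alleles and the detected peptide's
AUC — attributed once, not once per sub-peptide, so the
average-abundance metric (ΣAUC / n calls) does not double count.
Quantification is trapezoidal AUC over chromatogram points (or precomputed
AUCs), and iFOT normalization scales each peak by the sample total times
10^5 (a common fraction-of-total convention; the scale factor is a
parameter).

The abundance-vs-expression concordance analysis pairs each call with the
iFOT expression of the locus of each supporting allele, splits both axes
at the cohort median (the split quantile is configurable; the median is a
neutral default where no external threshold exists) and tests subtype
enrichment of high/high pairs with an uncorrected two-tailed chi-square on
the 2×2 table.

## The dual-level signature

Per-gene differential expression uses Welch's two-sample t test — unequal
variances are the safe assumption at 6 samples per group — with raw p
values and a Benjamini–Hochberg column alongside (derivation thresholds
apply to raw p, matching the tradition of dual-level filtering; the BH
column is reported for transparency). Signature genes must pass
`p < 0.05` at both the mRNA and the protein level with concordant
direction; concordance is on by default because a gene moving opposite
ways at the two levels is biologically incoherent as a subtype marker,
and it is switchable for sensitivity analyses.

Classification is nearest centroid on Pearson correlation of per-gene
standardized expression, with ties resolved toward bad-TiME (the
conservative call for a treatment-selection signature: a tie should not
recommend therapy). The score is `cor(good) − cor(bad)`. Nearest centroid
was chosen as the simplest classifier that is invariant to per-gene affine
rescaling and gene order — properties the test suite verifies — and
because the cross-cohort application needs nothing more than a gene list
with directions and centroids. Cross-platform gene matching is by
uppercased symbol with an optional user alias table (for mouse-to-human
application); at least 50% of signature genes must be present, and the
floor is a parameter.

ROC AUC is the Mann–Whitney U statistic over positive/negative score
pairs with half-credit ties.

## Outcome association

Survival uses the product-limit estimator and the log-rank test
(`survival::survfit`/`survdiff`), with censoring at last follow-up.
The Cox workflow mirrors the two-step convention: univariable
proportional-hazards fits per candidate variable, then one multivariable
fit over the variables with univariable `p < 0.2`. Ties use the Efron
approximation (the standard default, more accurate than Breslow with tied
event times). Suspected complete separation (|log HR| > 15) is flagged.
Response is dichotomized as CR/PR = responder by default; counting SD as
benefit is a configuration switch because the clinical narrative, not a
fixed rule, decides it. The Fisher test is exact and two-tailed by the
probability-mass rule.

## What the synthetic cohorts emulate — and what they do not

The generator plants two latent subtypes that drive every data type:

- **Cells**: per-sample Dirichlet mixtures over the 15 phenotypes
  (concentration 50 — moderate biological variability), with hi/lo marker
  archetypes at 3.0/0.4 arcsinh units and Gaussian noise (SD 0.4). The
  subtype tilts mixture weights (`exp(±0.35 · shift)` on the Dirichlet
  location of good/bad-associated phenotypes) and shifts activation-marker
  means by `activation_shift` noise-SD units. Values are exported on the
  raw scale (inverse arcsinh, clamped at zero) so preprocessing is
  exercised.
- **Peptides**: random protein sequences (40–120 residues, uniform
  alphabet), one mutation per protein, a shared catalog three times the
  per-patient mutation count, Bernoulli detection, and log-normal peak
  AUCs (sdlog 1, baseline meanlog 9) with the subtype-I mean raised by
  `abundance_shift` on the log scale. MHC-locus protein expression is
  log-normal with half the abundance shift — both effects point the same
  way, as in the motivating biology, but the 2:1 ratio is a modeling
  choice, not an estimate.
- **Expression**: signature genes separated by `signature_effect` SD units
  with a random concordant direction at both levels; per-gene mRNA-protein
  correlation is exact by construction (shared latent component), default
  0.7 — the upper range of reported transcript–protein correlations,
  appropriate for genes selected at both levels.
- **Outcomes**: exponential survival with baseline median 18 months
  (mid-range for resected MPM), hazard multiplied by `hazard_ratio`
  (default 1.74) for subtype II, uniform censoring on [0, 60] months
  (non-informative by construction), Bernoulli response (defaults 0.8 good
  / 0.1 bad), and mRECIST categories split CR:PR = 3:1 among responders
  and PD:SD = 4:1 among non-responders.

No published distributional detail exists for any of these quantities; all
distributions are stand-ins chosen for realism and testability, not claims
about the source data. Passing recovery tests therefore demonstrates that
the pipeline's inference is correct *when its assumptions hold* —
Gaussian-ish marker noise, log-normal abundances, proportional hazards —
and cannot establish robustness to spillover, batch effects, spectral
search errors, heterodimeric class-II binding, non-proportional hazards,
or any property of real MPM cohorts. The external anchors of the original
analyses (public expression cohorts, mutation databases, IEDB predictors)
are deliberately out of scope; the predictor seam and the alias table are
where real resources would plug in.

## Numerical and testing choices

- Degenerate inputs have defined behavior everywhere: zero-norm vectors
  give cosine 0 with a warning; constant features are dropped from Z-ratio
  comparisons; all-zero paired differences give t = 0, p = 1; zero
  variance in both groups gives p = 1 with a flag; empty response margins
  give p = 1 with an undefined odds ratio.
- All randomness flows from explicit integer seeds; generator sub-stages
  use fixed offsets of the cohort seed, and the pipeline manifest contains
  no timestamps, so identical configurations produce byte-identical
  output trees (verified by md5).
- The test suite runs its simulations at reduced scale — 12 samples with
  120–300 cells each and 25–60 clusters, 150–500 genes, catalogs of a few
  dozen mutations, 330 patients for hazard-ratio recovery, and 200–400
  seeds for calibration loops. These sizes were chosen so the full suite
  and the acceptance script each complete in minutes while keeping
  Monte-Carlo error well inside the asserted margins.
- Null calibration asserts type-I error within ±3 percentage points of
  the nominal 5% for the abundance comparison, the log-rank test and the
  per-gene Welch test; parameter recovery asserts ARI = 1 at activation
  shift 3, signature precision/recall ≥ 0.8 at effect 3, Cox log-HR bias
  below 10% at n = 330, and ≥ 95% directional power at abundance shift 2.

## Known limitations

- The exact-recovery guarantees for neoantigen calls depend on the toy
  predictor's background floor; with a real predictor the pipeline reports
  what the predictor implies, and the tier boundaries become the only
  hard guarantees.
- The quadratic-cost density estimate and the complete similarity graph
  limit practical scale to thousands of cells and hundreds of nodes;
  both are per-sample/per-map costs, not per-cohort.
- Class-II binding is treated per locus through the predictor seam;
  DQ/DP heterodimer pairing is not modeled.
- The 500-cluster default describes the clustering request, not the
  realized node count, which depends on the data; downstream code treats
  the node set as data throughout.
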