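---
title: "Methods: epidermal methylome landscape and subtype analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epidermal methylome landscape and subtype analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidermeth)
```

## Scope and model

`epidermeth` analyzes Infinium-style DNA methylation data — beta values
$\beta \in [0,1]$, the estimated methylated fraction per cytosine — from
cohorts of healthy epidermis, actinic keratosis (AK) and cutaneous squamous
cell carcinoma (cSCC). The package covers five analytical layers:

1. **Probe filtering** (detection p-value, sex chromosomes, SNP overlap,
   self-hybridization),
2. **Differential methylation** with empirical-Bayes moderated statistics
   and Benjamini–Hochberg (BH) correction,
3. **Landscape statistics**: shifts per epigenomic substructure (CpG
   island / shore / shelf / open sea), lamina-associated domain (LAD)
   hypomethylation, non-CpG (CH) methylation,
4. **Methylation age** via a pluggable linear clock,
5. **Two-subclass discovery** from keratin-gene and enhancer-aggregated
   profiles, with a confidence-score filter for whole-exome variant tables
   on the side.

Everything runs on a synthetic cohort built by the generator module, so the
full pipeline is testable without controlled-access patient data.

## Differential methylation

Per probe we fit group means and pool the residual variance $s^2$ on $d$
degrees of freedom. Variances are shrunk toward a prior:

$$\tilde s^2 = \frac{d_0 s_0^2 + d\, s^2}{d_0 + d},$$

with $(d_0, s_0^2)$ estimated from the marginal distribution of all $s^2$ by
the closed-form moment estimator on $\log s^2$ (digamma/trigamma inversion).
Two details matter in practice: when the observed spread of $\log s^2$ does
not exceed its theoretical sampling variance the prior degrees of freedom
are infinite and every probe collapses onto $s_0^2 = \overline{s^2}$; and
the total degrees of freedom $d + d_0$ are capped at the pooled residual df
of the whole matrix. Tests verify agreement with an independent established
implementation of the same estimator to $10^{-8}$, and that $d_0 = 0$
degenerates exactly to ordinary two-sample t statistics.

Statistics default to a moderated **F** even for two groups (where
$F = t^2$), because the pairwise comparisons this package mirrors are
F-tests; a moderated t is available. Tests are computed on beta values
directly — the effect size of record is $\Delta\beta$ (comparison minus
reference) and no logit transform is implied — but a `transform = "mvalue"`
switch runs the statistics on M-values while still reporting $\Delta\beta$
on the beta scale. Probes with zero residual variance take $\tilde s^2$ from
the prior when $d_0 > 0$; at $d_0 = 0$ they are reported as indeterminate
(`NA`) rather than as infinite statistics.

`bh_adjust()` is an own implementation of the step-up procedure (ties
preserved, capped at 1, input order restored); it is cross-checked in the
test suite against both `stats::p.adjust` and a brute-force enumeration.

## Landscape statistics

`substructure_shift()` computes per-probe group-mean differences over
CpG-context probes of each substructure class and summarizes each class by
its mean and a two-sided one-sample t-test against zero *across probes*.
Probes are treated as units; because neighbouring probes are correlated,
these p-values are descriptive summaries of effect consistency (the
astronomically small values typical of such analyses should be read that
way), not calibrated genome-wide inference. The same convention applies to
`region_shift()` (LADs). `shift_fractions()` classifies each significant
probe as hyper- ($\Delta\beta > 0$) or hypomethylated ($\Delta\beta < 0$);
a significant probe with $\Delta\beta$ exactly zero counts as unchanged, so
fractions sum to one exactly. `noncpg_analysis()` is the moderated test
restricted to CH-context probes plus a per-sample mean over the significant
set.

Coordinates follow one rule, implemented in a single place
(`probes_in_regions()`): manifest positions are 1-based cytosine sites,
region sets are BED-native 0-based half-open, and a probe at 1-based $p$
belongs to $(\text{start}, \text{end})$ iff
$\text{start} < p \le \text{end}$. Chromosome names are normalized to the
`chr` dialect on load; mixed dialects are an error, never silently patched,
because a silent empty join is the classic failure mode of this operation.

## Methylation age

Clocks are linear models on a transformed age scale, logarithmic below the
pivot `adult_age` (default 20 years) and linear above it:
$f(a) = \log(a+1) - \log(A+1)$ for $a \le A$, else $(a - A)/(A+1)$ —
continuous and differentiable at the pivot, exactly invertible. Clock
coefficients are **never bundled** (published clocks carry their own
licensing and provenance); a clock is read from a small TSV or produced by
`generate_clock()`. The age gap is `predicted − chronological`, so negative
values mean a methylome "younger" than the patient. Missing clock probes
are dropped term-wise (which biases the score if many are absent — hence
the per-sample missingness report and the low-confidence flag above 20%).

## Subtype discovery

Features are mean beta values aggregated per keratin gene
(`aggregate_gene_beta`; a probe linked to several genes contributes to
each) or per enhancer region (`aggregate_region_beta`). The subclass count
is **fixed at k = 2 by design** — the package implements a two-subclass
model, it does not estimate the number of clusters. Defaults are euclidean
distance with average linkage (neither is dictated by the underlying
method; both are exposed). PCA is on centered, unscaled features — beta
values are already bounded and commensurate — with component signs fixed by
making the largest-magnitude loading positive.

Two guards keep the caller honest:

* a **silhouette floor** (default 0.25, the conventional boundary below
  which no substantial structure should be claimed): if the 2-cluster cut
  falls below it, the result is an explicit "no subclass structure" report,
  not a forced call;
* **anchored labeling**: the cluster whose centroid is nearer the healthy
  centroid (or a supplied keratinocyte reference profile) is
  `keratinocyte_like`, the other `EpSC_like`; with no anchor at all, a
  per-sample EpSC-gained-region score labels the higher cluster
  `EpSC_like`. This makes labels deterministic and invariant under sample
  permutation.

`delta_vs_healthy()` subtracts the healthy-group mean per feature (healthy
columns then average to zero exactly), and
`select_hypermethylated_genes()` applies a strict `> 0.2` threshold to the
EpSC-like mean of each EpSC-gained region — exactly 0.2 is not selected.

## Variant confidence filter

Each variant starts at score 10; one point (configurable) is deducted per
overlapping artifact category (repeats, DUKE-excluded, DAC-blacklisted,
self-chain, segmental duplication; the first two can be merged into one
category) and, for indels, per set Platypus filter. Retention requires
score ≥ 8 — the printed exclusion is strictly `< 8` — so at deduction 1 a
variant survives at most two artifact categories. The population cascade
(dbSNP-common unless OMIM-rescued, ExAC > 0.1%, EVS > 1%, in-house > 2%,
coding-only) runs in a fixed order with first-rule attribution in the
report. Depth bounds have **no default**: the source method states only
"too high or too low", so they are explicit configuration.

## The synthetic world

The generator emulates the statistical structure of such a study, not its
data. Defaults are the stated conditions where they exist, and a single
considered choice elsewhere:

* **Group sizes 12 / 16 / 18** (healthy / AK / cSCC) and a **subclass
  fraction of 0.5** among lesion samples.
* **Baselines** per substructure: islands 0.15, shores 0.40, shelves 0.60,
  open sea 0.75, CH probes 0.05 — the canonical bimodal beta landscape.
* **Lesion effects** (invented magnitudes, configurable, chosen so
  recovery at ±0.02 is a meaningful test): island +0.15, open sea −0.15,
  LAD −0.10, CH gain +0.10 on a responsive half of CH probes, subclass
  separation 0.30.
* **Noise**: Gaussian sd 0.05 per measurement plus per-probe baseline
  jitter sd 0.02, clamped to [0,1] with clamp events counted. Clamping
  truncates the low-beta tails (visible for CH probes near 0.05); the
  generator reports it rather than hiding it.
* **Clock**: 50 open-sea probes, uniform weights, intercept pinned so the
  flat 0.5 profile predicts the pivot age; `clock_embed_beta()` produces an
  exact-age pattern, which the cohort uses to plant a −15-year shift in all
  lesion samples plus −10 more in the EpSC-like half.
* **Enhancers**: ESC and keratinocyte sets share 25% of their regions;
  EpSC-gained/lost sets are separate; references are hypomethylated at
  their own enhancer sets by a 0.30 margin.

Channel separation is deliberate: LADs sit over shelf territory and replace
the substructure effect for their probes; CH probes carry only the CH
channel; enhancer and keratin intervals sit in shore territory (zero group
effect); clock probes are overwritten by the age embedding. Real
methylomes do not separate this cleanly — LADs are largely open sea,
enhancers overlap islands and shores, and effects compound. A green test
therefore establishes that each operation recovers what was planted at the
configured magnitude under realistic noise; it does not establish
performance under correlated, compounded real-data effects, batch
structure, or cell-composition mixtures (all out of scope by design).

The latent subclass truth lives only in the sample sheet
(`latent_subclass`) and the generator's `truth` element; no analysis
routine receives it.

## Numerical choices and degenerate inputs

* Beta files are written with 17 significant digits so a write/read round
  trip is bit-exact.
* Single-probe substructure classes report `NA` p-values; empty classes are
  reported with zero counts, not errors. Region sets covering no probes are
  an error in `region_shift` (a silent zero would hide a coordinate-dialect
  bug).
* Equidistant-point clustering ties resolve deterministically through the
  fixed agglomeration order of the underlying implementation; determinism
  (not a particular tree) is the contract, and merge heights are verified
  against a naive $O(n^3)$ oracle.
* All randomness flows from one root seed through fixed per-stage offsets;
  the same config + seed reproduces every output byte-identically.

## Known limitations

* Inference across probes is descriptive (see above); no block-finding for
  large hypomethylated domains.
* No IDAT parsing, no functional normalization (inputs are assumed
  normalized; `filter_probes` marks where that stage would sit), no VCF
  parsing (the variant filter consumes an annotated table), no batch or
  cell-composition correction.
* The 450k/850k harmonization joins on shared aggregated features; it does
  not model platform-specific probe biases.
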