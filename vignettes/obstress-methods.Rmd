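---
title: "Methods: marker-gated analysis of osteoblast stress responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-gated analysis of osteoblast stress responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obstress)
```

## The problem this package addresses

Osteoblasts (OBs) carrying a misfolding-prone procollagen mutation mount a
stress response whose marker genes (the integrated stress response plus
*Hspa9* and *Atf5*) rise with the amount of collagen the cell is making.
Detecting that pattern from UMI count data is statistically awkward for
three reasons: OBs are a minority population mixed with fibroblasts,
endothelium, chondrocytes, smooth muscle and immune cells; collagen genes
dominate the transcriptome so strongly that log or variance-stabilizing
normalizations distort expression ratios; and the response is
dose-dependent along a continuous differentiation gradient rather than a
clean two-group contrast. `obstress` implements the full analysis chain
built around those constraints — and a synthetic-data generator with known
ground truth so that every stage can be verified without any external
download.

## Expression statistics

All expression is **%UMI**: a gene's UMI count divided by the unit's
(cell's or spot's) total UMI count, times 100. No logarithm, no scale
factors, no pseudocounts at this stage (`to_percent_umi()`). Printed
thresholds throughout the package (0.75, 3.5, 0.15, 0.03) are on this
percent scale. Mitochondrial genes stay in the denominator by default; a
flag removes them for sensitivity analyses.

Group averages are **pooled fractions** (`weighted_group_mean()`): the sum
of the gene's counts over the group divided by the sum of all counts in
the group, times 100. This weights each cell by its total UMI and differs
from the unweighted mean of per-cell %UMI whenever library sizes vary —
tests assert the weighted definition specifically.

## Quality control

`filter_cells()` keeps units with at least 500 detected genes (counts
> 0), no upper feature bound, and a mitochondrial UMI fraction *strictly*
below 10% (a cell at exactly 10.0% is removed). "Detected features" means
genes with nonzero count; fractions are computed on raw counts before any
gating, and filtering is idempotent. `screen_dataset_death_markers()`
additionally compares whole datasets against a reference for elevation of
cell-death markers (*Apaf1*, *Trp53inp1* by default, user-extensible) and
flags the dataset for discard when any marker is significantly elevated.
The screen reuses the pipeline's weighted means and rank test with a
Bonferroni correction over the markers at α = 0.05 — a design choice,
since only the screen's intent, not its test, is fixed by the protocol.
Datasets that pass are merged by `merge_matrices()` with no batch
correction and no rescaling; genes align by name, never by index.

## Gating and subpopulations

A unit is an osteoblast (or OB-enriched spot) operationally: it meets
*every* inclusion threshold (*Col1a1*, *Runx2*, *Sp7*, *Ibsp*) and sits
below *every* exclusion ceiling. Inclusion thresholds carry an explicit
scale tag — raw counts for cells, %UMI for spots — because the two modes
read different axes. Spot exclusions are strict ceilings: *Col2a1* < 0.15
and *Col10a1* < 0.03 %UMI, which reject spots contaminated by growth-plate
chondrocytes.

`tune_thresholds()` formalizes "tune for efficient exclusion": among
candidate threshold sets whose gate retains at least `min_retention` of
the units co-expressing every inclusion marker at any positive level, it
picks the set minimizing total exclusion-marker leakage (fraction of
selected units expressing *Clec3b*, *Pecam1*, *Acan*, *Acta2*, *Cd68* or
*Cd33*). Ties go to the larger selected set, then to the lexicographically
smallest thresholds. The objective function is this package's
formalization of a goal that is otherwise stated only qualitatively.

Gated cells split on *Col1a1* %UMI into early (eOB), differentiating
(dOB) and mature (mOB) subpopulations at 0.75 and 3.5 %UMI. Edge
membership follows the printed inequalities exactly: both 0.75 and 3.5
belong to the middle bin (lower bin strict `<`, middle closed, upper
strict `>`).

## Differential expression

`differential_expression()` computes, per gene: pooled-fraction means in
both groups, fold change B/A, a two-sided Wilcoxon rank-sum test on the
per-cell %UMI values, and Bonferroni adjustment with denominator equal to
the number of genes tested *in that call* (the correction is applied when
building a DE gene list, not genome-wide; the denominator is exposed
because the alternative reading is defensible). The significance rule is
deliberately two-legged: **more than 20% change and adjusted p < 0.05**.
A fold of 1.15 with a vanishing p-value is not significant; the 20% floor
reflects the quantification accuracy of relative counts rather than a
power calculation reproducible here, and is taken as given.

Genes with zero counts in both groups get p = 1 and an undefined fold —
flagged, never dropped. A zero reference mean leaves the fold undefined
unless an explicit pseudocount mode is enabled (off by default).

`cross_tissue_filter()` reduces DE tables to robust hits via four
criteria: (i) significant in every required contrast (e.g. Hom E18.5 mOBs
*and* Het P5 mOBs); (ii) at least 2-fold change, either direction, in the
designated contrast; (iii) same-direction fold change in independent
replicate experiments — direction agreement only, since a per-experiment
significance requirement is not part of the rule; (iv) membership in at
least two functional categories of a user-supplied gene→category table
(GO-style membership without a database dependency; absent genes have
zero categories and fail).

## Running-average trajectories

`build_profile()` sorts cells by the covariate's %UMI (ties broken by
unit id, so profiles are deterministic and invariant to input order) and
slides a 20-cell window at stride 1; each window's value is the pooled
fraction of the target gene over its members, and the trailing partial
window is dropped. `compare_profiles()` aligns two genotypes' windows and
rank-tests each aligned pair.

Two readings had to be fixed by design here:

* **What gets tested per window.** The test compares the 20 per-cell %UMI
  values of one cohort's window against the 20 of the other — the only
  reading under which a per-window two-sample rank test is computable (a
  test of the two scalar running averages would be undefined).
* **How windows align across cohorts.** Each cohort is sorted
  independently, so windows have no intrinsic pairing. We pair greedily by
  covariate order: each window of cohort A is matched to the nearest (by
  mean covariate) still-unused window of cohort B. With equal cohort
  sizes this is nearly rank alignment; it is exposed as a strategy option
  and documented as this package's choice.

Instead of a Bonferroni correction across the heavily overlapping
windows, windows with p < 0.01 are *marked* and the expected number of
false-positive marks — `n_windows × 0.01`, exact arithmetic — is reported
next to the observed marks. For an analysis of ≈500 aligned windows the
budget is ≈5 marks; for ≈1500 windows, ≈15. The package's null
calibration (two cohorts from the identical wild-type generative model)
reproduces these budgets: the long-run mean marked count is ≈4.9 per
≈495-window analysis and ≈12.5 per ≈1490 windows. Because a gene's %UMI
shares its denominator with the covariate, relative counts carry a mild
compositional coupling along the gradient; that coupling is part of the
procedure being characterized, and the false-positive budget absorbs it.

Per-window tests default to the tie-corrected normal approximation with
continuity correction — window values from count data tie heavily, and at
20 vs 20 the approximation is slightly conservative at the 0.01 mark.
`rank_test()` itself switches to the exact permutation distribution
whenever both groups are ≤ 50 untied values, which matters for the
small-sample contexts below.

## Bulk RQ analysis

Bulk libraries lack UMIs, so counts are normalized to **relative
quantities**: each gene's count divided by the geometric mean of the four
housekeeping genes' counts (*Actg1*, *Actb*, *Mrfap1*, *Sdha*) in the
same replicate (`compute_rq()`). The geometric mean on raw counts is the
count-space analogue of averaging Ct values in qPCR; RQ is exactly
invariant to per-replicate depth scaling. Early, pre-steady-state
replicates are excluded by configuration, not hard-coded.

`validate_housekeeping()` screens candidates against single-cell data: a
candidate passes when its %UMI coefficient of variation across cells is
below a ceiling (default 1.0) and the rank test finds no genotype effect
(p > 0.05). The published validation procedure lives in supporting
material unavailable to this implementation; CV-plus-neutrality is the
documented stand-in, with both knobs exposed.

`dual_test()` runs the two-tailed Welch t-test and the Mann–Whitney
U-test side by side (RQ data does not reliably pass normality; Shapiro–
Wilk p-values are reported as diagnostics only). Significance keys on the
t-test plus the 20% change floor; a `discordant` flag records when the
two tests disagree at 0.05, mirroring how borderline cases are annotated
rather than silently resolved.

## The synthetic-data generator

`simulate_cells()` draws per-gene UMI counts from a negative binomial in
the mean/dispersion parameterization (per-gene dispersion, default 0.1 —
typical for UMI data and convenient for moment-based tests), at lognormal
library sizes (median 8000 UMI, σ = 0.35 on the log scale). Cell types
come from a configurable mixture: osteoblasts (70% by default) plus six
contaminants, each defined by an expression profile whose markers are
disjoint from the OB inclusion panel except for weak fibroblast *Col1a1*
(periosteal fibroblasts are the realistic near-miss for the gate).

Each osteoblast draws a latent *Col1a1* level from a three-component
lognormal mixture (weights 0.30/0.40/0.30; medians 0.35, 1.7 and
5.5 %UMI) whose density modes fall below 0.75, inside [0.75, 3.5] and
above 3.5 — reproducing the trimodal histogram that motivates the
subpopulation edges. The mixture parameters are free generator knobs:
only the two edges are anchored externally; the shapes were chosen once
to give all three subpopulations substantial mass, and the package makes
no claim that they match any real histogram quantitatively.

Dose responses are piecewise: fold 1 below a covariate threshold,
log-linear in the covariate above it, saturating at `max_fold` at a
configurable covariate maximum (default 8 %UMI) — the minimal shape
consistent with a threshold response that steepens exponentially.
Genotype enters through a multiplier *m* on the excess fold,
`fold = 1 + (m − 1)(f(x) − 1)`, with the convention WT = 1 (identity),
Het = 2 (the nominal curve), Hom = 3 (doubled excess). The convention
makes "WT multiplier forces fold 1" literal while keeping the homozygote
response strictly more pronounced than the heterozygote. Responses apply
to the cell's *latent* Col1a1 level; the realized %UMI then correlates
with it through sampling.

The default gene universe carries 600 anonymous background genes so a
typical simulated cell expresses ≈600 features and the 500-feature QC
floor separates intact cells from shallow libraries; 5% of cells are
drawn with a quadrupled mitochondrial load (≈15% mito fraction) to
exercise the strict 10% ceiling. Fast statistical simulations (null
calibration, power sweeps) use a 40-gene background universe — universe
size is a generator parameter, not part of any tested claim.

`simulate_spots()` pools consecutive groups of simulated cells (10 per
spot by default, matching what a 55-µm capture area can hold) into grid
spots; spot counts conserve the constituent cells' counts exactly and the
ground-truth composition rides along in the metadata. `simulate_bulk()`
generates replicate libraries from a fixed OB-culture profile with
lognormal depth variation; housekeeping genes keep genotype-independent
expected fractions by construction, and genotype effects enter only
through explicit fold injections.

What the generator does *not* emulate: ambient RNA, doublets, read-level
sequencing error, batch effects, spatial autocorrelation between
neighboring spots, or cell-cycle structure. Passing tests therefore
demonstrate that the statistics behave as designed under the assumed
negative-binomial, compositionally-coupled data model — not that real
tissue meets those assumptions.

## Numerical choices and degenerate inputs

* Strict vs closed comparisons follow the printed rules everywhere:
  mito fraction `< 0.10`, exclusion ceilings `<`, bin edges into the
  middle bin, mark threshold `p < 0.01`.
* Count-scale gating thresholds are evaluated on counts reconstructed
  from %UMI and totals; a 1e-9 slack absorbs float round-off so integer
  counts sitting exactly on a threshold are kept.
* Rank tests on fully tied data (including a group compared with itself)
  return p = 1 instead of a 0/0 variance.
* Fold changes with zero denominators are `NA` plus a flag; the
  significance rule then cannot fire without the opt-in pseudocount.
* All generators take explicit seeds and restore the caller's RNG state;
  identical spec + seed reproduces byte-identical matrices.
* Tie-breaks (covariate sorting by unit id, threshold tuning by set size
  then lexicographic order, merge suffixes by dataset index) are all
  deterministic.

## Problem sizes used in the tests

Unit and property tests run on 30–800-cell fixtures. The statistical
checks use: 100 replicates of paired 530- and 1540-cell null cohorts for
the false-positive budgets (the standalone acceptance script uses 600 and
200 replicates for tighter Monte-Carlo error on the same estimand); 20
seeded runs at 500 cells/group for 2-fold detection power; 3000 cells of
the six-way mixture for gating recovery; and 20 seeds of 6-replicate bulk
tables for RQ recovery. These sizes were chosen as the smallest that make
the Monte-Carlo error a small fraction of each tested margin.

## Known limitations

* The tuned gating thresholds for *Runx2*, *Sp7* and *Ibsp* are
  dataset-dependent configuration entries; the defaults are sensible for
  the simulator, not universal constants.
* The nearest-covariate window pairing is one defensible alignment; a
  common-quantile grid is a plausible alternative and the comparison API
  leaves room for it.
* The housekeeping validation criteria are a stand-in (see above).
* Relative counts are compositional: strong changes in a dominant
  transcript move every other gene's %UMI mechanically. The weighted-mean
  and trajectory machinery inherit this by design; interpretation of
  small fold changes near dominant-gene shifts should account for it.
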