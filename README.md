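# obstress

Marker-gated transcriptomic analysis of osteoblast stress responses.

Osteoblasts (OBs) synthesizing a misfolding-prone procollagen mount a
dose-dependent stress response — integrated-stress-response genes plus
*Hspa9* and *Atf5* rise with the cell's collagen output. Detecting that
pattern from UMI count data is hard in three specific ways: OBs are a
minority population among fibroblasts, endothelium, chondrocytes, smooth
muscle and immune cells; collagen transcripts dominate the transcriptome
so strongly that log or variance-stabilizing normalizations distort
expression ratios; and the response rides a continuous differentiation
gradient rather than a clean two-group contrast. `obstress` is for
analysts facing this class of problem: it implements the whole chain from
raw count matrices to gene calls, for single-cell, spatial-spot and bulk
RNA-seq data, plus a ground-truth synthetic-data generator so every stage
is testable offline.

## The statistics at the core

* **Relative counts.** Expression is %UMI, $100 \, c_{gu} / \sum_g c_{gu}$
  for count $c_{gu}$ of gene $g$ in unit $u$ — no log, no scale factors.
  Group means are pooled fractions,
  $100 \sum_u c_{gu} / \sum_u \sum_g c_{gu}$, weighting each cell by its
  total UMI.
* **Marker gating.** A unit is an osteoblast iff it passes every inclusion
  threshold (*Col1a1*, *Runx2*, *Sp7*, *Ibsp*) and every exclusion ceiling
  (for spots: *Col2a1* < 0.15, *Col10a1* < 0.03 %UMI). Thresholds are
  tunable against exclusion-marker leakage under a retention floor. Gated
  cells bin into eOB / dOB / mOB subpopulations at *Col1a1* = 0.75 and
  3.5 %UMI (edges belong to the middle bin).
* **Differential expression.** Wilcoxon rank-sum on per-cell %UMI,
  Bonferroni over the genes tested; significant means **>20% change and
  adjusted p < 0.05** — both legs required. A four-criterion cross-tissue
  filter (significance in required contrasts, ≥2-fold in a designated
  contrast, direction-replication across experiments, ≥2 annotation
  categories) distills robust gene lists.
* **Running-average trajectories.** Cells sorted by *Col1a1* %UMI, 20-cell
  windows at stride 1, pooled-fraction window values, per-window rank
  tests between genotypes. Windows with p < 0.01 are marked and compared
  against the expected false-positive count `n_windows × 0.01` — the
  procedure's replacement for Bonferroni across overlapping windows
  (budget ≈5 marks per ≈500 windows, ≈15 per ≈1500).
* **Bulk RQ.** Counts divided by the geometric mean of housekeeping genes
  (*Actg1*, *Actb*, *Mrfap1*, *Sdha*) per replicate — the count-space
  ΔΔCt analogue, exactly depth-invariant — with paired Welch t and
  Mann–Whitney U tests and a discordance flag.

## Worked example

Simulate a wild-type and a heterozygous cohort in which *Hspa9* responds
to *Col1a1* above a 1.5 %UMI threshold (up to 3-fold), then run the
single-cell chain:

```r
library(obstress)

universe <- gene_universe(n_background = 40)
profiles <- cell_type_profiles(universe)
spec <- function(seed, genotype) {
  simulation_spec(genotype = genotype, n_cells = 800, seed = seed,
    universe = universe, profiles = profiles)
}
dr <- dose_response("Hspa9", threshold = 1.5, max_fold = 3)

wt  <- simulate_cells(spec(1, "WT"))
het <- simulate_cells(spec(2, "Het"), dose_responses = list(dr))

m <- merge_matrices(list(wt, het))
m <- filter_cells(m, qc_config(min_features = 30))  # 40-gene background universe
attr(m, "qc_report")
#>   n_in n_out removed_min_features removed_max_features removed_mito
#> 1 1600  1527                    0                    0           73

p    <- to_percent_umi(m)
sel  <- gate(p, ob_cell_gate())          # raw-count marker thresholds
bins <- bin_subpopulations(p, sel$selected)
table(bins, m$unit_meta[sel$selected, "genotype"])
#> bins  Het  WT
#>   eOB 147 176
#>   dOB 247 225
#>   mOB 135 129
```

The 73 removed cells are the simulated high-mitochondrial fraction; 1059
of 1527 cells pass the osteoblast gate and split into the three *Col1a1*
subpopulations. Differential expression in mature osteoblasts:

```r
mob <- names(bins)[bins == "mOB"]
genotype <- m$unit_meta[mob, "genotype"]
differential_expression(m, mob[genotype == "WT"], mob[genotype == "Het"],
  genes = c("Hspa9", "Hspa5", "Ddit3", "Atf5"))
#>        gene mean_A mean_B fold_change pct_change    p_raw    p_adj significant
#> Hspa9 Hspa9 0.2487 0.5774       2.322     132.18 1.12e-34 4.49e-34        TRUE
#> Hspa5 Hspa5 0.3870 0.3643       0.941       5.88 9.67e-02 3.87e-01       FALSE
#> Ddit3 Ddit3 0.0441 0.0463       1.051       5.13 3.35e-01 1.00e+00       FALSE
#> Atf5   Atf5 0.0476 0.0446       0.937       6.26 3.80e-01 1.00e+00       FALSE
```

Only the gene given a dose response is called: 2.3-fold in mOBs (where
*Col1a1* is far above the 1.5 threshold), while its unresponsive ER
paralogue *Hspa5* stays flat. The trajectory comparison localizes the
response on the *Col1a1* axis:

```r
wt_ids  <- sel$selected[m$unit_meta[sel$selected, "genotype"] == "WT"]
het_ids <- sel$selected[m$unit_meta[sel$selected, "genotype"] == "Het"]
cmp <- compare_profiles(m, wt_ids, het_ids, "Hspa9")
c(windows = cmp$n_windows, marked = cmp$n_marked, expected_fp = cmp$expected_fp)
#>     windows      marked expected_fp
#>      509.00      213.00        5.09
range(cmp$pairs$covariate_B[cmp$pairs$marked])
#> [1] 1.98 9.18
```

213 marked windows against an expected 5 false positives, and every mark
sits above the simulated 1.5 %UMI threshold — the dose-dependent,
threshold-gated upregulation the pipeline exists to detect.

## Layout

* `R/` — simulator, IO/QC, normalization, gating, differential
  expression, trajectories, bulk RQ, pipeline orchestration
  (`run_single_cell()`, `run_spatial()`, `run_bulk()` with YAML configs
  and hashed run manifests).
* `tests/testthat/` — unit, property and statistical acceptance tests,
  all on simulated data.
* `vignettes/obstress-methods.Rmd` — the model, its assumptions, design
  decisions and limitations.
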