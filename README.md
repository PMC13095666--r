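# scmito

Single-cell analysis of mitochondrial DNA (mtDNA) heteroplasmy and copy
number in pooled CRISPR perturbation screens.

## The problem

Cells carry hundreds to thousands of mtDNA copies, and pathogenic mtDNA
mutations usually affect only a fraction of them — the *heteroplasmy*
level *h* ∈ [0, 1]. Single-cell multiome assays (joint scATAC + scRNA
with a CROPseq-style guide readout) make it possible to perturb nuclear
genes and read out, in the same cell, the guide identity, the mtDNA
coverage (a proxy for copy number) and the heteroplasmy. But every one
of those readouts is obtained by *sampling reads*: a cell observed at
combined read depth *n* has an estimated heteroplasmy
ĥ ~ Binomial(*n*, *h*)/*n*, so any perturbation that depletes mtDNA —
and with it the read depth — inflates the *apparent* cell-to-cell
heteroplasmy variance even when the underlying distribution of *h* is
unchanged. Deciding whether a variance change is biology or a
read-sampling bottleneck is the central statistical task this package
addresses.

## What the package does

* **Guide assignment** (`assign_guides`): reads with MAPQ ≥ 30 are
  deduplicated and tallied per (cell, guide); a cell is assigned when it
  has ≥ 2 reads and the most abundant guide holds a strict > 2:3
  majority of them.
* **Heteroplasmy calling** (`combined_heteroplasmy`): allele counts at a
  panel of linked SNVs are combined into one call per cell. Sites are
  oriented *cis*/*trans* relative to the focal pathogenic variant from
  per-cell correlation of site heteroplasmies (`infer_orientations`),
  and verified by long-read co-occurrence
  (`longread_haplotype_concordance`). For cis sites the mutant reads are
  the alt calls, for trans sites the ref calls, so
  *h* = Σ<sub>s</sub> f<sub>s</sub> / Σ<sub>s</sub> n<sub>s</sub> over
  the panel.
* **Copy number** (`mean_mtdna_coverage`): mean deduplicated mtDNA
  coverage per cell, deliberately not normalized to total ATAC signal so
  cell-cycle-linked replication trends stay visible; group contrasts use
  Welch *t*-tests on log10 coverage with Bonferroni correction.
* **Bottleneck test** (`simulate_bottleneck_null`): the null
  distribution of the knockdown-group heteroplasmy variance is built by
  resampling control cells without replacement, re-observing each at a
  depth drawn from the knockdown group, with ĥ ~ Binomial(depth, h)/depth
  (5,000 simulations); the observed variance gets a two-sided add-one
  empirical *P* value, Holm-adjusted across groups. A closed-form oracle
  Var(ĥ) = Var(h) + E[h(1−h)]·E[1/n] checks the machinery.
* **Depth–variance model** (`fit_depth_variance_quantiles`): cells are
  aggregated into equal-count depth bins and the 5th/95th percentile
  curves of Variance = β₀ + β₁/depth are fitted by exact pinball-loss
  quantile regression, with 95% bands from 200 bin bootstraps.
* **Nuclear response** (`residualize_expression`, `pc_scores`): per-gene
  OLS residualization of expression on mtDNA copy number, top-variable
  selection, PC1 scoring, rank tests vs the control group, cell-cycle
  phase composition chi-squared tests and coverage-vs-pseudotime trends.
* **Synthetic cohorts** (`generate_cohort`): fully seeded cohorts with
  known per-cell truth (heteroplasmy ~ N(0.582, 0.113²) clipped, copy
  number 1,750 with group-wise depletion, depth ∝ copy number) so every
  stage is testable without any download.

## Worked example

```r
library(scmito)

co    <- generate_cohort(1500, seed = 42)   # Tfam/Opa1/Polg depleted
reads <- generate_guide_reads(co$metadata, reads_per_cell_mean = 6,
                              ambient_rate = 0.05, seed = 43)

cnt <- count_guides_per_cell(filter_guide_reads(reads, 30),
                             dedup_by_umi = TRUE)
asg <- assign_guides(cnt, cells = co$metadata$cell_barcode)
summarize_assignment(asg, 1500)$status
#>       status count percent
#> 1   assigned  1401    93.4
#> 2  ambiguous    52     3.5
#> 3 unassigned    47     3.1

calls   <- combined_heteroplasmy(co$counts, co$panel)
calls_f <- filter_by_combined_depth(calls, 20)
# 1144/1500 cells pass depth >= 20; heteroplasmy 57.6% +/- 13.5%

grp  <- co$metadata$target_gene[match(calls$cell_barcode,
                                      co$metadata$cell_barcode)]
kd   <- calls[grp == "Tfam", ]
ctrl <- calls[!grp %in% c("Tfam", "Opa1", "Polg"), ]
bn <- simulate_bottleneck_null(ctrl$heteroplasmy, kd$combined_depth,
                               observed_variance = var(kd$heteroplasmy),
                               n_kd = nrow(kd), n_sims = 5000, seed = 44)
bn
#> Bottleneck null: 5000 sims of 275 cells; null var 0.03632 [0.03091, 0.04226]
#> Observed variance 0.03128, empirical p = 0.07239
```

Read: the Tfam-depleted group's heteroplasmy variance (0.031) lies
inside what depth-matched binomial resampling of control cells predicts
(95% interval 0.031–0.042), so its variance inflation relative to deep
controls is explained by the read-depth bottleneck, not by a change in
the underlying heteroplasmy distribution — the cohort was simulated
with identical *h* distributions in all groups.

The depth dependence itself:

```r
bins <- bin_equal_count(ctrl$combined_depth, ctrl$heteroplasmy, 15)
fit_depth_variance_quantiles(bins)
#>    tau       beta0     beta1 pinball_loss
#> 1 0.05 0.006699322 0.3715517  0.002182845
#> 2 0.95 0.017138497 0.2421748  0.003760712
```

Both percentile curves decay like 1/depth towards the true biological
variance (0.113² ≈ 0.0128 sits between the two intercepts).

A command-line interface wrapping these functions ships in
`inst/cli/scmito` (subcommands `assign-guides`, `call-heteroplasmy`,
`mtdna-cn`, `variance-null`, `depth-variance-model`,
`simulate-accuracy`, `simulate-cohort`, `response-pc1`, `run-all`).

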