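---
title: "Methods: heteroplasmy calling and the read-depth bottleneck"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heteroplasmy calling and the read-depth bottleneck}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmito)
```

This vignette documents the models and procedures implemented in
`scmito`, their assumptions, the parameters that matter, and the design
choices made where the methodology was genuinely open.

## The measurement model

Each cell carries $N$ mtDNA molecules of which a fraction $h$ (the
heteroplasmy) belongs to the mutant haplotype. Sequencing observes the
cell at a combined read depth $n$ across a panel of linked variant
sites, and the observed heteroplasmy is

$$\hat h \mid h, n \sim \frac{1}{n}\,\mathrm{Binomial}(n, h).$$

By the law of total variance, across a population of cells with
$\mathrm{E}[h] = \mu$ and $\mathrm{Var}(h) = \sigma^2$,

$$\mathrm{Var}(\hat h) \;=\; \sigma^2 + \mathrm{E}[h(1-h)]\cdot
\mathrm{E}[1/n],$$

implemented as `expected_sampled_variance()`. The second term is the
*read-sampling bottleneck*: any perturbation that reduces mtDNA copy
number also reduces $n$ (depth is proportional to copy number in
ATAC-derived mtDNA data) and inflates $\mathrm{Var}(\hat h)$ with no
change in the biology. Every downstream decision in the package is
shaped by this identity.

## Guide assignment

Guide reads are filtered at MAPQ ≥ 30 (inclusive boundary), optionally
UMI-collapsed, and tallied per (cell, guide). A cell is **assigned**
when it has at least `min_reads = 2` deduplicated reads and its most
abundant guide holds a strictly greater than `dominance = 2/3` share;
with enough reads but no strict majority it is **ambiguous**; below the
read floor it is **unassigned**. Two choices deserve comment:

* *Ties*: a tie for the top guide is declared ambiguous outright. For
  any dominance ≥ 1/2 this follows from strictness, but the explicit
  rule keeps the contract valid for permissive dominance settings too.
* *Deduplication*: PCR amplification during targeted guide enrichment
  can create read jackpots, so UMI collapse is preferred whenever UMIs
  are present, with unique read identifiers as the fallback. Both modes
  are exposed because upstream pipelines differ in whether they emit
  UMIs.

## Combined heteroplasmy over a linked-SNV panel

A panel of SNVs that segregate on exactly two mtDNA haplotypes lets
each site act as an independent observation of the same $h$. Sites are
oriented relative to the focal pathogenic variant: **cis** sites carry
their alternate allele on the focal haplotype, **trans** sites on the
opposing one. The combined call is the pooled count ratio

$$\hat h = \frac{\sum_s f_s}{\sum_s (\mathrm{ref}_s + \mathrm{alt}_s)},
\qquad f_s = \begin{cases}\mathrm{alt}_s & \text{cis}\\
\mathrm{ref}_s & \text{trans,}\end{cases}$$

i.e. raw counts are summed rather than per-site fractions averaged:
deeper sites carry proportionally more weight, which is the
maximum-likelihood pooling under the shared-$h$ model. Reads carrying
neither the reference nor the alternate base are excluded from both
numerator and denominator. Flipping every orientation maps $\hat h$ to
$1 - \hat h$ exactly, a property the test suite checks.

Orientations are inferred from data (`infer_orientations`): per-cell
site heteroplasmies are correlated with the focal site across cells
with at least 5 reads at both sites; $r \ge 0.3$ ⇒ cis, $r \le -0.3$ ⇒
trans, at least 10 qualifying cells required. These thresholds are
pragmatic defaults — orientation signals in linked panels are near
$|r| = 1$, so the test only needs to separate signal from noise — and
inconclusive sites are dropped from combined calling with a warning
rather than guessed. Long-read co-occurrence
(`longread_haplotype_concordance`) provides an orthogonal check: for
every position pair, the fraction of reads whose oriented alleles
agree; under perfect linkage this is 100%, under independence it is
$qq' + (1-q)(1-q')$.

Calls are filtered at a combined depth of ≥ 20 reads (inclusive), the
conventional confidence cutoff for single-cell heteroplasmic variant
calling; at $h \approx 0.58$ this caps the binomial standard error at
about $\sqrt{0.24/20} \approx 0.11$.

## Copy number from coverage

Relative mtDNA copy number is the mean deduplicated mtDNA coverage,
total aligned mitochondrial bases over the genome length (16,299 bp for
mouse, overridable). Coverage is deliberately **not** normalized to
total ATAC signal: nuclear read count itself rises through S/G2 as the
nuclear genome replicates, so normalization would erase exactly the
cell-cycle-linked mtDNA replication trend the coverage-vs-pseudotime
analysis (`coverage_phase_trend`) is meant to expose. A normalized
column is emitted alongside for analyses where library-size differences
dominate. Group contrasts use two-sided Welch $t$-tests on log10
coverage (Welch, because depleted groups have visibly different
spreads) with Bonferroni correction across pairs; zero-coverage cells
receive a pseudo-floor of half the smallest nonzero coverage before the
log — an arbitrary but explicit convention that only affects cells with
no mtDNA reads at all.

## The bottleneck null

To decide whether a knockdown (KD) group's variance exceeds what its
depths alone predict, `simulate_bottleneck_null()` builds a null by
depth-matched resampling: draw $n_{\mathrm{KD}}$ control cells without
replacement, give each a depth drawn with replacement from the KD
group, re-observe each as Binomial(depth, $h$)/depth, record the sample
variance ($n-1$ denominator throughout), and repeat $S = 5{,}000$
times. The observed KD variance is then assessed with a two-sided
add-one empirical $P$:

$$p = \min\!\Big(1,\; 2\min\big(\tfrac{1 + \#\{v \le v_{\mathrm{obs}}\}}
{S+1},\, \tfrac{1 + \#\{v \ge v_{\mathrm{obs}}\}}{S+1}\big)\Big),$$

Holm-adjusted across KD groups. The add-one form keeps $p > 0$ at
finite $S$ and makes $p = 1$ attainable, matching how such empirical
tests are conventionally reported.

One subtlety matters for calibration studies. If the control pool's
heteroplasmies are themselves *observed* values (estimated at finite
control depth), the resampling re-applies binomial noise on top of
noise already present, shifting the null upward by
$\mathrm{E}[h(1-h)]\cdot\mathrm{E}[1/n_{\mathrm{ctrl}}]$. At deep
control coverage this bias is small and conservative for detecting
variance inflation, and the pipeline follows the observed-control
procedure. The calibration tests, by contrast, feed the latent control
distribution (available for synthetic cohorts), under which the null is
exactly calibrated at any depth: with depth-matched groups the
empirical $p$ exceeds 0.05 at the nominal rate, and a doubling of the
latent s.d. is detected with high power. The test suite verifies both,
at $n_{\mathrm{KD}} = 300$ with control depths around 60×.

The pipeline's control pool is the union of all non-depleted groups
(nontargeting plus negative-control genes): in a uniformly assigned
library a single nontargeting group can be smaller than a three-guide
KD gene group, which would violate the without-replacement
precondition, and the pooled definition matches the control population
used for the depth–variance model.

## Depth–variance quantile model

Cells from the non-depleted population are sorted by depth and split
into equal-count bins (remainder cells go one-per-bin to the
lowest-depth bins, a deterministic convention); per bin the mean depth
and heteroplasmy variance are recorded. The envelope of the
depth–variance relationship is modelled as

$$\mathrm{Variance} = \beta_0 + \beta_1 / \mathrm{depth}$$

at the 5th and 95th percentiles via pinball-loss quantile regression.
The intercept is retained rather than forcing the curve through the
origin because the biological variance $\sigma^2$ does not vanish at
infinite depth; the $1/\mathrm{depth}$ term is the depth-dependent
component of the total-variance identity above.

No linear-programming solver is required: with two parameters, the
pinball-loss minimizer interpolates two observations, so the exact
optimum is found by enumerating all $\binom{n}{2}$ point pairs in
$(1/d, v)$ space and keeping the least-loss candidate — $O(n^3)$, well
under a millisecond at realistic bin counts, deterministic, and checked
against a 200 × 200 grid search in the tests. Uncertainty bands come
from resampling bins with replacement 200 times and taking pointwise
2.5/97.5 percentiles of the refitted curves on a 50-point depth grid;
degenerate replicates (all resampled depths equal) are redrawn up to 10
times. Default bin counts: 100 for the large non-depleted population,
15 for smaller groups — enough cells per bin (tens) for stable variance
estimates while retaining depth resolution; the pipeline default is 15,
matched to its cohort sizes.

## Accuracy-versus-depth simulation

`simulate_sampling_accuracy()` quantifies how read depth limits
heteroplasmy estimation: 2,000 cells with latent
$h \sim N(0.582, 0.113^2)$ clipped to $[0,1]$, each holding a pool of
1,750 molecules with $\mathrm{round}(h \cdot 1750)$ mutant copies, are
subsampled **without replacement** (hypergeometric) at sizes 5, 20, 50
and 100, and sampled-versus-true $h$ is summarized by least-squares
$R^2$ per size. The hypergeometric draw reflects sampling distinct
molecules from a finite per-cell pool, whereas the bottleneck null uses
binomial sampling of reads — reads can repeatedly interrogate the same
molecule after amplification, and at $n \ll N$ the two coincide
anyway; both procedures are kept as distinct, documented modes. A
matched-population mode instead samples each cell at a depth drawn from
a supplied empirical depth distribution, for studying a whole dataset's
depth profile. At $\sigma \to 0$ the sampled-$h$ variance reduces to
the hypergeometric variance
$p(1-p)\frac{N-n}{n(N-1)}$, which the tests verify within Monte-Carlo
error.

## Nuclear response statistics

Expression (assumed already log-normalized; normalization itself is out
of scope) is residualized per gene against mtDNA copy number by OLS,
$y_i = \beta_0 + \beta_1\,\mathrm{CN} + \varepsilon$, the covariate on
the linear scale by default with a log10 option. Residuals are exactly
orthogonal to the covariate (checked to $|r| < 10^{-6}$); a constant
covariate degrades gracefully to gene-centering with a warning. The top
2,000 (configurable) genes by residual variance — ties broken by gene
identifier for determinism — are centered, unit-scaled (preventing a
few high-variance genes from dominating) and decomposed by PCA with a
fixed sign convention: each component's largest-magnitude loading is
made positive, so scores are reproducible across platforms. Group
shifts in PC1 are tested against the control group with two-sided
Wilcoxon rank-sum tests (a paired signed-rank mode exists, but the
group comparisons here are unpaired) under Benjamini–Hochberg
adjustment; phase composition uses per-group 2 × 3 chi-squared tests
against all other cells, flagging rows with expected counts below 1.

## What the synthetic generator does and does not emulate

`generate_cohort()` reproduces the *structure* the analysis assumes:
uniform guide assignment from a 3-guides-per-gene library with
nontargeting controls; latent heteroplasmy Normal(0.582, 0.113²)
clipped to $[0,1]$, identical in expectation across groups; copy number
$1750 \times \mathrm{depletion} \times$ lognormal noise (sdlog 0.35)
$\times$ a cell-cycle factor rising linearly over pseudotime (range
2/3–4/3, mean 1); combined panel depth Poisson with 60/1750 reads per
copy, so a baseline cell has ~60× combined depth, matching a
post-enrichment single-cell ATAC regime, split multinomially across the
seven panel sites; per-site alternate counts Binomial(depth, $h$) at
cis sites and Binomial(depth, $1-h$) at trans sites (a trans site's
alternate allele rides the non-focal haplotype). Default depletion
factors 0.25/0.5/0.4 for the three depleted gene groups span the
severe-to-moderate range. Guide reads add a 5% ambient fraction and 10%
sub-threshold MAPQ; long reads are pure haplotypes with an optional
per-position flip rate.

It does **not** emulate: overdispersion of allele counts beyond
binomial (no within-cell amplification jackpots at variant sites),
strand artifacts, NUMT misalignment, doublets, or realistic
transcriptome structure (expression is a simple negative-binomial
baseline with one stress-response module scaled by depletion and one
module tracking copy number). Passing tests therefore demonstrate
correctness of the *inference machinery* under the stated sampling
model, not robustness to those real-data pathologies.

## Problem sizes and numerical conventions

The shipped test suite runs cohorts of 150–900 cells for module tests,
a 3,000-cell end-to-end pipeline reproduced twice and compared by
checksum, 100 + 100 calibration replicates at $S = 5{,}000$ simulations
each, and a 2,000-cell accuracy simulation — sizes chosen so each
check has clear statistical resolution while the whole suite completes
in a few minutes. Sample variances use the $n-1$ denominator
everywhere; empirical $P$ values use the add-one correction; quantile
fits are exact (no iterative tolerance); percentages in human-readable
summaries are rounded to one decimal while files carry full double
precision; all simulation entry points take a single seed, and the
pipeline derives independent per-stage substreams from it so stages can
be regenerated in isolation.

## Known limitations

* The bottleneck null inherits the observed-control bias discussed
  above; a deconvolution of control-observation noise would sharpen it
  but is deliberately not applied, to keep the procedure in its plain
  resampling form.
* Beta-binomial overdispersion modelling and Bayesian heteroplasmy
  posteriors are out of scope; strongly overdispersed counts will make
  the binomial null anticonservative.
* `brown_forsythe_test()` is mildly conservative at small group sizes
  (a property of median centering, visible in its type-I calibration
  test), which is the usual trade-off for its robustness to
  non-normality.
* Orientation inference assumes exactly two haplotypes; panels with
  recombinant or third haplotypes will surface as inconclusive
  orientations rather than errors.
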