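---
title: "Scoring sample heterogeneity with the molecular degree of perturbation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring sample heterogeneity with the molecular degree of perturbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdpr)
```

## The problem

Case/control transcriptome studies are small and people are heterogeneous:
undiagnosed illness, environment, genetics and microbiota all move gene
expression. A "healthy" subject who is molecularly perturbed inflates the
control variance; a patient whose disease leaves no molecular trace dilutes
the case mean. Both hide differentially expressed genes (DEGs) from a
standard two-group test. The molecular degree of perturbation (MDP) gives
every sample a single number — how far its transcriptome sits from a
reference class — so that such samples can be seen, inspected and, if the
analyst chooses, removed.

## The score

Let $x_{ij}$ be normalized expression of gene $i$ in sample $j$, and let
$h$ index the control samples. Per gene the control class provides a
center $m_i$ (median by default) and a scale $s_i$ (median absolute
deviation, MAD, by default). Every sample — control or not — is transformed
to an absolute modified z-score

$$ z_{ij} = \frac{|x_{ij} - m_i|}{s_i}, $$

and values with $z_{ij} < 2$ are set to zero: deviations below two robust
standard deviations are treated as ordinary biological noise, and only the
remaining entries count as perturbation. The MDP score of sample $j$ is the
mean of its thresholded $z_{ij}$ over a gene universe: all genes
(`allgenes`), the *perturbed genes* (`perturbedgenes`) — the top 25% of
genes ranked by mean thresholded $|z|$ across the non-control samples — or
any user-supplied GMT gene set, which lets prior knowledge (an immune-cell
module, a pathway) define what "perturbation" means.

Because center and scale are estimated per gene from the controls, the
thresholded z matrix is invariant under per-gene positive affine
transformations of the input, and a sample that coincides with the control
centers scores exactly zero. The test suite asserts both, plus agreement
with an explicit-loop reference implementation to 1e-10.

### Parameter choices

| Parameter | Default | Meaning |
|---|---|---|
| `center`, `scale` | median, MAD | robust to the very outliers being hunted; mean/SD available |
| `mad_constant` | 1.4826 | rescales the raw MAD to be SD-consistent under normality; set 1 for the raw MAD |
| `z_cutoff` | 2 | noise floor, in robust SD units; **strictly below** the cutoff is zeroed, a value exactly at it survives |
| `perturbed_fraction` | 0.25 | the perturbed-gene universe is the top `max(1, floor(0.25 G))` genes; ties broken by input order for reproducibility |
| `min_set_size` | 5 | GMT sets overlapping the matrix in fewer genes are skipped with a warning |

Two conventions deserve a note because the method's verbal description
leaves them open. First, whether the MAD is rescaled (and whether an extra
0.6745 factor belongs in the numerator) changes every score by a constant
factor; this package applies `mad_constant` to the MAD and nothing to the
numerator, and exposes the constant so either convention is reachable.
Second, with several case classes, "the perturbed group" used for gene
ranking is ambiguous; the default pools all non-control samples
(`ranking = "pooled"`), and `ranking = "per_class"` produces one
perturbed-gene universe per class instead. Genes whose control scale is
exactly zero are degenerate: they carry no dispersion information, their z
rows are set to zero, they are excluded from the ranking, and their count
is reported.

## Outlier flagging

Within each class, a sample is flagged when its score deviates from the
class mean by at least $k$ class standard deviations (default $k = 2$; SD
with $n-1$, candidate included — the simplest reading of "all samples
within each class"). Flagging is two-sided by default because both
directions are informative: a high-scoring control looks covertly
perturbed, a low-scoring patient looks molecularly unaffected. The default
score universe for flagging is `perturbedgenes`, the score on which
heterogeneity is usually inspected; `allgenes` is one argument away.
Classes with fewer than three members or zero score SD are never flagged —
an SD estimated from two points is not a threshold. Detection is
single-pass; re-running it on a cleaned dataset may flag new samples, which
is why `remove_outliers()` refuses to shrink any class below two members
rather than iterating silently.

## Differential expression and the random-removal null

DEGs are called by a per-gene two-sample Student t-test (pooled variance;
Welch optional), Benjamini–Hochberg adjustment, and the conventional
thresholds |log2 FC| ≥ 1, adjusted p ≤ 0.05 — both configurable, since
appropriate cutoffs are study-specific. The matrix is assumed to be on a
log2-like scale, so the fold change is a difference of group means;
`log2_transform = TRUE` handles linear-scale input. Zero-variance genes
are kept finite by convention: equal means give $t = 0, p = 1$; unequal
means with zero pooled variance give $p = 0$ with a `ZeroVariance` marker
rather than NaN.

`compare_outlier_removal()` reports DEG counts with and without the
flagged samples. Because removing *any* samples changes counts, the gain
is judged against `random_removal_null()`: repeatedly remove the same
number of samples per class uniformly at random (stratified, so the null
matches the flagged samples' class composition — the fair comparison),
recount DEGs, and compare. Each repetition draws from a deterministic
sub-seed of the master seed, so the null vector is reproducible and
independent of evaluation order.

## Single cells and viral load

For virus-inclusive single-cell data the same score applies with
uninfected cells as the reference class, after a fixed two-step gene
filter: keep the top 30% of genes by mean expression over all cells, then
drop genes with zeros in ≥ 40% of cells. The order matters (a zero-heavy
high-mean gene consumes a slot in step 1 even though step 2 removes it)
and is asserted by a test. Means are taken on the counts as supplied; any
normalization is the caller's decision, made before the filter.

Infected cells are then split on two axes — MDP score (cutoff 1) and viral
load VL (cutoff $10^3$ viral reads) — into four quadrants, with the
boundary inclusive on the high side (score ≥ 1, VL ≥ 1000) since the
cutoff line is treated as the low/high frontier. Three contrasts run
through the identical bulk DEG machinery: doubly-high vs doubly-low cells,
the MDP axis, and the VL axis. When perturbation is only partially coupled
to viral load, the doubly-stratified contrast finds the most DEGs and the
VL axis the fewest — viral load alone is a weak marker of cell
perturbation. VL is read from cell metadata, not recomputed from viral
gene rows. No dropout imputation is attempted; zero inflation biases the
score upward for all cells alike, which the reference class absorbs only
partially, and this is a stated limitation.

## What the generators emulate — and what they do not

`simulate_bulk()` draws log2-scale Gaussian expression: per-gene baselines
uniform on [4, 12], noise SDs uniform on [0.25, 0.75] (typical for
normalized array/RNA-seq intensities), and plants three kinds of truth:

* *signal genes* shifted by `effect_size` (half up, half down) in cases;
* *outlier controls* — a hidden condition, shifted by 4 gene-SDs on a
  random 25% of genes, not globally, so it also exercises the gene
  ranking;
* *null cases* — patients with the disease label but no molecular signal.

Defaults are 200 genes × 30 samples (15/15) with one planted outlier, the
scale at which outlier recovery is tested. The `"outlier-cohort"` preset
enlarges this to 1000 genes, 12 controls (one outlier — twelve controls
mirroring a representative whole-blood cohort) and 20 cases (two null),
with a 1.1 log2 effect on 150 genes: an effect deliberately close to the
fold-change cutoff, so that diluting the case mean or inflating the
control variance visibly suppresses DEG calls — the regime in which
outlier handling matters.

`simulate_singlecell()` draws counts as Poisson around log-normal
per-gene rates, zeroes entries with probability `zero_inflation_prob`
(0.02; low-expressed genes additionally drop out through sampling zeros),
and gives each infected cell a latent perturbation state (positive part
of a standard normal, so roughly half the infected cells respond). Signal
genes — drawn from the top of the baseline distribution so they survive
the mean filter — shift in proportion to that state. Log10 viral load is
Gaussian around 3 (the cutoff) with SD 0.8 and correlation
`vl_perturbation_coupling` (default 0.4) to the latent state: high enough
that the axes are related, low enough that MDP and VL visibly disagree,
which is the phenomenon of interest.

The generators do **not** emulate batch effects, library-size variation,
gene–gene correlation, negative-binomial overdispersion, or
expression-dependent dropout. Passing tests therefore demonstrate that the
algorithms do what they claim under controlled truth — not that any
particular biological dataset will show the same effect sizes.

## Numerical conventions, in one place

* Thresholding: strict `<` zeroing; every z entry is exactly 0 or ≥ cutoff.
* Subset sizes: `max(1, floor(fraction * G))`, stable ties.
* Degenerate genes: zero row, excluded from ranking, counted.
* GMT genes absent from the matrix: silently intersected away; the size
  actually used is recorded.
* All randomness flows from one integer seed through fixed sub-streams
  (structure vs noise vs per-repetition), so any component can be held
  fixed while another varies, and seeded runs are byte-identical.

## Problem sizes used in the test suite

The suite validates against brute-force re-implementations on 50 × 20
matrices, calibrates the t-test's type-I error on 2000-gene null cohorts,
measures planted-outlier recovery over 100 replicate 200 × 30 cohorts,
and runs the two end-to-end preset analyses over 20 seeds each with
100-repetition nulls — sizes chosen so the whole suite completes in well
under a minute while keeping every estimate's Monte-Carlo error small
relative to the margins being asserted.
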