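---
title: "Methods: finding hypomethylated blocks and small DMRs with methblocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: finding hypomethylated blocks and small DMRs with methblocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methblocks)
```

## The scientific problem

DNA methylation in somatic tissues is not perturbed uniformly by age and
environmental exposure. Two very different spatial scales of change have
been described: **blocks** — domains of hundreds of kilobases to megabases,
mostly in CpG-poor "open sea" territory, that lose methylation coordinately
and correspond to heterochromatic LOCK/LAD domains — and **small DMRs** —
regions of a few hundred base pairs, usually several array probes wide,
that gain or lose methylation locally. Blocks of hypomethylation were first
characterised in colon cancer; the same phenomenon appears in epidermis
affected by the combination of age and chronic sun exposure, progressively
across the four natural exposure groups (younger/older crossed with
sun-protected/sun-exposed: Y-pro, Y-exp, O-pro, O-exp), and correlates with
a dermatologist's photoaging grade.

`methblocks` implements the complete discovery pipeline for both scales on
both measurement platforms:

* **array arm** — 450k-style beta values: SNP-probe filtering, open-sea
  probe collapsing, large-window bump hunting with permutation family-wise
  error control (blocks), and probe-level bump hunting with covariate
  adjustment (small DMRs);
* **WGBS arm** — CpG count tables: coverage filtering, local-likelihood
  smoothing, reference-group t-statistics, and filter-based block calling;
* **enrichment** — base-pair odds ratios against reference domains and a
  permutation test with width- and probe-matched random region nulls;
* **summaries** — block methylation matrices, clinical-grade regression,
  classical MDS, the progressive-ordering check, and application of a
  frozen block set to a new cohort;
* **synthetic data** — a seeded generator that emits cohorts with known
  planted truth, so every stage above is testable by parameter recovery.

## The array block model

Let $\beta_{ps} \in [0,1]$ be the methylation fraction of probe $p$ in
sample $s$. Only open-sea probes enter block finding, because islands and
shores sit on a different methylation baseline and would dominate any
large-window average. Consecutive open-sea probes separated by at most
`max_gap` (default 1,500 bp) are collapsed into one region whose
per-sample value is the arithmetic mean of its member probes.

For a two-group comparison the per-region statistic $d_i$ is the least
squares coefficient of the group indicator (equal to the difference of
group means when no covariates are supplied; sex and body site can be
adjusted for). These raw differences are then smoothed with a **weighted
running mean** over a fixed genomic window (`window_bp`, default 250 kb,
weights = member probe counts), never crossing a chromosome boundary.
Regions whose window contains fewer than `min_regions` (default 5) regions
are flagged unsmoothable and excluded. We chose the running mean over a
loess-type smoother deliberately: it is deterministic, exactly
reproducible by a brute-force oracle in the tests, and has a single
interpretable tuning parameter. Candidate blocks are maximal same-sign
runs of smoothable regions with $|\tilde d_i| \ge$ `threshold` (default
0.05 beta units) spanning more than `min_width_bp` (default 200 kb); the
block statistic is the **area** $\sum_i |\tilde d_i|$ over member regions,
and block boundaries are reported as the span from the first to the last
member region.

### Permutation family-wise inference

Significance is assessed by shuffling group labels (within covariate
strata when covariates are supplied), re-running the entire
difference–smooth–segment pipeline per permutation, and recording the
genome-wide **maximum candidate area**. The family-wise adjusted p-value
of an observed block with area $A$ is

$$\mathrm{FWER}(A) = \frac{1 + \#\{\text{perms with max area} \ge A\}}{1 + n_\mathrm{perm}},$$

with ties counted as exceedances (conservative) and the "+1" pseudo-count
guaranteeing a valid, strictly positive p-value at finite permutation
count. When the number of distinct label assignments is at most
`n_perm`, all assignments except the observed one are enumerated and the
count is exact. The max-statistic construction is the standard family-wise
device for bump-style statistics; blocks are reported at FWER < 0.05.

## Small DMRs

The DMR finder operates at probe level across **all** relation classes.
Per-probe coefficients come from least squares of beta on the group
indicator plus covariates (default sex and body site; a rank-deficient
design, e.g. a covariate confounded with group, is rejected with the
offending term named). Probes are clustered by an inter-probe gap of at
most `cluster_gap` (default 500 bp — the paper-scale DMR of ~460 bp must
be representable; the value is exposed in the interface); maximal
same-sign runs with $|{\rm coef}| \ge 0.1$ and at least `min_probes`
(default 2 — a single probe is not a region) become candidates, and the
same max-area permutation machinery yields family-wise p-values, reported
at FWER < 0.1. Block and DMR analyses share no thresholds; each call set
echoes its own parameters.

## The WGBS arm

Input is one count table per sample (chromosome, CpG position, methylated
reads, total reads). A CpG is retained when every one of the four groups
passes the coverage rule. The phrase "coverage of 2 or greater in each
sample group" admits two readings; the default (`mode = "group_total"`)
requires the group's **summed** coverage to reach `min_cov` with at least
one covered sample, and a strict per-sample mode is available behind the
same flag. The default suits 3-samples-per-group designs at ~6x depth,
where demanding 2 reads in every sample would discard a large fraction of
sites.

Smoothing is a coverage- and distance-weighted **local linear fit**
(tricube distance weights times read counts) over the smallest symmetric
window holding at least `min_cpgs` CpGs and spanning at least
`min_window_bp`, evaluated at each CpG and clipped to $[0,1]$. Two presets
are provided: `local` (70 CpGs / 1 kb) for fine-scale estimates and
`large` (500 CpGs / 20 kb) for block hunting; block-scale smoothing must
be much wider than a DMR so that megabase-scale structure, not local
variation, drives the statistic. The smoother is shift-equivariant
(adding a constant shifts the fit by that constant), which the tests
assert directly.

Per CpG the statistic is

$$t_j = \frac{\bar m_{A,j} - \bar m_{B,j}}{\mathrm{sd}^{\rm ref}_j + f},$$

where $\mathrm{sd}^{\rm ref}_j$ is the standard deviation of the smoothed
values across the **reference group** samples (default Y-pro, the
unexposed baseline; at least 2 samples required), itself smoothed over the
same window, and $f$ is a **variance floor** set to the 75th percentile of
the genome-wide $\mathrm{sd}^{\rm ref}$. Without a floor, near-constant
CpGs produce unbounded t-values; the 75th percentile keeps the denominator
on the scale of typical between-sample variation. Blocks are maximal
same-sign runs with $|t| \ge 2$, allowing intra-run CpG gaps up to 1 kb,
filtered to width > 10 kb, at least 10 CpGs, and raw pooled group
difference > 5%. No permutation inference is applied on this arm — the
effect-size and width filters are the only gate, matching the published
analysis, which reported none for sequencing-based block calls.

## Enrichment against reference domains

Two statistics are kept deliberately distinct. The **base-pair odds
ratio** crosses query and reference membership over a finite universe into
a 2x2 bp table, $\mathrm{OR} = ad/bc$, with the Haldane 0.5 correction
applied (and flagged) only when a cell is zero; a chi-square p-value on
this table is reported as secondary and labelled approximate, because
adjacent base pairs are strongly autocorrelated. The **permutation
overlap test** counts query regions overlapping the reference by at least
1 bp and compares this to the same count over random region sets matched
to the query in width and probe count (each template region gets a
probe-anchored start whose window holds exactly the template's probe
count where feasible — infeasible regions are width-matched and logged);
a query is significant when its count strictly exceeds the null's 95th
percentile. Region-level overlap matches the published "how many
identified regions overlap" reading; the bp unit for odds ratios is an
explicit, logged parameter.

## Downstream summaries

The block methylation matrix (samples x blocks, mean methylation of the
measured sites in each block) is the tested artifact behind any heatmap:
rows ordered by sample mean, columns by group mean difference. Clinical
correlation is ordinary least squares of grade on per-sample mean block
methylation with $R^2$ and slope p-value, plus a subset filter (the
published variant excludes face samples). MDS is classical scaling on
Euclidean distances between beta vectors — the distance is a package
choice, exposed as such, since the source analysis names only "pairwise
distances" — with axis signs fixed by a largest-coordinate-positive
convention for reproducibility. The progressive-ordering verdict is true
when Y-pro has strictly the highest and O-exp strictly the lowest mean
block methylation with both intermediates between; under exchangeable
(null) groups this happens with probability $2/4! = 1/12$, which the
acceptance checks verify. `apply_blocks_to_cohort()` freezes a block set
(hash-checked) and recomputes block means and inside/outside densities on
a new cohort, the design used for the carcinoma comparison.

## The synthetic generator: what it emulates, and what it does not

The generator is the package's study stand-in, and its defaults are the
study conditions used throughout the tests:

* genome: 3 chromosomes x 20 Mb, ~6,000 array probes (15% island, 15%
  shore, the rest open sea), ~200,000 WGBS CpGs at ~300 bp spacing —
  minutes-scale, while preserving the density relations that matter
  (open-sea probes every ~15 kb, as on the real array in these regions);
* blocks: 15 disjoint regions drawn 202 kb–1.3 Mb, planted away from
  islands, with per-block methylation drops drawn from 5.2–16% (or fixed
  at 9% in recovery checks) — the published effect range;
* small DMRs: ~460 bp, |change| 0.37, carried by clusters of 4 probes on
  a mid-baseline (shore-like) so both directions stay inside $[0,1]$;
* group structure: O-exp carries the full planted drop, Y-pro none, and
  the intermediates (O-pro, Y-exp) a fraction 0.4 — the published heatmap
  shows this progressive gradient but does not parameterise it, so the
  fraction is an exposed configuration value;
* block edges taper linearly over 10 kb (the within-block spatial profile
  is not described in the source; flat-with-taper is the default and both
  the taper and a flat profile are configurable);
* array noise: truncated Gaussian on the beta scale, sd 0.05 (a
  logit-normal alternative is available); WGBS: per-site Gaussian
  perturbation of the methylation probability, Poisson coverage (default
  mean 6, within the published 5.6–7.2x), Binomial methylated counts;
* clinical grades: affine in mean block methylation plus noise scaled to
  a target population $R^2$, rounded to the integer 0–8 photoage scale
  (rounding slightly attenuates the realised $R^2$, visible in the
  round-trip checks).

It does **not** simulate probe chemistry (Infinium I/II effects), cell
composition, read-level artefacts, bisulfite conversion failure, or
genuine biological autocorrelation beyond the planted structure. Passing
recovery tests on these cohorts therefore demonstrates the pipeline's
correctness and calibration under the stated noise model — not robustness
to array normalisation artefacts or cellular heterogeneity, which are
upstream of this package's inputs.

## Numerical and interface choices

* Intervals are `GRanges` (1-based, closed) throughout, with all interval
  algebra delegated to `GenomicRanges`; BED files are read and written in
  their native 0-based half-open convention via `rtracklayer`, so exactly
  one conversion exists, at the file boundary.
* Every generator and permutation consumes an explicit seed; pipeline
  stages derive independent substreams from one manifest seed by stable
  string hashing (`substream_seed()`), so a run directory is reproducible
  bit-for-bit from its manifest.
* Missing beta values are allowed: collapsed region means ignore them
  per probe; inside the permutation engine remaining gaps are mean-imputed
  per unit so the label-permutation algebra stays exact.
* Ties between a null max-area and an observed area count against the
  observed block (conservative).
* Degenerate smoothing windows (zero positional spread) fall back to the
  weighted mean; chromosomes with fewer retained CpGs than a window falls
  back to a chromosome-wide weighted mean with a warning.
* The pipeline runner validates its YAML configuration against a closed
  schema — unknown keys are errors, naming their path — and refuses to run
  a stage whose upstream output is absent, naming the dependency.

## Problem sizes used by the test suite

The packaged checks run the full pipeline at the default desk scale
(3 x 20 Mb, 10 samples per group, 400 permutations for observed calls,
200 for the 100-replicate null-calibration loops, 3 per group at 6x for
the sequencing arm, 600 matched random sets for enrichment calibration and
100 x 100 for power). These sizes were chosen so each module's check
exercises the same code paths as a full-size analysis in minutes on one
core; all of them are configuration values, not constants.

## Known limitations

* Block boundary estimates shrink by roughly half a smoothing window at
  each edge (the smoothed difference must cross the threshold), so blocks
  near the 200 kb width filter can occasionally be missed at array probe
  density; the sequencing arm, with ~50x denser sites, does not share
  this limit. This mirrors the real platforms' relative resolution.
* The bp odds ratio's chi-square p-value ignores spatial autocorrelation
  and is reported only as a labelled approximation; the matched-null
  permutation p is the primary inference.
* Covariate adjustment assumes a fixed, balanced design within strata;
  permutations shuffle labels within covariate strata, which requires
  each stratum to contain samples from both comparison groups.
* No probe-type bias correction or cell-composition adjustment is
  performed; inputs are assumed normalised.
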