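---
title: "Group-based rare-variant association scans with Higher Criticism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-based rare-variant association scans with Higher Criticism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcscan)
```

## The problem

Whole-genome sequencing panels are dominated by rare variants, whose
single-variant association tests are individually powerless. The remaining
undiscovered genetic effects on complex quantitative traits are typically
*sparse* (few causal variants among many tested) and *weak* (small per-allele
effects). `hcscan` implements a group-based testing strategy for this regime:
variants are grouped into genomic units, rare variants inside each group are
collapsed into burden-style pseudo-variants, and the group is scored by a
statistic calibrated per group by permutation.

Three group statistics are provided and always computed on the same
permutation draws so they can be compared fairly:

* **Higher Criticism (HC).** With ordered two-tailed per-column p-values
  $p_1 \le \dots \le p_n$ from a group's design,
  $$\mathrm{HC}_n \;=\; \max_{1 \le i \le n/2,\; p_i \ge 1/n}
  \sqrt{n}\,\frac{i/n - p_i}{\sqrt{p_i(1-p_i)}},$$
  the maximal standardized departure of the empirical p-value distribution
  from uniform. HC is asymptotically optimal for detecting sparse, weak
  signal mixtures: it fires when *more small p-values than expected* are
  present, even if none is individually extreme.
* **minP.** The smallest per-column p-value. Most powerful when the group
  contains one strong signal.
* **SKAT (flat weight).** The variance-component score statistic
  $Q = r^\top G G^\top r$ on the group's *original, uncollapsed* dosages
  $G$, with $r$ the trait residuals under the null model. The flat
  (unweighted linear) kernel makes SKAT directly comparable to equal-weight
  collapsing for HC. An analytic tail probability from the mixture-of-
  chi-squares null is available; the comparison-grade p-value in scans is
  the permutation one, for parity with HC and minP.

## Data model and workflow

Genotypes are dosages in $[0,2]$ per sample and variant — hard allele counts
or fractional imputed doses — read from a tab-separated "dose" matrix
(`read_dose_matrix()`) or a VCF (`read_vcf()`, `DS` preferred over `GT`;
multi-allelic records are rejected because the collapsing model assumes one
dosage per site). Analysis is restricted to the complete-case sample —
individuals present in both genotype and phenotype tables with no missing
genotype and a finite trait value (`filter_complete_cases()`) — and every
downstream frequency estimate uses exactly this retained sample. Minor
allele frequency is the folded dosage proportion
$\min(f, 1-f)$, $f = \sum_j d_j / (2\,n_\text{obs})$.

Grouping is either by fixed windows (`make_fixed_windows()`) — 1-based
inclusive tiles $[kW{+}1, (k{+}1)W]$ anchored at position 1 per contig, the
customary widths being 10, 100 and 500 kb — or by user-supplied intervals
(genes via BED, `read_bed()`); a variant joins every interval containing its
position, so gene groups may overlap while windows never do. We anchor
windows at position 1 rather than at the first variant: it makes window
identity independent of which variants segregate in a particular sample.

### Collapsing

Within a group, variants with MAF strictly below the threshold (0.01 or
0.05 by convention) are *rare*. Walking the group in genomic order, every
maximal run of consecutive rare variants between adjacent common variants
becomes one pseudo-variant column, the weighted sum of its members'
dosages; common variants pass through unchanged. Runs at the group's edges
(before the first or after the last common variant) are collapsed too, so
every rare variant contributes to exactly one column. Weights are either
equal (unit) or Madsen–Browning,
$w_j = 1/\sqrt{n\,\hat q_j (1-\hat q_j)}$ with the smoothed frequency
$\hat q_j = (c_j + 1)/(2n + 2)$, which up-weights rarer variants. The
original weighting scheme estimates $\hat q$ from unaffected controls; a
quantitative trait has none, so we estimate it from the full retained
sample — the natural adaptation, and the add-one smoothing keeps every
weight finite.

### Per-column tests

Each design column is tested by the two-sided slope t-test of the simple
linear regression of the trait on the column (optional covariates are
residualised out of both first). Two-sided, because genetic effects can go
in either direction. A constant column gets $p = 1$ by convention.
P-values are clamped into $(0, 1]$.

### Permutation calibration

Group statistics have null distributions that depend on the number of
columns and their LD, so each group is calibrated by its own permutation
null: the phenotype-to-sample alignment is permuted $B$ times (1000 by
default) and all statistics are recomputed on the shared draws. Permuting
the phenotype alignment is equivalent, within a group, to permuting the
genotype rows, and is cheaper. The collapse structure and MAFs are
phenotype-free and therefore frozen before permutation. The empirical
p-value counts permutation statistics *equal or more extreme* than the
observed one; the default add-one rule $(r+1)/(B+1)$ never returns zero
and is super-uniform under the null, while the literal proportion rule
$r/B$ is available for reproducing proportion-style outputs.

Per-group random streams are derived from the master seed and the *group
name* (not its position in the work list), so scans are reproducible
byte-for-byte and per-group results do not depend on processing order or
parallel scheduling.

### Degenerate cases and numerical choices

* **HC index bound.** The upper index $n/2$ is taken as
  $\lfloor n/2 \rfloor$; for $n = 1$ the index set is empty.
* **HC sentinel.** If every usable $p_i$ lies below $1/n$ (an extreme
  departure from uniformity), no index is eligible and the statistic is
  reported as $+\infty$. The permutation counter treats the sentinel as
  most extreme, and $\infty$ ties with $\infty$, so sentinel-heavy small
  groups calibrate conservatively rather than spuriously. Note the guard's
  flip side: a *solitary* extremely small p-value is excluded by
  $p_i \ge 1/n$, so HC has limited power against a single strong variant —
  that regime belongs to minP, and the regime tests below confirm it.
* **Ties.** Sorting is stable; the HC formula is tie-insensitive. Variants
  at identical positions keep input order; adjacency for run collapsing is
  by column order.
* **Constant designs.** A group that collapses to an entirely constant
  design is emitted with $p = 1$ for every method, with a warning.
* **SKAT tail.** Eigenvalues of the projected kernel below
  $10^{-12}\,\|G\|_F^2$ are treated as rank deficiency. The analytic tail
  is computed by Imhof-type numerical inversion of the characteristic
  function, integrating one oscillation period at a time until the
  contributions vanish; a Liu-type four-moment chi-square approximation is
  the fallback if the quadrature fails. A rank-one kernel is evaluated
  exactly as a 1-df chi-square, where the statistic coincides with the
  per-variant score test.

## The synthetic panel

`simulate_genotypes()` emulates the features of a sequencing panel of
unrelated individuals that matter for these tests, without attempting to
reproduce any particular cohort:

* **Sample size 142** by default — the scale of a small complete-case
  sequencing panel, deliberately in the low-power regime where group tests
  earn their keep.
* **Rare-skewed MAF spectrum**: 70% of variants draw MAF uniformly from
  $[0.002, 0.05)$, the rest from $[0.05, 0.5]$.
* **Block LD** via a Gaussian copula: each haplotype is a latent Gaussian
  vector with exchangeable correlation $\rho = 0.2$ inside blocks of 10
  adjacent variants, thresholded at the $q_j$-quantile; the two haplotype
  draws sum to the dosage, so $\rho = 0$ recovers Binomial$(2, q_j)$
  Hardy–Weinberg dosages exactly. Correlated columns are the feature the
  per-window permutation exists to handle; two independent haplotypes (not
  one latent draw thresholded twice) are required for heterozygotes to
  exist at all.
* **Equally spaced positions** (25 variants per 10-kb window by default),
  so window occupancy is deterministic and tests are readable.

`simulate_phenotype()` plants sparse weak effects: by default 5 causal
windows, each with 1–3 causal rare variants, per-allele effects of
magnitude $|\beta| \sim U[0.4, 0.8]$ trait SDs with random sign, unit noise
SD. At $n = 142$ this puts single-variant power in the weak regime
(roughly 0.1–0.3 at $\alpha = 0.05$), which is the regime of interest. A
window is *true* iff it contains at least one causal variant; truth is
used only for scoring, never inside the tests.

What the simulator does **not** model: realistic site frequency spectra
from population genetics, recombination-driven LD decay, family structure,
genotyping error, or covariate confounding. Calibration and power results
on this panel therefore demonstrate the statistical machinery, not
performance on any real cohort.

## Evaluation utilities

`genomic_lambda()` maps p-values to 1-df chi-square quantiles and reports
the median ratio against 0.4549; `qq_table()` pairs sorted p-values with
$i/(n{+}1)$ expectations. `power_curve()` reports the true-positive rate
of true windows over the full cutoff range $(0,1)$ — essentially an ROC
curve — with AUC by trapezoid over the empirical step function evaluated
at every distinct p-value plus the endpoints (the natural completion when
no particular grid is prescribed). `per_window_power()` scores each true
window across simulation replicates and labels its best method, with a
"none" class when every method's power is below a floor (0.1 by default).

## A worked scan

```{r example, eval = FALSE}
ds <- simulate_genotypes(sim_config(seed = 1))
sim <- simulate_phenotype(ds, truth_config(), seed = 2)
groups <- assign_variants(ds, make_fixed_windows(ds, 1e4))
res <- hc_scan(ds, sim$phenotype, groups,
               collapse_config(maf_threshold = 0.05, weight_scheme = "equal"),
               perm_cfg = permutation_config(B = 1000, seed = 3))
genomic_lambda(res$hc_p)
power_curve(res, sim$truth$true_windows)
```

## Problem sizes used in the shipped checks

The package's own acceptance-style checks run at desk scale, chosen as the
smallest sizes at which the statistical claims are sharp: the null
calibration scan uses the full default panel (142 samples, 200 ten-kb
windows, $B = 1000$); power studies use a 1000-variant panel with
$B \in \{199, 999\}$ and 25–50 replicates; the strong-single-variant
regime plants one common causal variant at 0.5 SD per allele — "strong"
here means a per-window variance contribution several-fold above the weak
rare-variant default, while staying off the power ceiling so method
orderings remain visible.

## Known limitations

* No asymptotic null distribution for HC: inference is purely
  permutation-based, so genome-wide p-value resolution is limited by $B$.
* No family data, binary traits, kinship-aware permutation, or
  beta-density SKAT weights; covariates enter only by linear
  residualisation.
* Gene grouping is interval-driven; transcript and splice-form choices are
  externalized to the supplied BED.
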