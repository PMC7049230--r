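---
title: "Models and methods behind seroscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind seroscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seroscreen)
```

`seroscreen` implements the analysis chain of a two-stage serological
autoantibody study: an IP-MS antigen-capture screen (serum IgG
cross-linked to beads, incubated with cell lysate, captured proteins
identified and quantified label-free) followed by a custom antigen
microarray validating selected targets in a large case/control cohort.
This vignette explains the statistical models, the parameters that
matter, the simulators, and the design decisions taken where the
procedure left room.

## 1. IP-MS screening

### Identification filters

Three filters turn a search-engine protein-group table into a candidate
autoantigen list, applied in a fixed, idempotent order:

1. **QC flags** — reverse (decoy) hits, potential contaminants and
   proteins identified only by a modification site are removed.
2. **Replicate presence** — a protein is kept only if some non-control
   group quantified it in *every* replicate. "Quantified" means a
   nonmissing, nonzero LFQ intensity; MaxQuant-style tables write 0 for
   not-quantified, so 0 and absent both count as missing.
3. **Control exclusion** — any protein with any quantification in any
   bead-only negative control or buffer-only mock control is treated as
   background binding (to beads, tubes or secondary reagents) and
   removed. Both negative and mock groups are exclusion groups.

Each filter only ever shrinks its input, so the composed chain is
monotone and re-running it is a no-op.

### iBAQ relative abundance

iBAQ intensity (summed peptide intensity divided by the number of
theoretical peptides) is proportional to molar amount. Within a group we
summarise each protein by the mean iBAQ over replicates and report
`100 · mean_i / Σ_j mean_j`. Using the sum instead of the mean over
replicates rescales numerator and denominator identically, so the
fractions are unchanged — the choice is inert and the mean is used.
Fractions sum to 100 by construction.

### Missing-value imputation

Label-free MS missingness is left-censored: weak signals fall below the
detection limit. The screening chain therefore imputes each missing cell
of the log2 intensity matrix from a down-shifted normal,
$N(\mu_s - 1.8\,\sigma_s,\ (0.3\,\sigma_s)^2)$, where $\mu_s, \sigma_s$
are the observed mean and SD *of that sample* (column-wise). The
defaults 1.8 and 0.3 are the values proteomics practice has converged on
for this imputation family; both are exposed. A sample with fewer than
two observed values has no usable $\sigma_s$ and is an error. The same
imputation serves PCA and clustering.

### Permutation-FDR t-test

Per protein, a pooled-variance (Student) two-sample t-statistic on log2
intensities, with an optional SAM-style fudge term $s_0$ added to the
standard error (default 0). The null distribution pools statistics over
proteins across group-label permutations: all distinct assignments when
there are at most `n_permutations` (excluding the observed one),
otherwise a uniform subsample without replacement. The q-value of a
protein is

$$ q = \mathrm{median}_p \frac{\#\{|t^{*}_{p}| \ge |t|\}}{\#\{|t_{obs}| \ge |t|\}} $$

clipped to $[0,1]$ and monotonized along the $|t|$ ranking, so q never
decreases as significance decreases. Candidates pass when $q < 0.01$ and
$|\text{log2 difference}| > 2$, in either direction; both thresholds are
arguments, since published screens have quoted both FDR- and
p-value-based versions of the rule. The reported `difference` is the
difference of log2 means (group2 − group1), not a ratio of raw means.

**A resolution limit worth knowing.** At 3 vs 3 there are only 19
distinct non-identity label assignments. Pooling nulls across proteins
has fat tails: a null protein whose replicate noise happens to align
with a label split can produce $|t^*| > 10$, and with hundreds of
proteins roughly half of all permutations contain at least one such
value. The median null count at a borderline threshold is then 1 rather
than 0, capping q at `1/rank`. Consequently q < 0.01 at 3 vs 3 is
attainable only for proteins whose observed $|t|$ clears the pooled null
tail outright — a property of permutation FDR at minimal replication,
not of this implementation. The test suite demonstrates full recovery of
4-log2 shifts at replicate noise 0.3 (ratio of effect to SE ≈ 16) and
the type-I-error bound under the null at 4 vs 4, where the permutation
lattice is finer.

### Clustering and PCA

Selected proteins are z-scored across samples (mean 0, SD 1 per row);
rows and columns are clustered agglomeratively with Euclidean distance
and average linkage (`stats::hclust`), ties broken by input order.
Constant rows have no z-score and are dropped with a warning. PCA is
centred and unscaled on samples (`stats::prcomp`); variance fractions
are nonincreasing and sum to 1.

## 2. Microarray pre-processing

One serum sample occupies one of 16 incubation wells (subarrays) per
slide; each antigen is spotted in triplicate, alongside human-IgG
positive-control and buffer-blank negative-control spots. The chain,
in order:

1. **Net signal**: foreground − local background; strictly negative nets
   become missing (a spot darker than its surroundings carries no
   signal); exactly zero is kept, since only values *reaching* negative
   are invalid.
2. **Negative-control subtraction**: the mean net of the buffer blanks —
   unspecific binding of the fluorescent secondary antibody — is
   subtracted from antigen and IgG spots; negatives again become
   missing. Scope is per subarray by default (unspecific binding is
   serum-specific and each serum occupies one well); per-slide scope is
   available.
3. **Triplicate averaging**: mean of nonmissing replicates; all-missing
   triplets stay missing.
4. **IgG median-centring**: each subarray's IgG median is divided by the
   *median of the per-subarray IgG medians* to form its normalization
   factor; all of the subarray's intensities are divided by that factor,
   so high-IgG wells are scaled down and every subarray ends at the same
   IgG median. Taking the median of medians (rather than pooling all
   IgG spot values) makes one subarray's factor independent of how many
   control spots another contributes and gives an exact invariance:
   multiplying any non-reference subarray's spots by $c > 0$ leaves the
   whole NFI matrix unchanged.
5. **Winsorize-to-missing**: per target across samples, observed values
   strictly outside the 5th–95th percentile band (linear-interpolation
   quantiles) become missing — removed rather than clamped, so outliers
   neither enter the statistics nor masquerade as boundary values.
   Per-target trimming is the axis under which cross-sample comparisons
   stay meaningful, and it matches the target-wise missingness
   accounting of the next step; the percentiles are arguments.
6. **Missingness filter**: targets missing in strictly more than 25 % of
   samples are dropped (exactly 25 % is kept).
7. **KNN imputation**: for each missing cell, the k = 10 most similar
   *target columns* (RMS distance over co-observed samples, so columns
   with different overlap are comparable) supply the value — the mean of
   the neighbour's value in that row adjusted by the difference of the
   two columns' co-observed means. The adjustment makes imputation exact
   for duplicate or parallel-shifted columns. Observed cells are never
   altered. A sample row left with no observed value in any neighbour
   column (possible when a dim serum falls below every target's lower
   winsorization bound) falls back to the target's column mean.

The pipeline logs targets retained and missing-cell counts per stage
(`preprocess_audit()`) and keeps the per-subarray factors
(`norm_factors()`). Imputation operates on the NFI scale, as in the
chain above; the downstream rank tests are invariant to monotone
transforms, so a log2 view is used only for plotting.

## 3. Validation statistics

The NFI distributions are heavy-tailed (the Shapiro–Wilk pre-check
`normality_check()` is provided to log the routing decision), so
hypothesis testing is nonparametric:

* **Mann–Whitney U** with midranks; reported as rank sums per group,
  $U = \min(U_1, U_2)$, the normal approximation
  $z = (U_1 - n_1 n_2/2)/\sqrt{n_1 n_2 (N+1)/12}$ without continuity
  correction, and the tie-adjusted z using the variance
  $\frac{n_1 n_2}{12}\left[(N+1) - \frac{\sum(t^3 - t)}{N(N-1)}\right]$
  over tie groups of size $t$. Tie correction shrinks the variance, so
  $|z_{adj}| \ge |z|$ always. `u_z_from_rank_sums()` reconstructs U and
  z from a published rank sum alone, which is how summary tables are
  checked.
* **Spearman correlation** of autoantibody levels with clinical
  covariates (cup-disc ratio, visual-field mean deviation, intraocular
  pressure), pairwise-complete so valid N varies, with
  $t = R\sqrt{(N-2)/(1-R^2)}$ on $N-2$ df.
* **Kruskal–Wallis** (tie-corrected, chi-square reference) for three or
  more groups, e.g. control subgroupings.

No multiple-testing adjustment is applied across the handful of panel
targets, matching how such validation tables are conventionally
reported; `p.adjust` can be applied downstream if desired.

## 4. Classification

A single stratified random split (defaults 165 train / 75 test for a
240-sample cohort, largest-remainder apportionment across classes) and a
random forest (`randomForest`, 500 trees, $\sqrt{p}$ features per split)
estimate the panel's diagnostic potential. Metrics are the confusion
counts with sensitivity, specificity and accuracy as exact and rounded
percentages. A single split is a methodological limitation — it yields a
point estimate with substantial variance and no calibration; the package
mirrors that protocol deliberately and documents it rather than
silently substituting cross-validation.

## 5. Simulators and what passing tests mean

`simulate_ms_dataset()` draws per-protein baselines on log2 (uniform
22–30, the working range of LFQ intensities), adds the configured shift
to differential proteins in GTM-lysate groups, Gaussian replicate noise
(default SD 0.5 log2), and then censors each sample's lowest 15 % of
intensities — so missingness is intensity-dependent and the down-shift
imputation is the matched model. Background-shared proteins appear in
the control groups; everything else is structurally absent there. The
default dimensions (157 proteins, 51 background-shared, eight groups
with 3 replicates, 1 for the no-IgG controls) mirror the screen the
package is built around.

`simulate_array_dataset()` builds 15 slides × 16 wells = 240 sera
(120/120 cases/controls) with 9 targets in triplicate plus 3 IgG and 3
blank spots per well. Spot foreground is multiplicative — subarray batch
factor ($2^{N(0, 0.35)}$), target level, serum reactivity (a shared
per-subject titer component, SD 0.5 log2, plus a target-specific
component, SD 0.35) and heavy-tailed spot noise
($2^{0.25\,t_3}$) — on an additive local background (~300 counts on the
16-bit scale). The t-noise ensures normality tests reject, exercising
the nonparametric routing; the shared titer component gives targets the
between-subject correlation that makes KNN imputation informative.
Case shifts default to 1, 0.8, 0.6, 0.6 log2 on four targets, with the
first shift partially driven by a latent severity that also generates
the clinical covariates, so rank correlations are recoverable. Between-
slide variance components are not published anywhere we could anchor
them; the values above were chosen once as realistic for nitrocellulose
pad arrays and are all config parameters.

What the simulators do **not** emulate: spot morphology and spatial
artefacts, carry-over between wells, plate-position effects, batch
effects correlated with class (the simulators randomize sample-to-well
assignment), serum cross-reactivity between targets, and real antibody
prevalence distributions (reactivity is log-normal-ish by construction).
Passing tests therefore demonstrate that the chain computes its defined
quantities correctly and recovers planted structure under these
mechanisms — not that the pipeline is robust to confounded layouts or
non-multiplicative batch effects.

## 6. Numerical choices and degenerate inputs

* Quantiles everywhere are linear-interpolation (R type 7); the
  winsorization percentile definition is exposed because dialects
  differ between analysis suites.
* `mann_whitney()` errors when all pooled values are identical (zero
  rank variance); `spearman_test()` errors below 3 complete pairs or on
  constant input, and snaps $|\rho|$ within $10^{-12}$ of 1 to exactly
  1, reporting $t = \pm\infty$, $p = 0$.
* The permutation test enumerates label assignments with `combn` when
  few, samples without replacement otherwise; the observed assignment is
  excluded from the null pool.
* Problem sizes in the test suite (e.g. 50 null screens of 500 proteins
  at 4 vs 4, five-seed power runs, single full-size array cohorts) were
  chosen so each property is measured with adequate Monte-Carlo
  resolution while the whole suite runs in well under a minute.
* All randomness flows from explicit seeds; `run_pipeline()` derives
  per-stage seeds from the master seed and records them, with the config
  hash, in `provenance.json`.

## 7. Known limitations

* The permutation-FDR q-value at minimal replication is quantized (see
  above); FDR thresholds tighter than the permutation resolution are
  unattainable regardless of effect size.
* KNN imputation assumes between-target correlation; on a panel of
  mutually independent targets it regresses to column means.
* The negative-control subtraction scope (subarray vs slide) changes
  results when unspecific binding varies within a slide; both are
  offered, per-subarray is the default.
* The classifier's single-split protocol yields high-variance estimates
  on 75 test samples; confidence intervals are deliberately not printed
  to avoid suggesting precision the design cannot support.
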