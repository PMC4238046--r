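---
title: "Methods: translatome-switch analysis with transwitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: translatome-switch analysis with transwitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transwitch)
```

# Scope and model

`transwitch` analyses paired translatome/transcriptome expression studies:
the same conditions profiled twice, once from polysome-bound RNA (heavy
sucrose-gradient fractions; the TL compartment) and once from total RNA
(TR). The biological question is which genes change their ribosome loading
without a concurrent change in total mRNA — translation-exclusive
regulation. The package also covers the companion measurements such
studies use to validate individual genes: spike-in-normalized qPCR across
gradient fractions, and protein/mRNA decay kinetics.

This vignette records the statistical model of each stage, the parameters
that matter, the choices made where the design was genuinely open, and
what the synthetic-data generators do and do not emulate.

# The Z-ratio differential engine

## Procedure

For one contrast (test vs reference condition, within one compartment):

1. **Detection filter.** An observation is "detected" when its detection
   p-value is ≤ `detection_p_max` (default 0.02, the conventional
   bead-array cutoff). A gene is retained when it is detected in at least
   half (rounded up) of the samples of at least one of the two groups.
   The per-gene scope of the published recipe is not fully specified, so
   the rule is configurable: `"half"` (default), `"all"`, `"any"`.
2. **Z-score transformation.** Each retained column is standardized to
   mean 0, SD 1. The *population* SD (divide by n) is used so the
   transformed column has SD exactly 1; intensities are log10 throughout.
3. **Z-ratio.** Per gene, the difference of group-mean Z-scores, divided
   by the population SD of those differences across all retained genes.
   The statistic is dimensionless, approximately standard normal under a
   pure null, antisymmetric under contrast reversal, and invariant to any
   per-sample affine rescaling of the intensities.
4. **t-test.** Two-sample, two-tailed Student's t-test on the per-sample
   Z-scores, equal-variance by default (`welch = TRUE` switches). Zero
   pooled variance is guarded to p = 1 and flagged.
5. **Variance exclusion.** Genes whose pooled within-group SD of Z-scores
   strictly exceeds the 95th percentile of all genes are excluded
   (`variance_threshold = 1` disables the screen). An ANOVA variant is
   available: one-way ANOVA across replicate batches, excluding genes at
   p < threshold. Whether the original screen acted across groups or
   across replicates is ambiguous; the quantile rule is the default
   because it is monotone, distribution-free and directly targets "large
   variance".
6. **Empirical FDR.** See below.
7. **Significance call.** `significant = |Z-ratio| ≥ 1.5 AND FDR ≤ 0.3 AND
   p < 0.05 AND not excluded`. Boundary conventions: the Z-ratio gate is
   inclusive (a value of exactly 1.5 passes, for determinism), the FDR
   gate inclusive, the p gate exclusive. All three thresholds are
   parameters of `diff_params()`.

## The permutation FDR

The published recipe names an FDR threshold but not an estimator. We use
a label-permutation tail-area FDR because it is assumption-light and
directly testable on synthetic data; the method name is recorded in the
result metadata so downstream consumers know which estimator produced the
numbers. Whether the original was a local or tail-area quantity is
unknowable; tail-area is implemented and documented.

Design details, each of which matters in a 3v3 design:

* **Null set.** All distinct unordered relabelings of the contrast's
  samples into two groups of the original sizes, *excluding the identity
  split*. A 3v3 contrast has 10 distinct unordered splits; the identity
  reproduces the observed statistics and would floor every FDR at 1/10,
  so the 9 non-identity splits form the null (a warning reports the count
  when fewer than `n_permutations` exist; with larger designs a seeded
  random subset of the requested size is drawn).
* **Common scale.** Permuted group-mean differences are divided by the
  *observed* across-gene SD (the observed Z-ratio denominator), not
  re-standardized per permutation. Re-standardizing makes the statistic
  scale-free, so with few replicates the planted signal that leaks into
  every relabeling (a 3v3 relabeling always carries 1/3-strength effects)
  is inflated back to full standardized magnitude, and the estimated FDR
  of even arbitrarily strong true effects tends to 1. A fixed denominator
  keeps null and observed statistics on one common scale and preserves
  the estimator's calibration under a pure null, where the two
  conventions coincide in expectation.
* **Tail-area ratio and smoothing.** For gene g with threshold
  t = |Z-ratio(g)|: `fdr(g) = min(1, mean over permutations of
  #{null |z*| ≥ t} / #{observed |z| ≥ t})`, then monotone-smoothed: each
  gene receives the smallest raw estimate among thresholds at or below
  its own, so FDR is non-increasing in |Z-ratio|.

# The switch partition

A gene is **exclusive-TL** when it meets the full significance criteria in
the translatome and not in the transcriptome; symmetric for exclusive-TR;
**shared** when significant in both; **null** otherwise. The four sets are
asserted to be a disjoint cover on every run.

Open choices, resolved as follows:

* "Concurrent change" means the TR contrast meets the full criteria *in
  any direction* (the default), since the screening rule eliminates on any
  observed transcriptome change. With `direction_match = TRUE` only a
  same-direction TR change eliminates; a gene significant in both
  compartments with opposite directions is then assigned exclusive-TL
  (the screen is translatome-centric), which keeps the partition a
  disjoint cover.
* Genes that failed the detection filter in either compartment are
  assigned to null and flagged (`detection_failed`), never silently
  dropped.
* Top tables rank an exclusive set by |Z-ratio| in its own compartment,
  ties broken by p-value then gene id, so the ordering is deterministic.

# 5′-UTR motif over-representation

Coordinates are 0-based with the TSS at position 0; the search window
`[0, 200)` is half-open and a match counts when its *start* lies inside
the window, even if the match extends past the window end. Overlapping
matches are all reported by `scan_window()`, but enrichment counts are
gene-level: a gene counts once however many matches it carries.

`discover_motifs()` enumerates the exact ACGT k-mers observed in at least
2 target windows rather than all 4^10 possibilities: k-mers absent from
the targets can never be enriched, so the restriction is statistically
inert for ranking while keeping the scan at desk scale. Each candidate is
scored with the hypergeometric upper tail P[X ≥ k] for k of n target genes
carrying the motif against K of N universe genes, and Bonferroni-corrected
over the number of scored k-mers (the least assumption-laden correction,
since the candidate set is data-dependent). IUPAC degeneracy codes are
accepted in query motifs; scanning is sense-strand only, because 5′-UTRs
are mRNA-sense — the reverse complement is only consulted inside the
strand-bias diagnostic.

Bias diagnostics guard the comparisons that most often confound naive
motif enrichment: Wilcoxon rank-sum tests for GC-content and UTR-length
differences between targets and background, an exact binomial test of
sense vs reverse-complement match counts (null 0.5), and a
Kolmogorov–Smirnov test of match-start positions against uniformity on
the window (reported as NA with a reason below 5 matches). PWM comparison
slides the candidate along the reference without gaps, requires ≥ 4
overlapping columns, and takes the offset maximizing the mean per-column
Pearson correlation; zero-variance (e.g. uniform) columns contribute 0,
and score ties prefer the smallest |offset|.

# Polysome fraction quantification

Each fraction's RNA receives a fixed quantity of exogenous luciferase
mRNA before reverse transcription, so the ratio
`efficiency^(Ct_spike − Ct_target)` cancels per-fraction recovery
differences exactly — adding any constant to both Cts of a fraction
leaves its percent unchanged, which is asserted in tests. Amplification
efficiency defaults to 2 (perfect doubling per cycle) and is configurable
per assay in `(1, 2]`. Percentages are computed *per replicate* and then
averaged — not from pooled Cts — matching the per-experiment spiking
protocol. The heavy-polysome share sums fractions 9–11 of the 11-fraction
gradient by default. Condition comparisons use equal-variance two-tailed
t-tests per fraction and on the heavy share, with degenerate inputs
guarded (identical replicate sets give difference 0, p = 1).

# Decay kinetics

The "logarithmic fit" of a chase experiment is interpreted as first-order
kinetics: ordinary least squares of ln(abundance) on time, k = −slope,
half-life = ln 2 / k. This is the standard chase-experiment model and the
only interpretation consistent with exponential-looking decay on a linear
axis. Replicates are pooled into one regression by default (per-replicate
fits can be run by splitting the table). A non-negative slope is reported
as `stable` with infinite half-life rather than an error, since flat
courses are a real outcome of such experiments. The half-life CI is a
residual-resampling bootstrap (default 1000 resamples, percentile
interval); infinite bootstrap half-lives are retained and handled by the
percentile quantiles. Time units are hours throughout; `read_time_course()`
converts a `time_min` column on load and normalizes raw densitometry
(target band / loading-control band, rescaled to 1 at t = 0).

# The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated; their defaults are fixed, not tuning knobs.

**Expression studies** (`gen_expression()`): two conditions, both
compartments, three biological replicates (matching the triplicate design
of such studies), log10-normal intensities — a per-gene baseline uniform
on [1, 3.5] log10 units plus Gaussian noise of SD 0.2 (the published
studies report no within-group variance, so this is a plausible-scale
choice, not an estimate from deposited data). Genes are assigned to
regulation classes `tl_only` / `tr_only` / `both` / `null` (defaults 4% /
4% / 4% / 88%), and regulated genes receive an additive log10 offset with
random sign in the test condition's regulated compartment(s).

The offset is *calibrated per generation*: the realized mean |Z-ratio| of
planted genes is matched to `effect_size` by root finding on the actual
generated data, because the studies report effects only on the Z-ratio
scale. Two structural facts shape this calibration. First, the Z-ratio
standardizes by the across-gene spread, so the planted fraction bounds
the achievable statistic. Second, planted offsets also inflate the
per-sample SD used in Z-scoring, which breaks the baseline cancellation
for null genes and caps the realized statistic well below the naive
`1/sqrt(fraction)` bound — the realized effect is non-monotone in the
offset. The calibration therefore locates the peak first (`optimize`) and
root-finds below it; requests beyond the peak saturate at the largest
achievable value with a warning. With the default 8% planted per
compartment, effect sizes up to ≈ 3.2 are representable; `effect_size = 4`
saturates, which the tests exercise deliberately. Detection p-values are
uniform on [0, 0.02] for detected observations and (0.02, 1] for failures
(probability `detection_fail_rate = 0.05`), since only the 0.02 cut
matters downstream.

**UTR sets** (`gen_utrs()`): background sequences are i.i.d. nucleotides
at configurable GC (default 0.5); each target carries one planted motif
copy with probability `plant_rate`, at a uniform start inside the window
that also fits the sequence. The default length of 150 nt is a
median-scale human 5′-UTR; the 200 nt window is simply clipped at the
sequence end, as it is for real short UTRs.

**Fraction tables** (`gen_fractions()`): a monosome peak (Gaussian at
fraction 3) plus a broad polysome mass (Gaussian at 8.5) over 11
fractions; `shift` moves exactly that share of total mass into the heavy
set, so recovered heavy-share differences equal the planted shift by
construction. Spike Cts vary per fraction and replicate (SD 1 cycle) to
emulate recovery differences that normalization must cancel; measurement
noise (SD 0.05 cycles) is separate and can be set to 0.

**Decay courses** (`gen_decay()`): `2^(−t/half_life)` times mean-one
multiplicative lognormal noise with coefficient of variation `cv`. The
default half-life of 4.5 h is the reported stability of the eIF4E1
protein under cycloheximide chase, the package's reference kinetic
parameter.

All generators are deterministic given (configuration, seed), restore the
caller's RNG stream, and return planted truth for parameter-recovery
tests.

## What the generators do not emulate

No probe-level bead data, batch or spatial array artifacts, probe-to-gene
summarization, dye or amplification biases, heteroscedastic per-gene
variances, correlated genes, composition effects between TL and TR pools,
UTR secondary structure or codon effects, gradient A254 traces, or
synthesis-plus-decay joint kinetics. Passing tests therefore demonstrate
the correctness and calibration of the *computations* under the stated
noise model — not robustness to every artifact of real array or qPCR
data.

# Numerical conventions and degenerate inputs

* Population SD in Z-scoring and the Z-ratio denominator; sample SD in
  t-tests and variance screens (the conventional choices for each).
* Zero Z-ratio denominator (e.g. test ≡ reference) → all-zero Z-ratios
  with a warning. Zero column SD → error naming the sample. Empty
  detection-retained set → warning plus an all-excluded result, not an
  error.
* Hypergeometric edge cases: K = 0 gives enrichment 0, p = 1; k = K = n =
  N gives enrichment 1, p = 1.
* `quantile(type = 7)` for the variance screen; strict inequality above
  the cutoff so `threshold = 1` disables exclusions.
* Ties in ranking are always broken deterministically (documented orders);
  seeded RNG streams are isolated with a local seed helper.

# Problem sizes used in validation

The shipped tests run studies of 2000 genes × 12 samples (with 20-seed
replication for the calibration checks), motif universes of 550 sequences,
and decay courses of 15 observations — sizes at which every distributional
property we assert is already stable, chosen as the package's standard
validation conditions.

# Known limitations

* The permutation FDR has coarse resolution in 3v3 designs (9 null
  relabelings); it is accurate in the tails that matter for calling but
  quantized elsewhere.
* The variance-exclusion screen always removes its configured quantile of
  genes on homoscedastic data (by construction), trading a fixed ~5%
  recall loss for robustness against variance outliers.
* Motif discovery is exact-match k-mer based; degenerate or spaced motifs
  are only found through their exact realizations, and PWM refinement is
  out of scope.
* `compare_pwm()` is ungapped; motifs differing by indels score low.
* The decay fitter assumes a single first-order component; biphasic decay
  will show in the residuals and R², not in the point estimate.
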