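# transwitch

Translatome-switch analysis for polysome profiling studies.

When a cell reroutes translation — for example when the balance between the
cap-binding initiation factors eIF4E1 and eIF4E3 shifts — many mRNAs change
their ribosome loading without any change in their total abundance. Studies
of this "translational switch" profile two RNA pools from the same cells on
the same array platform: the **translatome** (TL; mRNA from the heavy,
polysome-bound sucrose-gradient fractions) and the **transcriptome** (TR;
total mRNA). The genes of interest are those regulated *exclusively* at the
translational level: significant in TL with no concurrent significant
change in TR.

`transwitch` implements that analysis end-to-end for R users, together with
the companion assays such studies lean on, and ships seeded synthetic-data
generators with planted ground truth so that every stage can be exercised
and validated offline.

## The statistics at its core

**Z-ratio differential expression.** Log10 intensities are filtered by
detection p-value (observations kept at p ≤ 0.02), each array is
standardized by the Z-score transformation z = (x − mean)/SD (population
SD, retained genes only), and each gene's effect is the Z-ratio

    Z-ratio(g) = ( z̄_test(g) − z̄_ref(g) ) / SD_genes( z̄_test − z̄_ref )

— the difference of group-mean Z-scores scaled by the spread of such
differences across all genes. Significance is the conjunction
|Z-ratio| ≥ 1.5, empirical FDR ≤ 0.3 and two-tailed t-test p < 0.05, after
a variance-exclusion screen. The FDR is estimated by group-label
permutation: null Z-ratios from all distinct non-identity relabelings of
the contrast's samples, tail-area ratios monotone-smoothed in |Z-ratio|.

**Switch partition.** TL-significant genes are eliminated when the TR
contrast also meets the full significance criteria, yielding the disjoint
partition {exclusive-TL, exclusive-TR, shared, null} and its Venn counts.

**5′-UTR motif over-representation.** Every 10-mer observed in ≥ 2 target
5′-UTR windows (starts within 200 nt of the TSS, 0-based half-open) is
scored with the hypergeometric upper tail P[X ≥ k] on gene-level counts
(N, K, n, k), Bonferroni-corrected over the scored k-mers, and screened for
GC, length, strand and localization bias; candidate PWMs can be compared
against a reference (e.g. the TOP motif) by best-offset mean column
correlation.

**Polysome fraction quantification.** Per-fraction qPCR Ct values are
normalized to a spiked exogenous luciferase control,
quantity = efficiency^(Ct_spike − Ct_target), expressed as percent of the
gradient total, and compared between conditions per fraction and as the
heavy-fraction (#9–11) share.

**Decay kinetics.** Protein (cycloheximide chase) and mRNA (actinomycin-D
chase) stability courses are fit by ordinary least squares of
ln(abundance) on time; half-life = ln 2 / k with a residual-resampling
bootstrap CI.

## Worked example

```r
library(transwitch)

# a synthetic paired TL/TR study: 2000 genes, 3 replicates, planted
# regulation classes calibrated to mean |Z-ratio| = 3
sim <- gen_expression(gen_config(n_genes = 2000, effect_size = 3, seed = 1))

params <- diff_params(n_permutations = 9)   # all distinct 3v3 relabelings
tl <- diff_contrast(sim$study, sample_contrast("E1", "EV", "TL"), params)
tr <- diff_contrast(sim$study, sample_contrast("E1", "EV", "TR"), params)
tl
#> Z-ratio differential result: E1 vs EV [TL]
#>   2000 genes, 2000 retained by detection, 152 significant (81 up, 71 down)

part <- partition_switch(tl, tr)
part
#> Switch partition of 2000 genes
#> exclusive_tl exclusive_tr       shared         null
#>           90           95           62         1753

switch_confusion(part, sim$truth)
#>          partition
#> truth     exclusive_tl exclusive_tr shared null
#>   tl_only           79            0      1    7
#>   tr_only            0           83      0    5
#>   both               2            4     61    1
#>   null               9            8      0 1740

# protein stability: triplicate chase at the 4.5 h default with 10% noise
course <- gen_decay(half_life = 4.5, cv = 0.1, n_reps = 3, seed = 1)
fit_decay(course$time_h, course$abundance, seed = 2)
#> First-order decay fit: half-life 4.55 h (k = 0.152 /h)
#>   95% bootstrap CI [4.05, 5.18] h
#>   R^2 = 0.951 over 15 points
```

Of the 86 genes planted as translation-only regulated, 79 are recovered
into the exclusive-translatome set (recall 0.92) with 90 genes called in
total (precision 0.88); genes planted in both compartments land in
`shared`, as the exclusivity screen intends. The decay fitter recovers the
planted 4.5 h half-life within its bootstrap interval.

`run_pipeline(out_dir = "run1", seed = 1)` chains every stage (synthesis →
differential → switch → motif → fractions → decay) into one output
directory with a JSON manifest of thresholds, seeds and output checksums;
rerunning with the same seed reproduces every file bit-identically.

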