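---
title: "Gated differential abundance analysis of label-free proteomics data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gated differential abundance analysis of label-free proteomics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfqdap)
```

## The problem

Label-free quantification (LFQ) mass spectrometry estimates relative
protein abundance from MS intensities without isotopic labels. A common
small-study design — the one this package targets — pools biological
material per condition (averaging individual variation into one sample)
and injects each pooled sample several times, so that replication is
technical: one control and a few treatment groups, three injections each.
The question per protein is whether its abundance differs between a
treatment and the control.

Three properties of LFQ data shape the analysis:

* intensities are roughly log-normal, so all modelling happens on the
  log2 scale, where technical variance is approximately constant and a
  fold change (FC) is a difference of means;
* each run carries its own location and spread bias (loading, ionisation,
  instrument drift) that must be normalized away before groups are
  compared;
* missing values are left-censored (missing not at random): a zero LFQ
  intensity is a non-detection, almost always because the protein sat
  below the detection limit in that run. The package therefore converts
  zeros to missing at parse time and no stage downstream ever sees a raw
  zero.

## The procedure

The pipeline (`run_pipeline()`) applies, in order:

1. **Peptide filter** — proteins identified by fewer than 2 distinct
   peptides are removed (`filter_by_peptides()`); single-peptide
   identifications are not considered reliable.
2. **Quantification filter** — proteins observed in fewer than 2 of all
   runs are removed (`filter_by_quantified()`). The count is across all
   runs jointly, not per group; a protein seen twice in one group and
   never elsewhere is retained and its absent cells are imputed.
3. **log2 transform** (`log2_transform()`).
4. **Median normalization** (`normalize_median()`) — every run's observed
   values are shifted so all run medians coincide. The common value is
   the *mean of the original medians* rather than zero: this keeps the
   matrix on the original intensity scale, which matters because step 6
   anchors imputed values at per-run observed minima — an anchor at an
   arbitrary scale would be meaningless.
5. **Width normalization** (`normalize_width()`) — every run's values are
   rescaled about the run median so all runs share the same distribution
   width. Width is the interquartile range by default (`q_low = 0.25`,
   `q_high = 0.75`); the quantile pair is configurable since "width" is a
   convention, and the IQR is the robust standard. Order matters and is
   enforced through the provenance record: widths are measured about
   medians, so medians must be aligned first. A consequence of using the
   mean of medians/widths as the reference is that shifting or rescaling
   a single run is absorbed only up to a small global constant (the
   reference itself moves by 1/12 of the perturbation in the 12-run
   design); the tests check exactly this behaviour.
6. **Left-censored imputation** (`impute_probabilistic_minimum()`) —
   missing cells are filled with draws from a normal centred at the run's
   observed minimum, truncated above at that minimum, with standard
   deviation `spread_factor` (default 0.25) times the run's observed SD.
   An imputed value therefore never exceeds the smallest observed value
   of its run, encoding the below-detection-limit interpretation. A
   global-downshift alternative (`method = "downshifted_normal"`, normal
   at mean − 1.8·SD with width 0.3·SD) is provided for sensitivity
   analysis. Normalization statistics are always computed from observed
   values only; imputation runs last.
7. **Gated two-sample tests** (`run_comparisons()`) — per protein and
   treatment, the three treatment values are compared with the three
   control values. First a two-tailed F-test of equal variances
   (`variance_gate()`): the larger sample variance over the smaller, with
   p = 2·min(tail, 1 − tail). If the gate rejects at `gate_alpha` (default
   0.05, matching the other thresholds in the procedure; two-tailed with
   the larger variance in the numerator), the unequal-variance Welch
   t-test is used, otherwise the pooled-variance Student t-test — the
   spreadsheet "type 3" and "type 2" conventions. Degenerate inputs are
   defined, not errors: equal variances give gate p = 1 (Student); one
   zero variance gives an infinite ratio, gate p = 0 (Welch); two
   constant equal groups give t p = 1, two constant unequal groups t
   p = 0.
8. **DAP calling** (`call_daps()`) — a protein is a differentially
   abundant protein (DAP) iff its t-test p-value is strictly below
   `p_threshold` (default 0.05) and |log2 FC| strictly exceeds
   log2(`fc_cutoff`) (default cutoff 2, i.e. |log2 FC| > 1). Both
   inequalities are strict, so boundary values are not significant.
   P-values are used raw by default; `p_adjust = "BH"` applies
   Benjamini–Hochberg within each treatment for users who want FDR
   control, but it is off by default because the procedure this package
   implements uses unadjusted p-values, and n = 3 vs 3 technical
   replicates give the test little power to spare.
9. **Reporting** — volcano plots (`volcano()`) with x = log2(FC) and
   y = −log2(p). The base-2 significance axis is deliberate: p < 0.05
   corresponds to the line y = 4.3219, and the FC cutoff to vertical
   lines at ±1, so both thresholds sit at round, directly interpretable
   positions. Cross-treatment DAP set intersections (`shared_sets()`),
   per-category counts (`category_summary()`), and annotation-grouped
   heat maps (`heatmap_abundance()`) summarise the calls. Heat map cells
   show the per-group *mean* of normalized log2 values, centred per row —
   one box per protein per group, colour encoding relative abundance
   across groups; DAP cells are asterisked. Group means (not
   replicate-level cells) are shown because the display summarises a
   group-level claim; the choice makes cells invariant to replicate
   order, which the tests verify.

Imputed cells take part in the comparisons as ordinary values, but each
result row records `n_imputed`, the number of imputed cells among the six
values compared. Extreme fold changes are often imputation-driven — a
protein detected in control but censored in all treatment runs gets three
near-minimum imputed values and a very large |log2 FC| — and `n_imputed`
makes such calls auditable without changing them.

## The synthetic-data generator

`simulate_lfq()` generates data from the model the pipeline assumes, with
known ground truth, so the whole pipeline can be exercised and scored
with no external data. Defaults mirror the pooled-plasma study design the
package emulates:

| parameter | default | meaning |
|---|---|---|
| `n_proteins` | 160 | plasma-proteome scale of a filtered protein-group table |
| `groups`, `reps_per_group` | control + T1–T3, 3 | 4 pooled samples × 3 technical injections = 12 runs |
| `baseline_mean`, `baseline_sd` | 25, 2 | per-protein baseline log2 intensity (log-normal intensities) |
| `tech_sd` | 0.25 | technical replicate SD on the log2 scale |
| `dap_fraction` | 0.2 | fraction of proteins carrying a treatment effect |
| `effect_range` | 1.5–10 | per-treatment effect magnitude bounds |
| `down_probability` | 0.8 | effects are mostly down-regulation |
| `run_shift_sd`, `run_scale_range` | 0.5, 0.8–1.25 | per-run location/spread biases the normalization must remove |
| `censor_quantile`, `censor_softness` | 0.05, 0.5 | soft left-censoring threshold and steepness |
| `single_peptide_fraction` | 0.07 | proteins forced to one peptide, removed by the filter |

Affected status and effect direction are drawn per *protein* (magnitude
per protein × treatment). This choice — rather than independent draws per
protein × treatment cell — reproduces the large cross-treatment shared
DAP sets seen in real exposure series, where the same proteins respond
at every dose; independent draws would leave three-way intersections
nearly empty. Effect magnitudes extend to |log2 FC| = 10 specifically to
exercise the imputation-driven extreme fold changes described above.

Censoring is a soft logistic threshold, not a hard cut: a cell goes
missing with probability `plogis((tau − x) / censor_softness)` where
`tau` is the `censor_quantile` quantile of all values. This leaves some
low values observed, so both the ≥2-run filter and the imputation see
realistic inputs. Setting `censor_quantile = 0` switches censoring off
entirely (used when testing normalization in isolation). Replication is
technical only — replicates share one pooled true level — so the
generator does not model biological between-individual variance, batch
structure beyond one scalar shift/scale per run, correlated proteins, or
peptide-level effects. Tests passing on these data show the pipeline
implements its model correctly; they cannot show the model suffices for
any particular real dataset.

## Numerical choices and reproducibility

* Imputation draws use one user seed with a per-run substream (run
  `j` is seeded with `seed + j`), so results are independent of column
  iteration order; the caller's RNG state is saved and restored.
  Truncated-normal draws are generated by inverse-CDF mapping, which
  makes them an exact deterministic function of the substream.
* The generator is fully reproducible from its seed; `run_pipeline()`
  re-run with the same configuration produces byte-identical result
  tables, and the provenance YAML it writes records every parameter,
  seed, stage, and input checksum needed to re-run.
* Normalization equalities hold to 1e-9 and idempotence to 1e-12; these
  are floating-point comfort margins, not statistical tolerances.
* Quantiles use R's default (type 7) definition throughout.

## Problem sizes in the test suite

The property suite runs at desk scale: normalization contracts on random
50 × 12 matrices; oracle agreement of the gate and both t variants on
1,000 random small samples against independent closed-form
implementations; the empirical level of the gated procedure on 20,000
equal-variance null proteins (3 vs 3), expected in [0.03, 0.07]; and
power/recovery checks on the default 160-protein synthetic design with a
brute-force oracle simulation (2,000 replicates per effect cell) of the
same gated test. The whole suite completes in well under a minute.

## Known limitations

* With three technical replicates per group the variance gate has very
  little power, so the Welch branch is taken about as often as the gate's
  level regardless of the true variance ratio; this is a property of the
  gated procedure itself, reproduced faithfully.
* Technical replication means p-values describe measurement
  reproducibility, not biological variability; inference about the
  population of fish (or any organism) is outside what these data can
  support.
* Median/width normalization assumes most proteins are unchanged; under
  very widespread, direction-biased regulation the reference itself
  shifts and fold changes acquire a corresponding bias.
* The probabilistic-minimum imputation is a single-value-distribution
  model; it does not propagate imputation uncertainty into the t-tests.
  `n_imputed` is the audit trail for calls that depend on it.
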