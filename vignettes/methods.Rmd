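---
title: "Methods: identifying injury-responsive proteins from imaging MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying injury-responsive proteins from imaging MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imstx)
```

## The identification problem

Linear-mode MALDI-TOF imaging of a thin tissue section produces one mass
spectrum per pixel over (by default) m/z 2,000–20,000. Rendering a single
m/z as an ion-density map localises that species — in the cochlea, to
structures such as the lateral wall, auditory nerve or Reissner's membrane
— and comparing maps across an injury-severity series (control, moderate
and severe noise exposure, ouabain) identifies signals whose density tracks
injury. But intact mass alone does not identify a protein: a ±1 kDa window
around a 5–12 kDa signal typically contains on the order of 10²
database entries. `imstx` intersects three orthogonal filters:

* **mass**: catalogue entries whose molecular weight (or annotated mature
  chain mass) falls in the m/z-centred window;
* **transcript**: candidates whose mRNA responds to at least one of the two
  injury models (two-group Student's *t*, p < α, permutation FDR as the
  global error summary);
* **peptide**: proteins actually identified in the section by LC-MS/MS
  (≥ 2 distinct peptides), with spectral counts as a semi-quantitative
  abundance proxy.

The assumptions are explicit: ions are singly charged (so m/z ≈ mass in
Da); protein abundance changes are at least partly transcriptionally
driven (proteins regulated purely post-transcriptionally are invisible to
the transcript filter); and the ±1 kDa window absorbs common modifications
but excludes large ones (poly-ubiquitination, heavy glycosylation).

## Key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `delta` (MW window half-width) | 1000 | Da | mass error + moderate PTMs; the window is centred on the m/z itself, with no proton-mass subtraction — the ~1 Da discrepancy is negligible against `delta`, and the convention matches how such windows are reported |
| `alpha` | 0.05 | — | raw per-gene gate; no per-gene multiplicity correction by design, the global error is the permutation FDR |
| `n_perm` | 1000 | — | ceiling only; with 3 vs 3 groups the balanced relabeling space (19 non-identity assignments) is enumerated exhaustively |
| ion-image `tolerance` | 0.1% of centre | Da | extraction width; scales with the TOF peak width |
| alias `rel_tolerance` | 5e-4 | — | unifies cross-run labels of one signal (5456/5458, 6199/6197, 11353/11356) without merging distinct signals (5456 vs 5667 differ by 4%) |
| `snr_threshold` | 5 | — | peaks must exceed 5 × robust noise (1.4826 × MAD of the baseline-subtracted spectrum) |
| `min_separation_da` | 10 (50 in the pipeline) | Da | greedy thinning, tallest peak kept first |
| `min_rel_intensity` | 0 (0.01 in the pipeline) | fraction of base peak | see numerical notes |
| `min_peptides` | 2 | — | conventional identification filter |

Masses are **average** masses (ExPASy residue table + 18.0153 Da water):
5–12 kDa species in linear MALDI-TOF are unresolved isotope envelopes, so
the average mass is the measured quantity. Monoisotopic masses are
available behind the `monoisotopic` flag. Chain features use 1-based
inclusive residue coordinates, the UniProt convention.

Full-length masses taken from spectral-count reports are printed in kDa at
0–1 decimals — coarser than the window half-width — so full-length
matching in the synthesis step is **disabled by default**
(`match_full_length = FALSE`) and identification flows through chain
masses, which are known to the dalton.

## Statistical machinery

`student_t_test` is the pooled-variance (equal-variance) two-sample *t*
with df = n₁ + n₂ − 2; Welch's form sits behind a flag. The row-wise
matrix implementation is cross-checked in the tests against
`stats::t.test` and against an exhaustive balanced-permutation oracle.

`permutation_fdr` estimates, for the observed p < α gene list, FDR =
mean over group-preserving label permutations of
(#significant under permuted labels) / (#significant observed), capped at
1. The identity assignment is excluded; when the permutation space is no
larger than `n_perm` it is enumerated (19 relabelings for 3 vs 3),
otherwise sampled uniformly under the run seed. The aggregator is the mean
(median behind a flag): with so few distinct relabelings the mean is the
lower-variance choice, and the capped ratio keeps the estimate in [0, 1].
If no gene passes the gate the estimate is flagged not-estimable rather
than returned as 0.

`refine_candidates` keeps a candidate if **any** mapped probe is
significant in **either** injury model — the most inclusive reading of a
many-to-many probe map; candidates with no mapping at all are excluded
from the refined pool but always listed in an `unmapped` sidecar.
Percentages use round-half-away-from-zero throughout (base `round()`
banker's rounding would turn 27.5% into 28% but 12.5% into 12%).

## Synthetic ground truth: what it does and does not emulate

The generators reproduce the *structure* of the study's inputs under known
truth:

* `make_phantom`: concentric annular bands approximate a mid-modiolar
  section (central auditory nerve, cochlear annulus with a lateral-wall
  outer band, a one-pixel Reissner spoke, background). Geometry is
  cosmetic; only region membership matters downstream.
* `simulate_ims`: per-pixel spectrum = baseline + region-localised
  Gaussian peaks × a per-condition severity multiplier + Gaussian noise,
  clipped at zero. The severity ordering is fixed as control < 106 dB <
  112 dB < ouabain with default multipliers (1, 2, 3, 4), so planted
  signals are injury-monotone by construction.
* `simulate_proteome`: uniform random sequences over the 20 standard
  residues; the stored MW is always recomputed from the sequence, so
  records are mass-self-consistent; a fraction carry one proper-subsequence
  chain feature.
* `simulate_expression`: null genes Gaussian (log2-scale mean 8, SD 1) in
  both groups; planted genes shifted by `effect_size`·SD in treatment.
  The source datasets publish no group sizes, so the default is
  n = 3 per group — the smallest design for which the *t*-test and the
  balanced permutation space are non-trivial and a common microarray
  reality. The bundle plants its two true probes at 5 SD so that recovery
  is power-limited only negligibly.
* `simulate_msms`: Poisson spectral counts with given means; zero means
  give exact zeros (condition-unique proteins).

Not emulated: isotope envelopes, matrix adducts, detector saturation,
mass-axis drift within a run, RMA normalization artefacts, correlated
gene expression, protein inference ambiguity. Passing tests therefore
demonstrate the pipeline's arithmetic and statistical behaviour, not
robustness to instrument physics.

In `simulate_bundle` the non-target proteins reported by MS/MS are chosen
with masses outside every target window. That is deliberate: the bundle is
a *parameter-recovery* benchmark (are the planted proteins, and only they,
called?), not a specificity stress test; decoys inside the windows would
make the expected call set seed-dependent.

## Numerical choices

* **Baseline/noise for peak picking**: rolling-minimum baseline over a
  200 Da window; robust noise = 1.4826 × MAD. On mean spectra averaged
  over ~10³ pixels, the residual noise is tiny and strictly non-negative
  after baseline subtraction, so rare spurious local maxima can clear any
  pure SNR gate; the pipeline therefore also applies a relative-intensity
  floor (1% of the base peak), mirroring how prominent signals are chosen
  in imaging software. A spectrum with zero noise estimate falls back to
  the MAD of the positive residuals; a flat spectrum returns no peaks.
* **Tie-breaks** are deterministic everywhere: candidate pools sort by
  |mass − centre| then accession; spectral-count ranking by condition
  count desc, total desc, accession asc; peak thinning keeps the tallest
  first.
* **Degenerate t-test inputs**: zero pooled variance with equal means
  gives (t = 0, p = 1); with unequal means a signed infinite sentinel with
  p = 0 and a warning.
* **Permutation-oracle calibration** is asserted as the *mean* absolute
  difference between the *t* p-value and the exhaustive permutation
  p-value over seeded random 6 vs 6 draws (924 balanced relabelings,
  resolution ≈ 0.001), at the 0.02 level. At 3 vs 3 or 4 vs 4 the
  permutation distribution has at most 35 distinct |t| atoms
  (resolution ≈ 0.03), so a 0.02 pointwise comparison is not meaningful
  at those sizes.
* **FDR calibration** checks use the estimator's Monte-Carlo spread:
  single-draw null estimates at 1000 genes fluctuate by ~0.1 (binomial
  variance of the observed significant count), so null behaviour is
  asserted on means over a few seeded replicates.
* **imzML**: continuous mode only; 64-bit m/z axis stored once, 32-bit
  intensities per pixel; positions written 1-based (x = column + 1,
  y = row + 1) and converted back to the package's 0-based row-major
  coordinates on read; the `.ibd` UUID and MD5 are recorded in the XML.

## Problem sizes

The shipped simulations use a 32 × 32 pixel phantom, a step-4 Da axis over
2,000–20,000 (4,501 points), 82-record catalogues, 1,000-gene expression
matrices at 3 vs 3, and ~22-protein spectral-count reports. These sizes
were chosen so that every planted feature is comfortably detectable while
a full end-to-end run completes in seconds; all of them scale up through
ordinary arguments.

## Limitations

* Identification is only as good as the catalogue's chain annotations;
  unannotated processing products cannot be matched.
* The transcript gate excludes post-transcriptionally regulated proteins
  by design.
* The permutation FDR is a global summary of the p < α list, not a
  per-gene q-value.
* Candidate counts from a molecular-weight query are database-version
  dependent; the bundled reference counts are packaged as fixtures, not
  reproduced from a live catalogue.
* No mass recalibration or cross-section alignment: cross-run signal
  identity is handled only through the relative alias tolerance.
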