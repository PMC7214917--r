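---
title: "BOLD delay mapping: model, parameters and design choices"
author: "bolddelay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BOLD delay mapping: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bolddelay)
```

## The method

Resting-state BOLD signal contains non-neuronal fluctuations — systemic
low-frequency oscillations (sLFOs), confined to roughly 0.01–0.15 Hz —
that travel through the vasculature with the blood. Because they arrive
at each voxel with a delay that tracks local perfusion, the per-voxel
arrival delay relative to a reference waveform acts as a
contrast-agent-free perfusion surrogate ("BOLD delay" or hemodynamic
lag). In ischemic stroke, tissue downstream of an occlusion shows delays
of several seconds.

`bolddelay` implements the full analysis chain:

1. **Preprocessing** (`discardInitial`, `regressConfounds`,
   `smoothSpatial`, `bandPass`): drop the pre-equilibrium frames, regress
   out the six rigid-body motion parameters, smooth with a 6-mm FWHM
   Gaussian, and band-pass to 0.01–0.15 Hz with a zero-phase
   (forward–backward) order-2 Butterworth filter. The order is fixed;
   re-ordering these stages is treated as a configuration error. Motion
   QC (framewise displacement on a 50-mm sphere, and DVARS computed after
   nuisance regression but before smoothing) is recorded per scan
   segment, not inherited from the full scan.
2. **Lag mapping** (`extractReference`, `estimateLag`, `calibrateNull`,
   `mapLags`): the reference is the mean BOLD time course over the major
   venous sinuses — a region outside the parenchyma that cannot itself
   be hypoperfused. Each voxel is assigned the integer-TR time shift in
   ±20 s that maximizes the Pearson correlation with the reference,
   computed on the truncated overlap with each overlap separately
   mean-centred (zero-padding would bias r toward 0 at large lags).
   Positive lag means the voxel lags the reference.
3. **Significance** (`calibrateNull`): surrogate references with the
   same amplitude spectrum but randomized Fourier phases are pushed
   through the identical lag search; the empirical (1 − α) quantile of
   the surrogate maxima is the validity threshold. Sub-threshold voxels
   keep their lag but are flagged invalid.
4. **Delineation** (`affectedTerritory`, `delineateLesion`): within the
   vascular territory containing the acute DWI lesion, voxels with delay
   strictly greater than a threshold (0 / 2.3 / 4.6 s for delay maps,
   6 s for Tmax-type maps) form candidate lesions; 26-connected clusters
   below 1 mL are removed. Thresholded masks nest by construction.
5. **Agreement** (`computeDice`, `blandAltman`, `cohenKappa`): Dice
   overlap, Bland–Altman bias with 1.96·SD limits of agreement and the
   bias as a percentage of the mean of pairwise means, and unweighted or
   quadratic-weighted Cohen's kappa for ordinal ratings.
6. **Scan-length experiment** (`experimentConfig`, `runCohort`): the
   full pipeline applied to nested prefixes of each scan (fractions
   0.2–1.0), with the full scan as reference for spatial and volumetric
   agreement.

## The synthetic cohort

Patient scans are not shippable, so the package carries a generator
(`syntheticConfig`, `generateSubject`, `generateCohort`) whose output
has a known answer. Each subject is an ellipsoidal "brain" on a
32 × 32 × 16 grid at 3 × 3 × 4 mm (desk-scale runtime while preserving
3-D morphology), with angular-sector vascular territories, a venous
sinus ball behind the brain carrying lag 0, and an ellipsoidal lesion
sized to a configurable fraction of the brain. A single band-limited
sLFO (Gaussian white noise brick-wall filtered to 0.01–0.15 Hz, then
variance-normalized — "low-frequency oscillation" without committing to
a parametric waveform) is delayed per voxel by Fourier phase ramps,
which are exact for band-limited signals and avoid interpolation bias at
TR = 0.4 s; the source series is generated with padding so cropped
delayed copies never wrap. Lags are smooth random fields rescaled to
−2…+2 s in normal tissue and +3…+10 s in the lesion (the literature
gives no quantitative patient lag distribution beyond the delineation
thresholds, so these ranges are configuration choices, exposed in
`syntheticConfig`). A configurable bound on the lag difference of
6-adjacent voxels (default 0.6 s) is enforced by iterative smoothing
with a final contraction fallback. White noise with SD = 1/snr is added;
motion traces are smooth excursions scaled by `motionAmplitude`, with
motion-coupled intensity artifacts added when non-zero.

What the generator does **not** emulate: anatomy, cardiac/respiratory
physiology, susceptibility or multiband reconstruction artifacts, and
dispersion (delays are pure time shifts; real sLFOs disperse as they
transit the vascular tree). Passing tests therefore demonstrate correct
recovery of time-shifted band-limited signals under noise and motion
confounds — not clinical performance.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `tr` | 0.4 | s | acquisition TR; sets the lag resolution |
| `nFrames` | 850 | frames | 340 s scan; 25 frames (10 s) discarded |
| `slfoBand` | 0.01–0.15 | Hz | the sLFO band; strictly inside (0, Nyquist) |
| `maxLag` | 20 | s | tracking half-range; stroke delays can be very long |
| `fwhm` | 6 | mm | spatial smoothing kernel |
| `alpha` | 0.05 | — | null threshold level |
| `nNull` | 10000 | — | surrogates for reported maps; 100–1000 suffice for exploration |
| `thresholdsBold` | 0, 2.3, 4.6 | s | delay thresholds (strict `>`) |
| `thresholdTmax` | 6 | s | hypoperfusion criterion for Tmax-type maps |
| `minClusterML` | 1 | mL | cluster-size filter in delineation |
| `minFraction` | 0.05 | — | DWI fraction for an "affected" territory |
| `snr` | 0.25 (cohort) | — | sLFO amplitude / noise SD |

## Numerical choices

- **Lag resolution.** Lags are integer multiples of TR; no sub-sample
  interpolation. At TR = 0.4 s the quantization error is at most 0.2 s,
  ample for thresholds expressed in whole seconds. Ties in peak
  correlation break toward the smallest |lag| (favouring the no-delay
  null), deterministically.
- **Zero-phase filtering.** The band-pass is applied forward and
  backward (order 2 per direction) so it cannot shift correlation
  peaks; the implementation applies the recursion to all voxels at once
  with odd-reflection padding of about one period of the low cutoff and
  steady-state initial conditions, and matches a reference
  forward–backward filter to ~1e-11.
- **Surrogate scheme.** "Shuffling" a strongly autocorrelated series by
  sample permutation destroys its autocorrelation and yields an
  anticonservative threshold; this package phase-randomizes instead,
  preserving the amplitude spectrum. A consequence worth knowing: the
  surrogate-versus-reference maximum correlation has a wider
  distribution than independent same-band noise would produce (the
  surrogate shares the reference's exact amplitudes), so the threshold
  is *conservative* for generic noise. The package's type-I check is
  therefore defined against probes drawn from the null model itself
  (phase-randomized copies of the reference), where the pass rate is α
  by construction; this is the well-posed calibration statement.
- **Segment accounting.** Scan fractions refer to the *original*
  pre-discard scan: a segment keeps
  `round(fraction × 850) − 25` frames as a prefix of the post-discard
  series and reports the nominal duration `round(fraction × 850) × TR`
  (68/136/204/272 s). Defining fractions on the post-discard 330 s scan
  would give 66 s for the 0.2 segment, contradicting the nominal
  durations; the pre-discard convention is the one that reproduces them.
- **Degenerate inputs.** Constant voxel series produce NA lag/r and are
  flagged invalid rather than raising; both-empty mask pairs give an
  undefined (NA) Dice excluded from summaries; exactly one empty mask
  gives Dice 0; degenerate kappa marginals give NA; constant confound
  columns are absorbed by the intercept silently, genuinely collinear
  ones are dropped with a warning.
- **Delineation internals.** 26-connectivity, 1 mL minimum cluster, no
  hole filling, strict `>` at every threshold, label-union handling of
  multi-territory strokes; delineation uses significance-masked maps by
  default with an `useValidOnly = FALSE` escape hatch, since published
  practice does not settle whether sub-significance voxels were
  excluded.

## Study conditions in the tests

The test-suite and acceptance computations run at the acquisition
constants (TR 0.4 s, 850 frames, 0.01–0.15 Hz) on the 32 × 32 × 16 grid.
Recovery checks use snr 10 over 10 seeds (median absolute lag error on
the full segment is bounded by one TR; without spatial smoothing the
noise-free error is pure quantization, ≤ TR/2). The scan-length cohort
uses 20 subjects at snr 0.25 with 0.5 mm motion — chosen so that
full-scan maps are reliable while shortened segments degrade visibly,
the regime the method is designed to operate in; at much higher snr all
segments saturate (Dice ≈ 1) and at much lower snr the shortest segment
collapses entirely. Null calibrations in tests use 100–500 surrogates
for runtime; the default for reported maps remains 10,000.

Median Dice against the full scan increases strictly with scan fraction
under these conditions, and lag-recovery error decreases with scan
length — the qualitative scan-shortening behaviour the pipeline is
built to measure. Within-subject lag error is dominated near the lesion
edge by the 6-mm smoothing kernel blending short and long lags; the
median is the robust summary for that reason.

## Known limitations

- Delays are modelled and estimated as pure time shifts; no dispersion
  or regressor-refinement iterations (deliberately out of scope).
- Only the venous-sinus reference mode is provided.
- The generator's geometry is schematic; territory borders are angular
  sectors, not arterial anatomy.
- No realignment estimation: motion parameters are an input, and no
  scrubbing/censoring is performed.
- Integer-TR lags limit resolution to 0.4 s at the default TR; a
  parabolic peak refinement was considered and deferred — thresholds in
  whole seconds do not need it.
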