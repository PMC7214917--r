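# bolddelay

Contrast-agent-free assessment of brain perfusion from resting-state
fMRI, for researchers working on hemodynamic lag mapping in
cerebrovascular disease — particularly acute ischemic stroke — and for
anyone studying how much scan time such maps actually need.

## The method

The BOLD signal carries systemic low-frequency oscillations (sLFOs,
0.01–0.15 Hz) that travel with the blood. The delay with which they
arrive at a voxel tracks local perfusion, so the per-voxel time shift
that maximizes the cross-correlation with a reference waveform — the
mean signal over the major venous sinuses — acts as a perfusion
surrogate:

```
lag(v) = argmax_{d ∈ [-20 s, +20 s]} corr( x_v(t), ref(t - d) )
```

with `d` searched over integer multiples of the TR on mean-centred
truncated overlaps. Voxel significance is calibrated against surrogate
references with identical amplitude spectra but randomized Fourier
phases (the empirical 1−α quantile of the surrogate peak correlations).
Perfusion lesions are delineated by thresholding the delay map
(> 0 / 2.3 / 4.6 s; > 6 s for Tmax-type maps) inside the vascular
territory containing the acute DWI lesion, removing 26-connected
clusters under 1 mL. Agreement between lesion sets is quantified by the
Dice coefficient, Bland–Altman bias with 95% limits of agreement, and
Cohen's kappa (unweighted or quadratic-weighted) for ordinal ratings.

A synthetic-cohort generator produces 4D BOLD datasets with known
ground-truth lag fields, masks and motion traces, so the whole chain —
preprocessing, lag mapping, delineation, agreement — is testable
without any data download, including the scan-length experiment: maps
from nested scan prefixes (fractions 0.2–1.0 of a 340 s, TR 0.4 s
acquisition, i.e. 68–340 s) compared against the full scan.

## Worked example

```r
library(bolddelay)

cfg <- syntheticConfig(seed = 7, snr = 2)        # 32x32x16, TR 0.4 s, 850 frames
sub <- generateSubject(cfg)
pp  <- preprocessBold(sub$bold, sub$motion)      # discard 25, regress, smooth, band-pass
ref <- extractReference(pp$series, sub$truth@sinusMask)
calib <- calibrateNull(ref, maxLag = 20, nNull = 1000, alpha = 0.05, seed = 8)
calib
#> NullCalibration: 1000 surrogates, alpha 0.050 -> r threshold 0.4451
lm <- mapLags(pp$series, ref, calib)
lm
#> LagMap: 32 x 32 x 16 grid, 3944 mapped voxels (3944 significant)
#>   tracking range: [-20, 20] s at TR 0.4 s
aff <- affectedTerritory(sub$truth@territoryAtlas, sub$truth@dwiMask)
del <- delineateLesion(lm, 2.3, aff, sub$truth@territoryAtlas)
del
#> DelineationResult (bold_delay): threshold > 2.3 s, 13.43 mL, 1 cluster(s)
#>   searched territory labels: 2
computeDice(lesionMask(del), sub$truth@lesionMask)
#> [1] 0.9702727
```

Reading the output: every brain voxel's peak correlation cleared the
phase-randomization threshold (r = 0.445), the automated search of the
affected territory found one supra-threshold cluster of 13.4 mL at the
2.3 s delay threshold, and that mask overlaps the generator's true
lesion with Dice 0.97.

The full scan-length experiment over a cohort:

```r
cfg <- experimentConfig(seed = 1)   # 20 subjects, snr 0.25, 0.5 mm motion
res <- runCohort(cfg, "results/experiment")
res$summary$dice                    # median/IQR Dice per fraction x threshold
res$summary$volumes                 # Bland-Altman of volumes vs the full scan
```

A thin CLI over the same functions lives at
`inst/scripts/bold-delay-cli.R` (subcommands `generate`, `run`,
`report`, `qc`).

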