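# hrvscd

Early detection of sudden cardiac death (SCD) risk from short-term heart
rate variability (HRV). The package is aimed at biosignal researchers who
want a tested, fully scripted pipeline from raw ECG (or RR-interval
series) to a cross-validated classifier separating normal subjects from
subjects at risk of SCD, using ensemble empirical mode decomposition
(EEMD) and entropy features.

## The method

An RR series is the sequence of intervals between successive ECG R peaks.
For each 2-minute RR segment the pipeline computes 27 features:

- **Time domain**: RMSSD, SDNN, pNN50.
- **Frequency domain**: VLF (0.003–0.04 Hz), LF (0.04–0.15 Hz),
  HF (0.15–0.4 Hz) band powers of the interpolated tachogram and LF/HF.
- **EEMD entropy**: the segment is decomposed by EEMD,
  x(t) = Σₖ IMFₖ(t) + r(t), where each intrinsic mode function (IMF)
  carries one oscillatory scale, fastest first. Five entropy estimators —
  Rényi spectral entropy (RenEn, order q = 2), fuzzy entropy (FuEn, a = 2,
  r = 0.15·SD, p = 2), dispersion entropy (DisEn, m = 2, c = 6),
  Rényi distribution entropy (RdisEn, a = 2, M = 512, q = 2) and improved
  multiscale permutation entropy (IMPE, m = 3, s = 2) — are computed on
  each of the first four IMFs, giving 20 values named `FuEn1` … `RenEn4`
  (estimator × IMF index).

Features are ranked by one of five two-class criteria (t-test, symmetric
KL "entropy" criterion, ROC, Wilcoxon, Bhattacharyya) and fed one by one
into 1-NN and 10-NN classifiers under stratified 10-fold cross-validation;
the accuracy/sensitivity/specificity curves and the best setting are
reported (SCD is the positive class).

Preprocessing for raw ECG: resampling to 360 Hz, undecimated db6 wavelet
denoising (baseline wander and power-line interference), Pan-Tompkins QRS
detection, median-filter deletion of ectopic intervals (> 20% deviation
from the 10-neighbour median), and segmentation of the 14 minutes before
the event into seven 2-min segments.

A seeded synthetic module generates two-class RR segments (broadband
irregularity contrast) and ECG with known beat times, so everything runs
and is tested without external databases.

## Worked example

Simulate the shipped two-class study conditions (18 normal vs 20 SCD-like
segments here for speed), extract the 27 features, rank and classify:

```r
library(hrvscd)

segs <- generate_rr_classes(rr_generator_spec(n_normal = 18, n_scd = 20),
                            seed = 42)
segs[[1]]
#> <rr_series> 151 intervals, 120.4 s, mean RR 798 ms  subject=norm01  group=normal  corrected=FALSE

tab <- build_feature_table(segs, eemd_cfg = eemd_config(ensemble_size = 50,
                                                        seed = 42))
tab
#> <feature_table> 38 rows x 27 features  labels: normal=18, scd=20

round(unlist(tab[1, c("RMSSD", "SDNN", "pNN50", "LF", "HF",
                      "FuEn1", "DisEn1", "IMPE1", "RdisEn1", "RenEn1")]), 4)
#>     RMSSD      SDNN     pNN50        LF        HF     FuEn1    DisEn1     IMPE1
#>   31.8646   42.5508   12.6667 1388.5750  500.6206    0.2183    3.1596    1.7027
#>   RdisEn1    RenEn1
#>    0.9439    0.7304

rk <- rank_features(tab, "entropy")
rk
#> <ranking_result> method=entropy  top 5: RenEn2, RMSSD, VLF, FuEn3, RenEn1

sw <- incremental_sweep(tab, rk, seed = 42)
sw$best
#> <cv_report> k=1  n_features=1  acc=100.0%  sens=100.0%  spec=100.0%
```

Reading the output: the first segment is a normal 2-min series of 151
beats; its time-domain variability (RMSSD ≈ 32 ms, SDNN ≈ 43 ms) and band
powers (LF ≈ 1389 ms², HF ≈ 501 ms²) are resting-HRV magnitudes, and the
IMF1 entropies quantify the irregularity of the fastest oscillatory mode.
Under the entropy ranking, EEMD-entropy features occupy most of the top
slots, and a single feature already separates the two synthetic classes
perfectly under 10-fold cross-validation — the planted contrast (3×
broadband irregularity) is deliberately strong.

The same steps are available from a shell via the thin CLI
(`inst/cli/hrvscd`): `simulate`, `preprocess`, `decompose`, `features`,
`rank`, `classify`; every subcommand takes `--seed` and is
bit-reproducible.

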