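# gliogrowth

Computer-assisted detection of growth in low-grade (WHO grade 2) gliomas from
longitudinal tumor volumetry.

Low-grade gliomas are surveilled for years with serial FLAIR MRI, and the
clinical gold standard — visually comparing 2D images across visits — tolerates
large volume increases before growth is called: each scan is compared against
only the few studies preceding it, small changes accumulate unnoticed, and
growth away from the measured slice is invisible. `gliogrowth` implements the
volumetric alternative for neuro-oncology researchers and imaging scientists:
segmentation-derived tumor volumes are tracked longitudinally and an **online
change-point detector** flags the visit at which the statistical level of the
volume series changed, typically years before visual comparison and at a
fraction of the volume change.

## The method

For a series of volumes \(v_1, \dots, v_n\) (pixels³) at months
\(t_1, \dots, t_n\):

1. **Baseline**: the first volume minimum after surgical resection — the
   earliest running-minimum scan followed by a strict increase — excluding
   still-resolving post-surgical FLAIR change. Its volume is \(v_0\).
2. **Change-point detection**: segments between change points are modeled at a
   constant root-mean-square level with cost
   \(C(x) = n \ln(\tfrac1n \sum x_i^2)\); a change-point set \(K\) minimizes
   \(\sum_{\text{seg}} C + |K| \cdot 500/v_0\) subject to ≥ 2 samples per
   segment, solved exactly by dynamic programming. The online wrapper sweeps
   visits using only past measurements — simulating the clinic — and reports
   the alert visit, the time to growth (TTG: baseline to the first change
   point), and ΔV (fractional volume change at the change point).
3. **Growth kinetics**: post-baseline curves normalized as
   \(y = (v - v_0)/v_\text{last}\), \(x = (t - t_0)/(t_\text{last} - t_0)\)
   are fit with `poly1` (\(y = p_1 x + p_2\)) and `exp1`
   (\(y = a e^{bx}\)); a curve is exponential when
   \(\mathrm{sse}_{\exp} < 0.6\,\mathrm{sse}_{\text{lin}}\).
4. **Cohort statistics**: per-pathology ΔG (CAD earlier than visual
   comparison), median (IQR) TTG and ΔV per arm, and two-tailed
   Mann–Whitney–Wilcoxon tests.

A synthetic-data generator produces volume trajectories (per-scan fractional
noise: mean 0.99%, SD 26.54% — the calibration measured on true-negative
stable curves — with post-operative decay limbs and linear/exponential growth
onset) and ellipsoid mask phantoms, so the entire pipeline is exercised
without patient data. See the methods vignette
(`vignettes/glioma-growth-detection.Rmd`) for assumptions, parameter
rationale, and limitations.

## Worked example

```r
library(gliogrowth)

# one post-operative case growing exponentially from month 12 after baseline
cfg <- synthetic_config("postop_decay_then_growth", noise_sd = 0.1,
                        onset_month = 12, n_visits = 14, seed = 42)
s <- simulate_trajectory(cfg, "case_4385")
find_baseline(s)
#> <baseline_result> scan 5: v0 = 9013 px^3 at month 19.9

detect_growth_online(s)
#> <detection_result> case case_4385: growth detected at visit 8
#>   (change point at sample 7), TTG 8.6 months, dV +27%

f <- growth_fit(normalize_curve(s))
f$classification   # "exponential"  (sse_exp 0.011 < 0.6 * sse_lin 0.049)
f$r2               # 0.984
```

The detector alerts at the 8th scan, 8.6 months after the post-surgical
baseline and at +27% volume — long before the series approaches the ~170%
change at which visual comparison historically called growth. On a full
simulated cohort (34 progressing, 22 stable, 7 imaging-abnormality cases):

```r
cases <- simulate_cohort(seed = 1)
summ <- cohort_summary(cases, detect_cohort(cases))
summ$progression[summ$progression$pathology == "all",
                 c("n", "delta_g", "ttg_cad_median", "ttg_vc_median")]
#>    n delta_g ttg_cad_median ttg_vc_median
#>   34      32            8.3          41.3
```

Computer-assisted detection preceded the synthetic visual-comparison call in
32 of 34 progressing cases, with a median lead of about 33 months. (The
stable-group alarm rate under the calibrated 26.54% per-scan noise is high by
design — the signal is attention-directing and physician-reviewed; see the
vignette's sensitivity section.)

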