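# musclemre

Quantitative analysis of skeletal-muscle magnetic resonance elastography
(MRE) and Dixon fat-fraction imaging, with the reliability statistics needed
to judge whether such measurements can serve as clinical outcome measures in
muscle disease (e.g. muscular dystrophies, where fibrosis and fatty
replacement progress over years).

MRE induces low-frequency shear waves in tissue (here a 60 Hz driver on the
thigh) and images the propagating displacement field at 8 phase offsets of
the vibration cycle. Stiffer tissue carries longer wavelengths, so shear
stiffness can be estimated as

&nbsp;&nbsp;&nbsp;&nbsp; *mu* = *rho* (*f* *lambda*)^2

with *rho* = 1000 kg/m^3 (muscle density by convention), *f* the driver
frequency and *lambda* the measured shear wavelength. The package implements
two estimators of per-muscle stiffness:

* **Method A** — ROI statistics on a vendor-style voxelwise stiffness map:
  invalid voxels (unmeasurable wave propagation) are discarded, then the 5%
  lowest and highest values per muscle, and the remainder averaged
  (`estimate_stiffness_a()`).
* **Method B** — automated wavelength measurement on the wave images: the
  muscle's proximo-distal axis (first principal component of its
  segmentation), the sagittal slice with maximum overlap, a 1D profile along
  the in-plane-projected axis, the dominant Fourier wavelength per phase
  (wavelengths over 50 mm rejected as artefacts), the 8-phase average, and
  the formula above (`estimate_stiffness_b()`).

Around these sit Dixon PDFF quantification (`compute_pdff()`,
`muscle_pdff()`, `muscle_volume()`, `normal_pdff_cutoff()`), a seeded
synthetic thigh phantom with known ground truth (`phantom_spec()`,
`generate_phantom()`, `simulate_reliability_cohort()`), and the statistics
layer: ICC(A,1) for absolute agreement (`icc_a1()`), normality-gated
Pearson/Spearman correlations (`gated_correlation()`), Holm correction
(`holm_adjust()`), gated paired/two-sample comparisons (`compare_groups()`),
the standardized response mean (`srm()`), and report builders
(`reliability_report()`, `longitudinal_report()`).

## Worked example

```r
library(musclemre)

spec <- phantom_spec()              # synthetic thigh, realistic noise levels
ph   <- generate_phantom(spec, seed = 42)

pdff <- muscle_pdff(compute_pdff(ph$fat, ph$water, signal_floor = 1),
                    ph$labelmap)
vols <- muscle_volume(ph$labelmap)
a <- estimate_stiffness_a(ph$stiffness_map, ph$labelmap, trim = 0.05)
b <- estimate_stiffness_b(ph$waves, ph$labelmap)
```

which prints, next to the phantom's ground truth:

```
              muscle pdff_pct volume_cc stiff_a_kpa stiff_b_kpa true_kpa
      rectus_femoris      5.3     142.4         2.9        2.91      2.9
    vastus_lateralis      6.1     142.4         3.5        3.50      3.5
     semimembranosus      6.9     142.4         2.7        2.71      2.7
 biceps_femoris_long      5.3     142.4         3.0        3.01      3.0
```

Both estimators recover the implanted stiffness: Method A despite 2% extreme
outliers and 10% invalid voxels in the vendor map, Method B despite wave
noise and a 10% oblique wave component. A simulated 12-subject test-retest
cohort then shows the expected excellent repeatability of Dixon metrics:

```r
tab <- simulate_reliability_cohort(12, spec = spec, seed = 42)
rel <- reliability_report(tab)
```

```
              muscle  n   icc  icc_band correlation_type correlation
 biceps_femoris_long 12 0.999 excellent          pearson       1.000
      rectus_femoris 12 1.000 excellent          pearson       1.000
     semimembranosus 12 0.999 excellent          pearson       0.999
    vastus_lateralis 12 1.000 excellent          pearson       1.000
```

A command-line interface covering the same pipeline is installed as the
`mre` script (`exec/mre`): subcommands `simulate`, `pdff`, `stiffness-a`,
`stiffness-b`, `reliability`, `longitudinal`.

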