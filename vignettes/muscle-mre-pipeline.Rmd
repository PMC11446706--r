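---
title: "Muscle MRE and Dixon quantification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle MRE and Dixon quantification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musclemre)
```

# The measurement problem

Muscular dystrophies progressively replace contractile muscle with fat and
fibrous tissue. Dixon MRI quantifies the fat component (proton-density fat
fraction, PDFF), but is blind to fibrosis; magnetic resonance elastography
(MRE) probes tissue mechanics directly by imaging externally induced shear
waves, and is therefore a candidate fibrosis-sensitive outcome measure.
Whether a simple 2D muscle MRE measurement is *reliable enough* to serve as
one is an empirical question that hinges on test-retest agreement and
longitudinal sensitivity — exactly the quantities this package computes.

The package covers the full desk-side analysis chain: per-muscle stiffness
from MRE by two methods, per-muscle PDFF and volume from Dixon images, and
the reliability/longitudinal statistics, all exercised end to end on a
seeded synthetic phantom with known ground truth.

# The wave model and stiffness estimators

For a locally homogeneous, isotropic, linearly elastic, incompressible
medium, a shear wave of frequency $f$ and wavelength $\lambda$ implies a
shear stiffness

$$\mu = \rho\,(f\lambda)^2,$$

with $\rho = 1000\ \mathrm{kg/m^3}$ assumed for muscle by convention. At the
60 Hz driver frequency used throughout, $\lambda = 30\ \mathrm{mm}$ gives
$\mu = 3.24$ kPa and $\lambda = 50$ mm gives 9.0 kPa. Stiffness is computed
in Pa (SI) and reported in kPa. These assumptions are knowingly wrong for
skeletal muscle (anisotropic, viscoelastic, finite, pre-stressed); the
package implements the conventional estimator, it does not defend it.

**Method A** takes a vendor-style voxelwise stiffness map with a validity
mask (regions of unmeasurable wave propagation are excluded, as vendor
software does automatically). Per muscle ROI, invalid voxels are dropped,
the values sorted, `floor(trim * n)` voxels removed from each tail
(`trim = 0.05` by default — residual outliers concentrate in the tails), and
the rest averaged. Trimming is per-ROI rather than per-map so that small
muscles are not biased by the map-wide distribution; tail counts use
`floor()` with stable sorting, so results are deterministic across
platforms. A muscle with no valid voxels yields a missing value, not an
error. The vendor inversion algorithm itself is out of scope (it is
undisclosed), which is precisely why the map is taken as input.

**Method B** measures the wavelength itself:

1. *Axis.* The muscle's proximo-distal axis is the first principal component
   of the world coordinates of its segmentation voxels. Waves propagate
   along the fibre direction; measuring along any other direction stretches
   the apparent wavelength by $1/\cos\theta$ and inflates stiffness (the
   package's test suite demonstrates this failure mode explicitly). The
   sign is fixed to a positive superior component; an elongation ratio
   below 1.5 flags a near-isotropic shape whose axis is unstable.
2. *Slice.* The measurement is 2D: the sagittal slice maximizing overlap
   between the muscle and the measurable region is selected (ties to the
   lowest index, deterministically). The measurable region is an arbitrary
   boolean mask, defaulting to the full wave footprint.
3. *Profile.* The axis is projected into the slice plane (an unprojected 3D
   line would leave the slice), a line is drawn through the in-slice
   centroid, and the wave image is sampled bilinearly at a step equal to
   the smaller in-plane spacing. The profile is restricted to the longest
   contiguous in-muscle run and mean-detrended. Runs shorter than 4 samples
   are rejected with a QC flag.
4. *Spectrum.* The profile is zero-padded to at least 8 times its length
   (next power of two) and the power spectrum evaluated over nonzero
   frequencies; padding refines the wavelength grid so quantization stays
   well under the acceptance tolerances (about 1 mm near 40 mm on a
   110-sample profile). The wavelength at maximum power is taken, ties
   breaking to the longer wavelength. If the *dominant* wavelength exceeds
   50 mm the result is missing: long wavelengths at this geometry are
   treated as artefacts. We deliberately test the global spectral peak
   rather than restricting the candidate set first — restricting first
   would let the leakage shoulder of an over-50 mm artefact masquerade as a
   sub-50 mm measurement, returning a number precisely when the data are
   least trustworthy. No lower bound is imposed beyond the profile's
   Nyquist limit.
5. *Phase averaging.* Steps 3–4 run on each of the 8 phase-offset images
   (0°…315° of the vibration cycle); missing phases are dropped, and at
   least 4 valid phases are required before the arithmetic mean wavelength
   is reported. Averaging per-phase peaks (rather than pooling spectra and
   picking one peak) follows the literal measurement protocol; the choice
   matters little for clean sinusoids but keeps per-phase QC information.

All QC-flagged outcomes propagate as missing values, never as numbers.

# Dixon quantification

$\mathrm{PDFF} = \mathrm{fat}/(\mathrm{fat}+\mathrm{water})$, computed
voxelwise, clipped to $[0,1]$. Voxels whose total signal is at or below a
floor (default 1% of the signal scale) are missing rather than NaN; without
the floor, background noise ratios pollute ROI means. A voxelwise
pre-correction hook (identity by default) is exposed for T1-bias
correction schemes without hard-wiring any particular formula. Per-muscle
PDFF is the mean over non-missing voxels (median available upstream of this
package's scope); muscle volume is voxel count times voxel volume in cc.
Total-thigh PDFF is volume-weighted by default (each voxel counts equally),
with an unweighted option, since muscles differ in size by an order of
magnitude. The normality cutoff for a thigh is the healthy-control mean
plus 2.5 sample standard deviations of total-thigh PDFF.

# The synthetic phantom

No patient images ship with the package; a seeded generator
(`phantom_spec()`, `generate_phantom()`) stands in for them. It emulates:

* **Geometry.** 16 sagittal slices of 10 mm thickness, 1.5 mm in-plane
  (slice axis first), mirroring a realistic sagittal MRE acquisition grid;
  four cylindrical "muscles" of 16 mm radius and 170 mm length with typical
  healthy-control truths (PDFF 5–7%, stiffness 2.7–3.5 kPa).
* **Dixon.** Inside muscle $m$: fat $= S\,p_m$, water $= S(1-p_m)$ at
  signal scale $S = 100$, plus independent Gaussian noise on both images
  (default sd $S/20$, i.e. SNR 20 — a deliberately conservative choice,
  since the wave-image noise level of real acquisitions is not
  characterized), clipped at zero; background is pure noise.
* **Waves.** A scalar plane wave per muscle along its axis with the
  wavelength implied by its true stiffness, sampled at the 8 phase
  offsets; optionally an oblique contaminant (45° rotated in-plane,
  $\lambda' = 0.7\lambda$, relative amplitude 0.1 by default) reproducing
  the oblique-wave failure mode with a controllable knob, plus Gaussian
  noise (default sd $0.1A$). Displacement is a single encoded scalar
  component, as in a single-direction phase-contrast acquisition; no 3D
  vector field, refraction, attenuation or Rician magnitude bias is
  modelled.
* **Vendor map.** Truth plus Gaussian noise (sd 0.2 kPa), a fraction of
  in-muscle voxels replaced by extreme outliers (×10 or ×0.1; 2% by
  default, the budget accurate to one voxel), a fraction marked invalid
  (10%), background invalid.
* **Sessions and cohorts.** `make_session_pair()` regenerates the dataset
  with fresh noise and optionally perturbed truths;
  `simulate_reliability_cohort()` draws subject-level truths (PDFF sd
  0.025 absolute, matching the few-percent spread of healthy-control
  thigh PDFF; overall size factor sd 0.08) and re-perturbs them between
  sessions by a chosen multiple of the between-subject sd. A small (1%)
  between-session size wobble emulates repositioning/segmentation
  variability — without it, measured volumes would be bitwise repeatable
  and volume ICC trivially 1.

Everything is deterministic in (spec, seed); sub-seeds for the individual
generators are derived arithmetically so stages can be regenerated
independently. Because the phantom implants ideal sinusoids in simple
convex shapes, passing recovery tests shows the estimators are correct *on
the model they assume*; it says nothing about refraction, interference and
geometric complexity in real thighs — which is exactly the gap the original
measurement problem lives in.

# Statistics layer

* **ICC(A,1)** (single rater, two-way model, absolute agreement) from the
  ANOVA mean squares,
  $\mathrm{ICC} = (MS_R - MS_E)/(MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E))$.
  The p-value uses $F = MS_R/MS_E$ with $(n-1,(n-1)(k-1))$ degrees of
  freedom — the conventional test for this family, adopted here because
  reliability reports customarily attach one. A zero-variance matrix is
  defined as ICC 1 with a degeneracy flag. Bands: $>0.90$ excellent,
  $>0.75$ good, $0.50$–$0.75$ moderate, $<0.50$ poor.
* **Normality gating.** Shapiro–Wilk at $\alpha = 0.05$ on *both* variables
  (correlations) or both samples / the paired differences (comparisons);
  all must pass for the parametric choice. The symmetric both-must-pass
  rule is the conservative resolution of an underspecified convention, and
  the chosen branch is always reported. Two-sample t-tests are Welch
  (equal variances not assumed); Wilcoxon tests are exact up to n = 25
  without ties, approximate otherwise.
* **Holm correction** (via `stats::p.adjust`) within one report family: the
  set of muscles per (metric, side) for reliability, per (metric, group,
  interval, side) for longitudinal change — per-side families, matching
  per-table familywise control where sides are reported separately.
* **SRM** = mean change / sd of change; missing when the change sd is zero.
* Incomplete subjects are dropped listwise per cell, with counts logged.

# Problem sizes and numerical choices

The validation suite runs noiseless and noisy (noise sd $0.2A$, 20% oblique
amplitude) recovery at implanted wavelengths of 20/30/40 mm on a
three-muscle phantom, recovering stiffness within 1% (well inside the 5% /
15% documented tolerances); PDFF recovery over 20 noise seeds at SNR 20
(within 0.01 absolute); ICC against a definitional brute-force ANOVA on 100
random 20×2 matrices (agreement ~1e-15); Holm against the step-down
definition on 1000 random vectors; and a test-retest simulation with 20
subjects (retest ICC > 0.99 for PDFF, > 0.96 for volume at zero session
noise) plus a 200-subject sweep over session-noise multiples
{0, 0.25, 0.5, 1} of the between-subject sd, on a reduced two-muscle grid,
where mean PDFF ICC falls monotonically from ~1.0 to ~0.65. These sizes
were chosen so the whole suite completes in about a minute while keeping
Monte-Carlo error far from every asserted margin.

Other numerical details: voxel spacing is always derived from affine column
norms (the affine is the single source of geometric truth, 0-based voxel
indices, RAS mm world coordinates); label resampling is nearest-neighbour
through the composed affines (no interpolation, so no invented labels), with
rigid/affine co-registration assumed — phantoms share frames by
construction; wave phases live in one 4D NIfTI with the 0°→315° order as a
file contract; measurement tables enforce key uniqueness at construction.

# Limitations

The phantom's idealized waves make Method B look better than it is on real
data, where test-retest reliability of this 2D approach is known to be
poor. The estimator chain is faithful to the simple 2D protocol by design:
no 3D wavefield inversion, no viscoelastic or anisotropic modelling, no
deformable registration, no water–fat separation or B0/stitching handling,
and no claim that the 50 mm cutoff or the 45°/0.7λ contamination model
generalizes beyond the acquisition geometry they encode.
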