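Package: musclemre
Title: Muscle Magnetic Resonance Elastography and Dixon Fat-Fraction Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of skeletal-muscle shear stiffness from magnetic
    resonance elastography (MRE) and of fatty muscle replacement from Dixon
    imaging, together with the reliability statistics used to evaluate such
    measurements as clinical outcome measures. Two stiffness estimators are
    provided: per-muscle trimmed-mean statistics on vendor-style stiffness
    maps, and an automated wavelength-based estimator that extracts a 1D wave
    profile along each muscle's proximo-distal axis and converts the dominant
    Fourier wavelength to shear stiffness via mu = rho (f lambda)^2. A seeded
    synthetic thigh phantom generator with known ground truth supports
    end-to-end validation and test-retest simulation. The statistics layer
    implements ICC(A,1) (two-way mixed effects, absolute agreement),
    normality-gated Pearson/Spearman correlations, Holm correction, paired and
    two-sample comparisons, and the standardized response mean.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
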