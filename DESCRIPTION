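Package: lqtmorph
Title: T-Wave Morphology Parameterization and LQT3 Genotype Classification
    from Single-Lead ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discriminating the LQT3 long-QT-syndrome genotype from
    LQT1 and LQT2 using single-lead Holter ECG morphology. Implements resting
    segment selection driven by the LF/HF heart-rate-variability ratio, a
    20-feature geometric parameterization of the ST-T complex (durations,
    sign-clipped rectangle areas, and a rhythm-invariant unit-circle wave
    transformation), nonparametric selection of an uncorrelated feature triad
    (Wilcoxon rank-sum discrimination, Spearman redundancy screening), and a
    class-weighted Gaussian-kernel support vector machine with exact Shapley
    attribution. A genotype-conditioned synthetic ECG generator with
    ground-truth fiducials makes the full pipeline testable without access to
    restricted clinical Holter databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
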