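Package: tumorfd
Title: 3D Box-Counting Fractal Dimension of Tumor Masks and
    Microvascular Invasion Risk Modelling
Version: 0.1.0
Authors@R:
    person("Riley", "Carver", email = "rcarver@example.org",
           role = c("aut", "cre"))
Description: Estimates the three-dimensional fractal dimension of
    segmented tumor volumes on CT by box counting with log-log curve
    fitting, and carries the estimate through a complete biomarker
    evaluation: cohort simulation calibrated to published summary
    statistics, univariable/multivariable logistic modelling of
    microvascular invasion, ROC analysis with DeLong comparison,
    Youden cut-off selection, Hosmer-Lemeshow calibration, decision
    curve analysis, intraclass correlation for reader agreement, and
    Kaplan-Meier risk stratification with log-rank testing. Includes
    minimal NIfTI-1 and DICOM series readers, isotropic resampling,
    intensity quantization, deterministic fractal phantoms (Menger
    sponge, spheres, slabs), and a rough-tumor generator with tunable
    boundary complexity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
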