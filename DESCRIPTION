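Package: nirsarrest
Title: Transcutaneous NIRS Analysis of Hemodynamic Collapse During Cardiac Arrest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-channel physiological recordings of
    pentobarbital-induced cardiac arrest: conversion of multi-distance
    dual-wavelength continuous-wave NIRS attenuation into hemoglobin
    chromophores and an absolute tissue saturation index via spatially
    resolved spectroscopy and the modified Beer-Lambert law; arrest-onset
    detection as the first excursion two standard deviations beyond a
    pre-infusion baseline; short-time-Fourier-transform pulse-rate and
    pulse-amplitude estimation; and the cohort summary statistics (paired and
    unpaired t-tests, repeated-measures ANOVA with adjusted post-hoc
    comparisons, D'Agostino-Pearson normality screen). Includes a synthetic
    physiology generator that emulates a porcine euthanasia experiment --
    pulsatile arterial blood pressure, NIRS optics with a cardiac pulsatile
    component, lagged tissue-PO2 decay, transient tachycardia, residual
    post-arrest pulsation, and shared motion artifacts across independently
    clocked streams -- with ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    zoo,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    withr,
    ggplot2,
    readr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
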