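Package: cardioage
Title: Quantification Toolkit for Cardiac Aging Phenotyping in Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Re-usable quantification stack for murine cardiac-aging studies:
    single-lead ECG fiducial-point delineation and interval/HRV measurement
    (zero-phase filtering, coiflet wavelet R-peak detection with sub-sample
    parabolic refinement, adaptive P/T windowing, slope-threshold onsets and
    T90 repolarization), quantitative telomere FISH intensity per nucleus from
    multichannel 16-bit confocal z-stacks (maximum projection, background
    subtraction, Otsu nuclear masking, 8-connected labeling, PCM1-based
    cardiomyocyte classification), echocardiographic and metabolic derived
    metrics (Teichholz ejection fraction, fractional shortening, cubed LV
    mass, OGTT AUC, adipokine ratios), lifespan statistics (Kaplan-Meier,
    logrank, mean/maximum-lifespan summaries), microarray fold-change
    differential expression with Fisher-exact gene-set enrichment and
    average-linkage z-score heatmaps, and a normality-gated group-comparison
    toolkit with exact small-sample rank tests. Every input type has a
    synthetic generator with analytic ground truth so the whole pipeline is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    flexsurv,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    survival,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
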