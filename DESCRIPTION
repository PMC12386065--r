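Package: lasrtools
Title: Manual Left Atrial Reservoir Strain and Method-Agreement Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes biplane left atrial reservoir strain (LASr) from caliper
    length measurements in apical four- and two-chamber echocardiographic views,
    together with auxiliary chamber-quantification indices (biplane area-length
    left atrial volume index, left ventricular mass index, relative wall
    thickness). Implements the full method-comparison toolkit used to validate
    a manual strain measurement against an automated speckle-tracking
    reference: Pearson correlation with post hoc power, paired t-tests,
    Bland-Altman limits of agreement, intraclass correlation ICC(2,1),
    coefficient of variation, standard error of measurement, minimal
    detectable change, and repeatability coefficients with chi-square
    confidence intervals. A calibrated bivariate-normal cohort simulator
    generates paired manual/automatic strain values, duplicate measurements,
    and clinical covariates so that every stage of the validation pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
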