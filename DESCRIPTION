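Package: oppomark
Title: Opposite-Direction Epigenetic Marker Discovery for Exercise and Drinking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An epigenome-wide association (EWAS) pipeline on Illumina
    27K-style beta-value matrices that discovers CpG markers whose
    methylation shifts under an exercise intervention oppose the shifts
    associated with hazardous drinking.  Implements detection-p masking,
    missing-rate and replicate-error-SD filtering, batch adjustment,
    age-probe screening and reference-based cell-type deconvolution;
    paired longitudinal testing and a two-step case-control plus
    behavioral principal-component association, both with Bonferroni
    control; direction-of-effect intersection with post-hoc
    cell-proportion and subgroup confirmations; and a multivariate
    methylation-behavior association built on Infomax independent
    component analysis with stability-based model-order selection.
    A synthetic three-cohort generator with a ground-truth manifest
    supports calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
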