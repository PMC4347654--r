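Package: cmrquant
Title: Semi-Automated Infarct Size and Area-at-Risk Quantification for Cardiac MR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Semi-automated quantification of myocardial infarct size (IS) on
    late gadolinium enhancement (LGE) imaging and of the ischaemic area at
    risk (AAR) on T2-weighted STIR imaging, from short-axis cardiac MR stacks
    and manually drawn endocardial/epicardial contours. Implements k-standard-
    deviation remote-ROI thresholding, full-width-half-maximum (FWHM) infarct-
    core thresholding and per-slice Otsu automated thresholding, together with
    the two standard manual corrections (inclusion of enclosed hypointense
    cores such as microvascular obstruction, and removal of isolated
    enhancement without interslice continuity), %LV-mass normalisation and the
    myocardial salvage index. Ships a synthetic short-axis phantom generator
    with exact ground truth, agreement and reproducibility statistics
    (two-way absolute-agreement intraclass correlation, Bland-Altman limits of
    agreement, paired t, Wilcoxon signed-rank comparison of squared
    differences, Pearson correlation) and a cohort pipeline that assembles the
    corresponding accuracy and reproducibility report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    withr,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
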