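Package: cardti
Title: Cardiac Diffusion Tensor Biomarkers of Chronic Myocardial Infarction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for microstructural biomarkers of chronic
    myocardial infarction from in vivo cardiac diffusion tensor imaging
    (cDTI). Implements late-gadolinium-enhancement (LGE) threshold
    segmentation of remote, border, and infarct myocardium; registration of
    diastolic LGE-derived label maps onto systolic cDTI slices; log-linear
    diffusion tensor reconstruction with a mean-diffusivity rejection filter;
    biomarker maps (MD, FA, eigenvalues, radial diffusivity); extracellular
    volume fraction (ECV) mapping from pre- and post-contrast T1 and
    hematocrit; regional non-parametric statistics; a seeded infarcted
    left-ventricle phantom generator; and a Monte-Carlo random-walk diffusion
    simulator relating ECV to diffusion tensor quantities in synthetic
    myocyte geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    nortest,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
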