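Package: voxnorm
Title: Voxel-Wise Normative Modelling of Neonatal Brain Microstructure
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Normative modelling of developing brain microstructure from
    diffusion-tensor scalar maps. Fits, at every intracerebral voxel, a
    two-output Gaussian process regression of fractional anisotropy (FA)
    and mean diffusivity (MD) on postmenstrual age at scan and sex over a
    normative cohort, and scores individual subjects as
    uncertainty-normalised Z-score deviation maps. Extreme deviations
    (|Z| > 3.1) are summarised as directional whole-brain atypicality
    indices and group overlap maps, and related to covariates and
    neurodevelopmental outcomes through a battery of nonparametric and
    regression analyses (Mann-Whitney U with Vargha-Delaney A, Spearman
    correlation, Holm correction, bootstrap confidence intervals for
    adjusted R-squared). Includes a synthetic cohort generator producing
    NIfTI scalar maps with known ground truth so the full pipeline can be
    exercised and validated without access to restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lmtest,
    Rcpp,
    RNifti,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
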