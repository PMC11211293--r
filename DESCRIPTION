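Package: flrvolumetry
Title: Blood-Free Future Liver Remnant Volumetry on Labeled CT-Like Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for assessing the future liver remnant (FLR) before major
    hepatectomy in blood-filled and blood-free settings. Generates synthetic
    CT-like label phantoms of the liver with hepatic and portal vein trees,
    lesions and a resection partition; simulates automated segmentations at a
    controlled Dice level; computes Dice and volumetric similarity, vessel
    trunk/branch continuity classification, blood-filled and blood-free liver
    volumetry with FLR percentage and resection-candidacy decisions; and runs
    the cohort-level agreement statistics (Bland-Altman limits of agreement,
    exact McNemar, Mann-Whitney U, Kruskal-Wallis, Wald proportion intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
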