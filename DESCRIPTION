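Package: isletscore
Title: Automated Immunofluorescence Scoring of Pancreatic Islets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated quantification of beta-cell area score, islet size and
    beta-cell density from three-channel immunofluorescence images of pancreatic
    islets (DAPI nuclear stain, a 488-channel beta-cell marker and a 555-channel
    alpha-cell counterstain). Staining is separated from background by
    two-cluster k-means on the intensity histogram, nuclei are detected in the
    DAPI channel, and cells are classified as alpha or beta by majority voting
    over stained pixels in a patch around each nucleus. Includes a seeded
    synthetic islet-image generator with full ground truth, cohort-level
    statistics (per-patient medians, unpaired t-tests, Pearson correlation,
    ANCOVA slope comparison) and tidy/ggplot2 interfaces for all results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml,
    EBImage,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
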