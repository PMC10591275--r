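Package: ieegloc
Title: Intracranial Electrode Localization from Post-Implant CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless engine for localizing intracranial EEG (sEEG and ECoG)
    electrode contacts from a post-implant CT volume. Detects metal-contact
    densities, refines contact coordinates to intensity-weighted centers at
    native CT resolution, extrapolates and interpolates whole shafts and strips
    from two seed contacts, assigns anatomic labels from a parcellation volume
    by 3x3x3 majority vote, corrects ECoG brain shift by topology-preserving
    projection onto the pial envelope, maps per-electrode values onto surface
    vertices, and exports BIDS-iEEG electrode metadata. Ships deterministic
    synthetic-fixture generators (CT volumes, label volumes, icosphere meshes)
    with known ground truth, and a batch command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    tibble,
    dplyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    yaml,
    xml2,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
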