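Package: SpermatoTyper
Title: Identification of Fish Spermatogenic Cell Types from Multi-Channel
    Immunofluorescence Testis Sections
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated image-analysis pipeline for staging spermatogenesis
    in fish testis sections stained with DAPI and antibodies against Ddx4,
    Piwil1, Sycp3 and Pcna. The package segments nuclei from the DAPI channel,
    measures nuclear morphometry (perimeter-based diameter, nucleolus census)
    and marker intensities normalized to reference spermatogonia within the
    same image, quantifies subnuclear Sycp3/Pcna localization to stage primary
    spermatocytes, infers clonal cyst cell numbers from largest planar section
    counts via a packed-sphere ("clay ball") model, and classifies each nucleus
    into one of twelve spermatogenic cell types and subtypes with a
    deterministic rule cascade. A synthetic-scene generator with machine
    readable ground truth makes every stage testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: CellBiology, Classification, Software
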