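Package: lipogate
Title: Imaging Flow Cytometry Feature Extraction and Sequential Gating for
    Giant Liposome Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for phenotyping gene-expressing giant liposomes
    (synthetic cells) from imaging-flow-cytometry event images. Provides a
    synthetic event-image generator emulating ImageStream-like multichannel
    tiles of giant vesicles (membrane rings, lumen reporters, DNA condensate
    blobs, filament bundles, membrane-relocalized signal, multilamellar
    vesicles, doublets, rods, aggregates, debris, defocus blur), the scalar
    image features used to gate them (geometry, intensity, focus, gray-level
    co-occurrence texture statistics, bright detail similarity), declarative
    gates and sequential gating pipelines with per-stage accounting, preset
    classification cascades (liposome identification, morphometry, gene
    expression, DNA replication, filament formation, membrane relocalization,
    lipid-synthesis positivity), and population statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
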