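Package: myohisto
Title: Muscle Histomorphometry and qPCR Quantification Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantification pipeline for dystrophic muscle histopathology:
    muscle-fibre segmentation from laminin immunofluorescence, centronucleated
    fibre (CNF) classification via Euclidean distance transforms, minimum Feret
    diameter morphometry with a circularity exclusion filter, Sirius Red/Fast
    Green collagen scoring by Beer-Lambert colour deconvolution, H&E-based
    myonecrosis scoring, fluorescence marker quantification (IgM, eMyHC,
    PDGFRA, F4/80, p-SMAD2) with damage/repair/healthy region classification,
    and RT-qPCR relative quantification with standard curves and geNorm
    reference-gene normalization. Ships a ground-truthed synthetic muscle
    cross-section and qPCR plate generator so the whole pipeline is testable
    without external slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    xml2,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
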