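Package: zebrafat
Title: Fat-Water MRI Body-Fat Quantification and Morphometry for Adult Zebrafish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies whole-body fat in adult zebrafish from paired
    chemical-shift-selective (CHESS) fat and water magnitude image stacks:
    background noise estimation from signal-free air, Rician bias
    correction, receiver-gain normalization, per-voxel fat signal fraction,
    and voxel-wise fat volume and mass. Includes a digital fish-in-agarose
    phantom simulator with known ground truth and a simulated reference
    fat-mass readout for end-to-end validation, method-comparison
    statistics, and the morphometric computations of diet-induced obesity
    studies (body mass index, Fulton's condition index, body fat
    percentage, adipocyte polygon morphometry, ration energy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
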