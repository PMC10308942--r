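Package: bloomrates
Title: Growth Accounting for Marine Bacterioplankton from Image Cytometry and Dilution Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify in situ growth of marine bacterioplankton
    populations during phytoplankton blooms. Measures the frequency of
    dividing cells (FDC), cell biovolume (capped-cylinder model) and total
    fluorescence from paired FISH/DAPI epifluorescence micrographs; estimates
    cell division and grazing rates from seawater dilution experiments
    (Landry-Hassett regression); calibrates FDC against experimentally
    determined division rates with a taxon-interaction linear model; and
    decomposes abundance time series into cell division, net growth and
    mortality rates via loess smoothing and sliding-window regression.
    Includes seeded generators for synthetic micrographs, dilution series and
    bloom trajectories with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    utils,
    tools,
    EBImage,
    tiff,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
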