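Package: lignoscope
Title: Quantification of Stem Cell Wall Lignification from Double-Stained
    Micrographs and Its Biogeographic Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the degree of cell wall lignification (DCWL) of plant
    stem cross-sections from Safranin/Astra-Blue double-stained micrographs by
    hue-saturation-brightness pixel classification, and analyses DCWL across
    lifeforms and climatic gradients. Includes a synthetic micrograph generator
    with per-pixel ground truth, a synthetic species-site study generator
    emulating a global collection network, descriptive statistics (class-binned
    means, locally weighted polynomial regression, group comparisons,
    percentile trimming), and redundancy analysis with variance partitioning
    and Monte-Carlo permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    utils,
    tools,
    png,
    jsonlite,
    yaml
Suggests:
    tiff,
    vegan,
    ggplot2,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
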