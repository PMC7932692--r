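Package: sistermem
Title: Non-Genetic Memory Analysis of Sister, Neighbor and Random Cell Pairs
    from Microfluidic Lineage Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying non-genetic (epigenetic) inheritance memory in
    single-cell growth data from mother-machine and sisters-machine microfluidic
    devices. Provides a stochastic generator of sisters-machine lineage tables
    (adder size control, AR(1) heritable growth and size factors, Ornstein-Uhlenbeck
    intrinsic and trap-shared environmental noise, post-division growth-rate
    compensation), cell-cycle segmentation and pair construction (sister, neighbor
    and random pairs), pair Pearson correlation functions on generation and time
    grids, windowed elongation rates, pair-difference variance dynamics with
    saturation metrics, exponential memory-half-life fits, and bootstrap errors,
    plus a config-driven simulate/analyze pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
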