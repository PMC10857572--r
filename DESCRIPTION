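Package: nmrbridge
Title: Standardize Bruker 1D-NMR Metabolomics Studies and Export Analysis-Ready Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ingests heterogeneous raw Bruker 1D-NMR metabolomics study
    directories (as deposited in MetaboLights or Metabolomics Workbench, or
    held locally), detects their directory-layout dialect, rewrites them into
    a single canonical study layout, decodes processed 1r spectra into a
    sample-by-spectral-point matrix on a shared ppm grid, reduces it to a
    fixed number of equal-width bins, and writes ready-to-use inputs for
    MetaboAnalyst (CSV) and Workflows4Metabolomics (tabular trio).  Includes
    a deterministic synthetic-study generator used as the test bed, a
    pluggable repository download client, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
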