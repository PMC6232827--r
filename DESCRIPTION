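Package: phagespec
Title: Protease Cleavage Specificity Profiling from Substrate Phage Display
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for determining the extended cleavage specificity of
    neutrophil serine proteases (and other endopeptidases) from substrate
    phage display. Simulates biopanning selections of a phage-displayed
    random nonamer library, aligns selected peptides into the Schechter-Berger
    P5-P4' subsite frame by anchoring a preferred P1 residue, builds
    position frequency and log-odds matrices with pseudocounts, designs and
    interprets tandem-thioredoxin reporter substrates (including the
    SalI-site valine fallback cleavage), and scans protein sequences for
    ranked candidate cleavage sites. All results are returned as tibbles
    with broom-style tidy()/glance() methods and ggplot2 autoplot() support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
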