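Package: cas12atools
Title: Amplicon Indel Quantification and PAM Preference Profiling for
    Cas12a Nucleases
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing Cas12a (Cpf1) nuclease activity from
    amplicon deep sequencing and plasmid reporter assays. Implements
    semi-global read alignment with affine gaps, anchor-identity read
    filtering, indel calling within a window around the nuclease cut site,
    per-sample indel frequency with a minimum-read exclusion rule, GFP
    disruption and GFxFP reporter arithmetic with background subtraction,
    HDR normalization for transfection efficiency, aggregation of PAM-panel
    activities into per-position base-preference matrices with IUPAC
    consensus calling, target-site scanning, and seeded simulators for
    edited amplicon reads, reporter plates and PAM panels with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
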