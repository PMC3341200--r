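Package: pias3net
Title: Mass-Action Model of the MITF-PIAS3-STAT3 Signalling Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic mass-action model of the crosstalk between the
    transcription factors MITF and STAT3 through their shared inhibitor
    PIAS3 in melanocytes. Provides the 15-state ordinary differential
    equation system (four MITF phosphoforms and their PIAS3 complexes,
    the RSK1 phosphorylation cycle, the STAT3 arm, and a shared
    ubiquitination fraction for S73-phosphorylated MITF), transcriptional
    activity readouts, a catalog of 28 formalized virtual experiments with
    boolean success criteria, and a binned success-rate global sensitivity
    analysis with a permutation null.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
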