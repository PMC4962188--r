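Package: rrmtools
Title: Resonant Recognition Model Analysis of Protein and DNA Sequences
Version: 0.1.0
Authors@R: person("rrmtools", "maintainers", email = "maintainers@rrmtools.example", role = c("aut", "cre"))
Description: Implements the Resonant Recognition Model (RRM) for protein and
    DNA sequence analysis: electron-ion interaction potential (EIIP) numerical
    encoding of sequences, Fourier amplitude/phase spectra, multiplicative
    cross-spectral consensus with signal-to-noise peak calling, mapping of RRM
    frequencies to electromagnetic wavelengths and physical frequencies, a
    curated catalog of characteristic frequencies for biological functional
    groups with super-family classification, and coverage analysis of light
    source spectral power distributions against the catalog. Includes a
    synthetic-sequence simulator with known embedded periodicities so the whole
    pipeline is testable without external data, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
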