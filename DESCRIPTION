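Package: imstx
Title: Proteo-Transcriptomic Identification of Injury-Responsive Proteins
    from Imaging Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Workflow for identifying tissue proteins responsive to injury by
    combining MALDI-TOF imaging mass spectrometry with transcriptomic and
    LC-MS/MS evidence. Extracts ion-density maps and peaks from imaging-MS
    datacubes, enumerates proteome candidates within a molecular-weight
    window around each m/z signal, refines candidate pools by two-group
    differential mRNA expression with a permutation-based false discovery
    rate, and confirms identities by intersecting chain masses with
    spectral-count LC-MS/MS reports. Includes synthetic phantom generators
    with known ground truth for end-to-end validation, imzML (continuous
    mode) input/output, and bundled reference tables from a cochlear-injury
    study of noise- and ouabain-exposed mice.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    xml2,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
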