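Package: glycoMRM
Title: Spike-In SILAC MRM Quantification of ER Glycosyltransferase Panels
Version: 0.1.0
Authors@R:
    person("ZMBH", "Proteomics", email = "proteomics@example.org", role = c("aut", "cre"))
Description: Tools for scheduled multiple reaction monitoring (MRM) assays
    targeting low-abundance endoplasmic-reticulum glycosyltransferases.
    Covers in silico assay design (tryptic digestion, proteotypic peptide
    selection, b/y fragment m/z calculation, indexed retention time
    calibration and scheduling), transition-level quality control via
    reference dot-products and chromatographic flags, spike-in SILAC
    light/heavy protein quantification with reference-protein (SEC63)
    normalization, regression-based two-group differential abundance with
    Benjamini-Hochberg correction, and NanoString nCounter transcript
    normalization. A synthetic-data generator with known ground truth
    emulates patient-versus-control study designs so the whole pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
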