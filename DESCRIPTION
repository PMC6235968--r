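Package: prmquant
Title: Targeted Parallel-Reaction-Monitoring Quantification of Ethylene-Signaling Proteins
Version: 0.1.0
Authors@R: person("Postharvest", "Proteomics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A workflow for absolute protein quantification by parallel
    reaction monitoring (PRM) with stable-isotope-labeled spike-in peptides,
    built around the ethylene signal-transduction proteins (ETRs, CTRs, EIN2)
    of ripening tomato fruit. Covers in-silico tryptic digestion and
    proteotypic peptide selection, assay-panel construction with light/heavy
    precursor and fragment m/z arithmetic, a seeded simulator of co-eluting
    light/heavy transition chromatograms with known ground truth, extracted
    ion chromatogram integration, transition-group scoring with decoy-based
    q-values, single-point-calibration absolute quantification, mixed-model
    peptide-to-protein roll-up with Tukey letters, qPCR standard-curve
    efficiency and reference-gene normalization, and a Monte-Carlo
    protein-mRNA correlation procedure with Fisher-transform confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
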