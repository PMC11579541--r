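Package: dmpkr
Title: Preclinical Drug Metabolism and Pharmacokinetics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable analysis chain for preclinical DMPK studies of small
    molecules: bidirectional MDCK-MDR1 permeability and efflux-ratio analysis,
    MTT cytotoxicity (RGR/TC50), microsomal depletion kinetics with
    well-stirred in-vitro-to-in-vivo extrapolation of hepatic clearance,
    CYP phenotyping and cocktail-inhibition IC50 estimation with censoring,
    plasma-protein binding from ultrafiltration, non-compartmental
    pharmacokinetics (single dose, absolute bioavailability, steady state,
    dose proportionality), composite tissue-distribution exposure analysis,
    and excretion mass balance.  A synthetic-data generator with known ground
    truth backs every assay so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
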