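Package: serflux
Title: Serine Uptake, Flux Variability and Sphingolipid Labeling Analysis for Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse how serine uptake feeds sphingolipid biosynthesis
    in Saccharomyces cerevisiae. Provides a constraint-based modelling core
    (SBML-FBC and toy-JSON model input, gene-protein-reaction rules, gene
    deletions, medium constraints), flux balance and flux variability analysis
    at a fraction of the biomass optimum with serine-uptake scans, estimation
    of stable-isotope serine incorporation from SILAC peptide ratios with
    intensity-dependent outlier calling, quantification of radiolabel uptake
    kinetics, internal-standard amino-acid concentrations, long-chain-base
    amounts and isotope-labeled lipid mole fractions, mining of genetic
    interaction screens, and deterministic synthetic-data generators with
    known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
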