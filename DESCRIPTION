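Package: wfsdose
Title: Genotype-Phenotype Dose Analysis for Wolfram Syndrome Registries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for allele-dose genotype-phenotype analysis of
    autosomal-recessive WFS1-related (Wolfram syndrome) patient
    registries. Parses protein-level HGVS-style variant descriptors,
    classifies alleles as truncating (nonsense/frameshift) versus
    in-frame (missense and in-frame insertion/deletion), annotates
    in-frame variants against transmembrane-domain residue intervals,
    and quantifies allele-dose effects on age of onset of clinical
    manifestations (diabetes mellitus, optic atrophy, diabetes
    insipidus, hearing loss) with exact and approximate Wilcoxon
    rank-sum tests and Bonferroni adjustment. Includes a seeded
    synthetic-registry generator and a Monte-Carlo power/calibration
    harness so the full pipeline is exercisable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
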