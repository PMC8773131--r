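Package: CEPspec
Title: Cleavage-Site Specificity Profiling of Cell-Envelope Proteinases from
    Casein Peptidomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for profiling the cleavage-site specificity of
    cell-envelope proteinases (CEPs) and other endopeptidases from
    peptidomics data. Observed peptides are mapped onto parent protein
    sequences (bundled mature bovine beta-casein and alphaS1-casein
    references), cleavage sites are inferred from peptide termini and
    accumulated over a hydrolysis time course, and per-residue subsite
    statistics are computed: the cleavage probability %P at the P1 and
    P1' positions, its mean over the 20-amino-acid alphabet, and the
    preference coefficient Kn. The package also matches peptides against
    a local bioactive-peptide reference table at full-length identity,
    computes inter-enzyme site and peptide overlap statistics, and
    includes a stochastic in-silico digestion simulator with per-residue
    subsite weights for validating the whole pipeline by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    BiocGenerics,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Software
RoxygenNote: 7.3.3
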