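Package: mhcassoc
Title: MHC Amplicon Genotyping, Functional Divergence, Supertypes and
    Reproductive-Success Association Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for amplicon-based genotyping of major
    histocompatibility complex (MHC) loci (Degree-of-Change and
    Threshold allele calling with artifact screening), amino-acid
    p-distance and Grantham functional divergence, supertype clustering
    from physicochemical descriptors of positively selected sites, and
    multimodel-averaged generalized linear mixed models linking parental
    MHC to clutch size and fledging success, including the
    cross-fostering decomposition into genetic versus social parent
    effects. A synthetic-data module emulates allele pools, noisy
    amplicon read spectra and cross-fostered breeding records with known
    injected effects, so the whole pipeline runs and can be validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    MASS,
    cluster,
    emmeans,
    graphics,
    jsonlite,
    lme4,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
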