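Package: pollenpanel
Title: Private-Allele SNP Panels and Pollen-Load Genotype Deconvolution for
    Orchard Cross-Pollination Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring cross-pollination in multi-cultivar orchards
    from the pollen carried by individual flower visitors.  Designs and
    validates private-allele SNP panels that identify each cultivar by a
    homozygous genotype unique to it, models single-base-extension
    (SABER-style) allele-presence assays on mixed pollen DNA, deconvolves
    per-bee allele calls into the minimal set of contributing cultivars,
    classifies bees as carrying cross-pollen, self-pollen or both, and tests
    distance and orchard-design effects on cross-pollen carriage with a
    binomial mixed model with a random transect intercept.  A seeded
    orchard-foraging and assay simulator generates complete synthetic studies
    with known ground truth so that every stage of the pipeline can be
    exercised and checked end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    lme4,
    stats,
    tools,
    utils,
    yaml
Suggests:
    glmmTMB,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
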