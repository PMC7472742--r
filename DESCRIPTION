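Package: sdrmap
Title: Mapping a Sex-Determining Region from Family Genotypes and Larval Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating a sex-determining region (SDR) in species
    without sexual dimorphism, using full-sib families. Implements
    exclusion-principle parentage testing over multi-allelic markers,
    phenotype-free assignment of larvae into putative sex-groups by
    segregation of parental haplotypes (XY, ZW and randomized-control
    scenarios), recombinant-based refinement of the SDR interval from
    opposite-sex genotype runs, count-based sex-biased differential
    expression with an exact conditional test, and per-linkage-group
    enrichment of sex-biased genes via a relative-abundance statistic.
    A synthetic-data module simulates families, crossovers, parentage
    panels and sex-biased count matrices with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
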