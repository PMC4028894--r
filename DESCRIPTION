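Package: radlinkmap
Title: Sex-Specific RAD-Seq Linkage Maps for Outbred Full-Sib Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Construction and characterisation of dense SNP linkage maps from
    restriction-site associated DNA sequencing (RAD-Seq) genotypes in outbred
    two-parent full-sib families, modelled on the Atlantic salmon (Salmo salar)
    SalMap reference families. Implements the SNP and individual quality-control
    cascade (missingness, excess-heterozygosity paralog removal, Mendelian-error
    handling), two-point recombination-fraction and LOD estimation per parent,
    anchor-seeded assignment of markers to linkage groups with a stepwise LOD
    schedule, per-parent multipoint marker ordering with ripple verification and
    Haldane map distances, comparison of male and female recombination (map-length
    ratios and marker-clustering interval profiles), and comparative-genomics
    post-processing of BLAST-style alignment tables (reference-contig assignment,
    homeology detection after whole-genome duplication, gene association and
    outgroup synteny assignment). A synthetic-data generator emulates the
    statistical structure of such a study, including coverage-dependent missing
    genotypes, paralogous sequence variants, Mendelian genotyping errors and
    telomere-biased male crossover placement, with full ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
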