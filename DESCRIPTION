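Package: embryophase
Title: Proband-Free Preimplantation Genetic Testing for Thalassemia by
    Affected-Embryo Haplotype Phasing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a proband-free preimplantation genetic testing
    (PGT-M) workflow for recessive thalassemia. Parental disease
    haplotypes are phased using affected embryos from the same IVF cohort
    as the linkage reference; sibling embryos are then genotyped by
    informative-SNP linkage voting with direct mutation detection
    (read-depth collapse for the SEA alpha-globin deletion,
    allele-fraction calls for the HBB CD41-42 -AAAG indel) as
    cross-validation. Includes aneuploidy screening from binned read
    counts, transfer-decision and cohort reporting, and a seeded
    synthetic-cohort simulator modelling Mendelian transmission,
    recombination, whole-genome-amplification allele dropout and
    amplification failure, and sequencing depth, so the entire pipeline
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
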