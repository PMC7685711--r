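Package: virtype
Title: Titer-Associated Multilocus Viral Genotypes: Simulation, Association
    and Selection Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying two multilocus genotypes of a DNA virus that
    differ roughly 100-fold in within-host titer. Provides a seeded synthetic
    cohort generator (four host populations, linked focal SNPs with
    diminishing titer returns, population-private background variation), a
    per-SNP titer association pipeline with permutation-based genome-wide
    significance and a haplotype permutation test, linkage disequilibrium and
    four-gamete recombination screening with High/Low/intermediate haplotype
    typing and coinfection screening, polarized McDonald-Kreitman counts with
    the Direction of Selection statistic and background contrasts, a discrete
    susceptible-infected evolutionary simulator with titer-scaled mutation and
    viral recombination, and closed-form selection-coefficient arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
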