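Package: dupsweep
Title: Copy-Number-Aware Association and Selection Scans at Duplicated
    Resistance Loci
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting insecticide-resistance loci that segregate
    as tandem duplications carrying a resistance SNP. Implements
    copy-number-aware estimation of resistant-allele dosage from
    allele-supporting read fractions, genotype-phenotype association
    (Fisher exact tests, Woolf odds ratios with Haldane-Anscombe
    correction, binomial GLMs with BIC stepwise reduction), windowed
    selection scans (Hudson's FST, the population branch statistic,
    Garud's H statistics, haplotype diversity, EHH decay), haplotype
    minimum-spanning-tree networks inside duplications, Patterson's D
    introgression tests with block-jackknife errors, and a k-mer
    genotype-phenotype association pipeline with canonical 2-bit k-mer
    counting, greedy overlap assembly and exact-match placement. A
    synthetic-cohort generator reproduces the statistical structure the
    analyses assume so the full pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
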