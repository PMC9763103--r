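Package: founderscan
Title: Identity-by-Descent Risk-Haplotype Detection in Deep Founder Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects haplotypes shared identical-by-descent (IBD) by three or more
    distantly related affected individuals in a deep founder pedigree, filters them
    by founder-pair ancestry, absence from population controls and carrier
    phenotype, fine-maps the surviving haplotypes against whole-genome variant
    data, and prioritizes rare haplotype-specific deleterious variants using
    population frequencies and deleteriousness scores (SIFT, PolyPhen, CADD,
    ncER). Includes a gene-dropping simulator that generates phased pedigree
    genotypes with planted risk haplotypes, recombination, genotype error and
    array-genotyped control cohorts, together with marker/sample QC
    (missingness, exact Hardy-Weinberg test, MAF, Mendelian checks, LD pruning)
    and a likelihood-ratio (LOD) scored seed-and-extend pairwise IBD detector.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
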