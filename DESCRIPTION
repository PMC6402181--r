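Package: liftann
Title: Cross-Assembly Variant Liftover, Annotation Transfer, and Catalog
    Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates variants called in a non-model organism by borrowing
    annotation resources from a better-characterised genome. Variants are
    normalized, lifted across assemblies through UCSC chain files with full
    allele reconciliation (strand flips, reference-allele swaps), joined
    against allele-keyed clinical assertions, positional score tables and
    interval tracks in target coordinates, translated back to their original
    coordinates, and merged with unliftable records into a single annotated
    VCF. Also provides gene-context and coding-consequence classification
    with impact tiers, population catalog summaries (allele frequency
    spectra, private alleles, variant types, region breakdown), Mendelian
    trio validation, a variants-of-interest prioritisation rule, and a
    deterministic synthetic fixture generator (genomes, chains, cohort VCF,
    gene models, annotation tables, pedigree, truth file) for end-to-end
    testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
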