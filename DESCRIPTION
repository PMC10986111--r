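Package: ystrpop
Title: Y-STR Haplotype Diversity and Population Differentiation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forensic Y-chromosomal STR population analysis. Reads and
    validates Yfiler 17-locus haplotype tables (including the unordered
    DYS385 a/b pair and microvariant alleles), computes Nei gene diversity
    per locus, haplotype diversity, discrimination capacity and haplotype
    match probability, partitions haplotype variation by two-level AMOVA
    with pairwise FST matrices and permutation significance, embeds
    population distance matrices by classical multidimensional scaling,
    and ships a forward-time Wright-Fisher simulator of patrilineal
    stepwise-mutating Y-STR haplotypes for validation and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
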