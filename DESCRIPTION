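Package: zrhc
Title: Zero-Recombinant Haplotype Phasing on General Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic haplotype phasing for pedigrees genotyped at
    bi-allelic markers under the zero-recombination assumption. Builds a
    system of parity constraints on transmission indicators over GF(2) from
    the pedigree graph and its locus graphs, reduces it via a spanning tree
    and a constraint graph instead of Gaussian elimination, and returns a
    general solution: every haplotype configuration compatible with the
    genotypes, expressed over free GF(2) variables. Handles arbitrary
    mating loops, detects Mendelian and cross-locus inconsistencies, and
    ships a zero-recombinant gene-dropping simulator with recorded truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
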