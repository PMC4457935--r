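Package: evoselect
Title: Directed-Evolution Library Design and Amplicon Selection Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for directed-evolution experiments that select
    protein variants from doped degenerate-oligonucleotide libraries by
    iterative conjugational recombination. Provides the doped-library
    mutation-spectrum model (per-position Bernoulli doping, exact
    substitution-count distributions), coupon-collector coverage confidence
    (Monte Carlo and an exact inclusion-exclusion CDF) for deciding how many
    clones guarantee full single-substitution coverage, an amplicon
    deep-sequencing pipeline (paired-read merging, quality trimming,
    Smith-Waterman local alignment, substitution calling, codon translation,
    population tabulation and across-cycle enrichment trajectories), a
    synthetic selection simulator with multinomial colony bottlenecks and
    per-variant fitness, and the coupled-ATPase and colony-count assay
    arithmetic (NADH slope to rate, apparent kcat, competition-plate QC,
    survival and specific-fluorescence ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
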