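Package: clovermap
Title: Pseudo-Testcross Linkage Mapping and EST-SSR Analysis for
    Allotetraploid White Clover
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building genetic linkage maps in an outcrossing
    allotetraploid full-sib (F1) design such as white clover (Trifolium
    repens, 2n = 4X = 32): mismatch-tolerant EST-SSR microsatellite
    mining with motif canonicalization, two-way pseudo-testcross
    splitting of a locus-by-progeny genotype table, two-point
    recombination/LOD estimation with Kosambi distances, LOD-threshold
    grouping, regression-style marker ordering with ripple and
    goodness-of-fit locus removal, reference-guided disassembly of
    over-merged linkage groups, parental-map integration through shared
    bi-parental anchor loci, a grid-sampled r-squared scan that detects
    linkage disequilibrium within and across linkage groups, and synteny
    block chaining of map-to-genome homolog anchors.  A synthetic-data
    module simulates the full study design (gametes under a Markov
    recombination model, segregation distortion, multi-locus markers,
    planted cross-chromosome disequilibrium, transcripts with planted
    SSR tracts, and colinear reference genomes) so that every inference
    can be scored against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
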