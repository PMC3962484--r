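Package: salhap
Title: Linkage Mapping and Half-Tetrad Analysis of Salmonid RAD-Seq Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds duplicate-aware reference databases of fixed-length RAD
    loci, calls genotypes under read-depth rules suited to haploid and
    gynogenetic salmonid crosses, constructs two-point linkage maps with
    LOD-escalated grouping, locates centromeres by half-tetrad analysis of
    gynogenetic diploids, and characterizes homeologous-arm divergence after
    whole genome duplication.  Ships a meiosis simulator (crossover
    interference models, half-tetrad genetics, read-depth noise) so the whole
    pipeline is testable end to end without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
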