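# salhap

Duplicate-aware RAD-seq linkage mapping and half-tetrad centromere
analysis for salmonid crosses.

Salmonids descend from a whole genome duplication, so many 74-nt RAD
loci persist as homeologous pairs whose copies differ at only 1–3
nucleotides.  Short-read markers from such pairs collapse into single
apparent loci, producing phantom heterozygotes and corrupting naive
marker databases — while at the same time the duplicated loci are the
only markers that can reveal which chromosome arms are homeologous.
`salhap` is for geneticists building linkage maps in this setting from
haploid, gynogenetic-diploid and diploid crosses.  It provides the full
chain:

* **Reference database construction** — de novo clustering of 74-nt tags
  (loci distinct at > 3 mismatches), a coverage filter (depth > 5 reads
  in > 85% of individuals), a self-alignment screen for repeats, a
  DUST-style low-complexity screen, and duplicate identification from
  haploid offspring: a haploid is hemizygous at every true single-copy
  locus, so a locus heterozygous in ≥ 2 haploids of one family is
  duplicated.
* **Genotype calling** under depth rules robust to unbalanced allele
  coverage: missing below 10 reads; heterozygous only when both verified
  alleles (depth > 2) are present and total depth ≥ 10.  Duplicated
  markers are classified from their segregation (one or both paralogs
  polymorphic — OPP/BPP) by maternal gamete enumeration, e.g. parents
  `aa`/`ab` → `0.5 aa : 0.5 ab`, parents `ab`/`ac` → `0.25` each of
  `aa, ab, ac, bc`; BPP loci decompose into two mappable markers.
* **Two-point linkage mapping** — rf = R/n, LOD = R·log₁₀(2rf) +
  (n−R)·log₁₀(2(1−rf)); single-linkage grouping at rf ≤ 0.25 with LOD
  escalating from 3.0 in steps of 1.0 until the 34-chromosome karyotype
  resolves; seriation ordering; consensus merging of family maps;
  anchoring to chromosomes.
* **Half-tetrad analysis** — a gynogenetic diploid (second polar body
  retained) is heterozygous at a locus exactly when a crossover fell
  between locus and centromere, so the heterozygote fraction y rises
  from 0 at the centromere to 1 under complete interference (2/3 under
  Poisson crossovers: y_k = (2/3)(1 − (−1/2)^k)).  The package locates
  centromeres, classifies chromosomes metacentric/acrocentric, computes
  per-arm maximum proportion of heterozygotes (MPH) and counts
  crossovers per progeny per arm.
* **Duplication analysis** — kernel-smoothed duplicate density along the
  map (2 cM bandwidth), homeologous-arm inference from mapped BPP
  paralog pairs, and reciprocal-unique cross-database alignment.
* **A meiosis simulator** (tetrads, configurable crossover interference,
  negative-binomial read depth, sequencing error) generating all of the
  above inputs with truth files, so the entire pipeline is testable
  without sequencing data.

## Worked example

```r
library(salhap)

cfg <- make_fixtures("tiny")              # 2 chromosomes, 1 homeolog pair
man <- run_pipeline(cfg, "salhap_run", seed = 42)
res <- man$results

table(res$refdb$status)
#> duplicated     unique
#>          4         36
```

All four simulated paralog pairs were collapsed into single database
loci and flagged duplicated by the two-heterozygous-haploids rule; the
36 single-copy loci screened clean.

```r
head(res$map[, c("group", "marker", "bin", "position", "chrom")], 5)
#>   group marker    bin position chrom
#> 1  LG01 C00031 C00031 0.000000     2
#> 2  LG01 C00022 C00022 4.558039     2
#> 3  LG01 C00040 C00022 4.558039     2
#> 4  LG01 C00033 C00033 9.116078     2
#> 5  LG01 C00036 C00033 9.116078     2
```

The consensus map lists each marker's linkage group, co-segregation bin
and cumulative Kosambi position in cM, anchored to the simulated
chromosomes.

```r
res$centromere$crossovers$double_crossover_freq
#> [1] 0
res$duplication$homeologies
#>   arm_a arm_b support
#> 1    1q    2q       2
```

Under complete interference no progeny shows a double crossover, and
the two mapped both-paralog-polymorphic loci link the q arms of
chromosomes 1 and 2 — exactly the homeologous pair the simulation
planted.  `make_fixtures("demo")` scales the same run to the full
karyotype (16 metacentric + 18 acrocentric chromosomes; haploid
families of 46/48/72, gynogenetic families of 84/90/93).

A command-line veneer over the same functions is installed at
`inst/cli/salhap.R` (subcommands `run`, `simulate`, `build-refdb`,
`genotype`, `map`, `centromere`, `crossovers`, `duplication`,
`crossmap`).

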