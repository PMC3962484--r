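---
title: "Duplicate-aware RAD linkage mapping and half-tetrad centromere analysis"
author: "salhap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplicate-aware RAD linkage mapping and half-tetrad centromere analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salhap)
```

## The problem

Salmonid genomes descend from a whole genome duplication.  Many loci still
exist as *homeologous* pairs: two copies on different chromosome arms whose
sequences are nearly identical.  For short-read RAD markers (here, 74-nt
tags) this is a double hazard.  Paralogous copies within a few mismatches of
each other collapse into one apparent locus, so a homozygous individual can
look heterozygous; and repeat-derived tags align promiscuously.  A usable
marker database must therefore be built with explicit screens for
repetitiveness, low complexity, and duplication, and the duplicated loci —
far from being noise — are the raw material for identifying which arms are
homeologous.

`salhap` implements the full computational chain for this setting:

1. a **meiosis simulator** producing haploid, gynogenetic-diploid and
   diploid crosses with configurable crossover interference and a
   read-depth noise model, so every downstream stage is testable against
   known truth without sequencing data;
2. a **reference database builder** (clustering, coverage filter,
   self-alignment screen, low-complexity screen, haploid-based duplicate
   identification);
3. a **genotype caller** with depth rules suited to unbalanced allele
   coverage, plus the duplicated-marker segregation model;
4. **two-point linkage mapping** with LOD-escalated grouping, seriation
   ordering, consensus merging and chromosome anchoring;
5. **half-tetrad centromere analysis** of gynogenetic diploids;
6. **duplication analysis**: kernel-smoothed duplicate density, homeology
   inference, cross-database alignment.

## Genetic model

### Tetrads, crossovers and interference

Each meiosis is simulated as a tetrad: four chromatids, two per homolog,
with sisters sharing a centromere.  Crossovers are placed per chromosome
arm and each exchange joins one chromatid of each homolog, chosen uniformly
(**no chromatid interference** — this assumption is what produces the
classical 2/3 limit below).  Three interference regimes are available:

* `complete` — exactly one crossover per arm, uniformly positioned.  This
  is the near-complete interference described for salmonid female meiosis.
  Note that one obligate crossover per arm fixes the *genetic* arm length
  at 50 cM regardless of the configured coordinate length; configured cM
  act as a marker-placement coordinate (and as the Poisson rate under
  `none`).
* `none` — the crossover count per arm is Poisson with mean equal to the
  arm length in Morgans (a tetrad-level rate), positions uniform.
* `gamma` — a stationary gamma renewal process with shape `nu`
  interpolates between the two (`nu = 1` is Poisson; large `nu` approaches
  regular spacing).

Crossover positions along an arm are taken uniform; the real positional
distribution is unknown and deliberately not modelled further.

### Half-tetrad genetics

A gynogenetic haploid inherits one random chromatid; at every
non-duplicated locus it is hemizygous and scores homozygous, which is
exactly why apparent heterozygosity in haploids diagnoses collapsed
paralogs.  A gynogenetic diploid retains the second polar body: it carries
the two chromatids that co-segregated at meiosis I.  Those chromatids
differ at a locus — the offspring is heterozygous — precisely when an odd
number of exchanges separates them between locus and centromere.  With
`k` crossovers in that interval and no chromatid interference, brute-force
enumeration of chromatid choices (frozen as a test oracle) gives

$$y_k = \frac{2}{3}\left(1 - \left(-\tfrac{1}{2}\right)^k\right),$$

so `y` is 0 at the centromere, 1 under complete interference at any locus
distal to the obligate crossover, and tends to 2/3 when crossover counts
are Poisson.  These are the limits the acceptance checks reproduce by
simulation at n = 10,000 offspring.  The gene–centromere distance
estimator `y/2 × 100` cM is exact under complete interference and biased
distally under Poisson crossovers; the bias is documented, not corrected,
because complete interference is the study condition.

### Duplicated-marker segregation

A collapsed duplicated locus is scored as the unordered pair of the
alleles carried by its two paralogs.  Enumerating the four equally likely
maternal gamete combinations gives the expected haploid offspring classes
for each parental configuration; e.g. parents `aa`/`ab` segregate
`0.5 aa : 0.5 ab` (one paralog mappable), parents `ab`/`ac` segregate
`0.25` each of `aa, ab, ac, bc` (both paralogs mappable), while `ab`/`ab`
and `aa`/`bb` are uninformative.  `infer_duplicate_marker()` recovers the
configuration from the observed class set alone and decomposes each
composite genotype into one allele per paralog, turning a BPP locus into
two mappable markers — the mechanism by which homeologous arms are linked.

## Synthetic data: what it emulates and what it does not

The generator reproduces the *genetic structure* the analysis depends on:
a 34-chromosome karyotype (16 metacentric, 18 acrocentric), homeologous
arm pairs carrying paralog pairs at 1–3 mismatches placed in the distal
30% of their arms (where residual tetrasomic pairing keeps homeologs
similar), three cross types at the study's family sizes (haploid 46/48/72;
gynogenetic diploid 84/90/93), and read pileups with negative-binomial
depth (default mean 20–30, dispersion 10) and per-read error (default
0–0.5%).  Error reads carry novel third-allele sequences by default so
that error-driven false heterozygotes in haploids remain detectable; a
`parental` mode flips reads to the other parental allele instead, to
stress the more-than-one-heterozygous-haploid rule.  The
locus-discovery panel is emulated as unrelated diploids drawn by
Hardy–Weinberg sampling with uniform allele frequencies.

It does **not** emulate: base-level reads with quality scores, barcode
structure or restriction-site dropout; population allele-frequency spectra
(panel frequencies are uniform); male meiosis and pseudolinkage; or
missing-data patterns caused by DNA quality.  Passing tests therefore
demonstrate the correctness of the algorithms under the stated genetic
model, not robustness to every artifact of real libraries.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_depth_per_locus` | 5 reads | panel depth counted as "sequenced" (strict >) |
| `min_individual_fraction` | 0.85 | panel fraction required (strict >) |
| `max_mismatch` | 3 nt | whole-locus distance treated as "same locus" |
| `min_reads_for_genotype` | 10 reads | below this a call is missing |
| allele verification | depth > 2 | an allele with ≤ 2 reads is unverified |
| `min_het_haploids_for_duplicate` | 2 | het haploids in one family to flag duplication |
| `low_complexity_threshold` | 1.0 | DUST-style triplet score cutoff |
| `max_rf` | 0.25 | grouping recombination-fraction ceiling |
| `lod_start`, `lod_increment` | 3.0, 1.0 | LOD escalation until ≥ `target_groups` |
| `target_groups` | 34 | the karyotype's chromosome count |
| `map_function` | kosambi | adjacent-interval distances (haldane, morgan selectable) |
| duplicate-density `bandwidth` | 2 cM | Gaussian kernel bandwidth |
| centromere `y_floor` | 2/n | heterozygote fraction read as "about zero" |

The heterozygote rule (both verified alleles > 2 reads and total ≥ 10)
corrects the bias against heterozygotes with unbalanced allele depth; the
rule cannot fire below 10 reads by construction.  Three or more verified
alleles at one locus are aberrant (paralog collapse in a diploid) and the
call is set missing, which is what effectively excludes duplicated loci
from gynogenetic-diploid profiles.

## Numerical and design choices

* **Sequence matching** is whole-locus Hamming comparison, computed as an
  indicator-matrix product and cross-checked in the tests against an
  independent string-distance implementation.  There is no indel model;
  74-nt tags are compared end to end.
* **Locus clustering** takes single-linkage components over unique read
  sequences at ≤ 3 mismatches (alleles of one locus, including collapsed
  paralog alleles up to 6 apart, chain through their shared ancestor
  sequence), then assigns each sequence to the depth-weighted consensus it
  uniquely matches; sequences within 3 of two consensi are flagged
  ambiguous and left out.  Consensus ties are broken by lexicographic base
  order so output is deterministic.
* **The low-complexity screen** replaces an alignment-based
  low-complexity filter with a native DUST-style statistic: with $c_t$ the
  count of triplet $t$ among the 72 overlapping 3-mers,
  $S = \sum_t \binom{c_t}{2} / 71$.  Uniform-random 74-mers score 0.56 on
  average and exceed 1.0 about 0.2% of the time (the calibration target
  was < 1% false masking), while dinucleotide and mononucleotide repeats
  score 18 and 36.  The threshold 1.0 was fixed from that random-sequence
  distribution once.
* **Grouping** is single-linkage transitive closure over pairs with
  rf ≤ 0.25 and LOD ≥ threshold, the LOD raised by 1.0 until at least 34
  groups exist.  Haploid marker phase is arbitrary, so the grouping table
  uses the phase-minimized recombinant count min(R, n−R), i.e. the better
  of the two phases.  Pairs with fewer than 10 joint observations get
  LOD 0.  Marker density matters at n = 46: at ~11 cM spacing the
  escalation equilibrates with occasional centromere-region splits and
  sporadic false joins, while at ~4 cM spacing (30 markers per
  chromosome, the pipeline default) partitions are clean and the count is
  34, occasionally 35–36 when a centromere region splits off.
* **Ordering** bins co-segregating markers (representative: smallest
  marker id), then seriates bins to minimize total adjacent recombinant
  count — multi-start nearest-neighbour construction with 2-opt
  improvement, which matches exhaustive search on the small groups where
  that is testable.  Distances are summed two-point intervals (no
  multipoint re-estimation); Kosambi is the default map function.
* **Consensus merging** aligns family-map orientations by rank
  correlation of shared markers, builds a directed precedence graph from
  every within-family order relation, and topologically sorts it.  Cycles
  are resolved by dropping, per strongly connected component, the marker
  supported by fewest families (ties: lexicographically larger dropped),
  reported as conflicts.  Merging k copies of one map returns that map.
* **Centromere intervals** are the maximal run of consecutive loci with
  y ≤ 2/n (tolerating one miscalled offspring); metacentric requires
  above-floor loci on both flanks.  After location, groups are flipped so
  the shorter (p) side precedes the centromere.  Crossover counting first
  phases markers into maternal coupling along the map (flipping a marker
  when more than half the joint offspring disagree with its phased
  neighbour), then counts switches per progeny per arm.
* **Homeology calls** require both decomposed BPP paralogs to map onto
  arms with located centromeres; same-arm pairs are anomalous and
  excluded.  Calls keep any support ≥ 1 by default (`min_support`
  exposes the threshold).  Cross-database alignment keeps a pair only if
  each locus is the other's sole match within 3 mismatches (reciprocal
  uniqueness).
* **Seeding**: one global seed is fanned out to per-stage child seeds by a
  fixed affine map modulo $2^{31}-1$, so any stage can be rerun alone and
  the whole pipeline is byte-deterministic given config + seed.

## Worked example

```{r example, eval = FALSE}
library(salhap)

cfg <- make_fixtures("tiny")      # 2 chromosomes, 1 homeolog pair
man <- run_pipeline(cfg, "salhap_run", seed = 42)
res <- man$results

table(res$refdb$status)           # unique / duplicated / excluded_*
head(res$map)                     # consensus map: group, marker, cM
res$centromere$crossovers$double_crossover_freq
res$duplication$homeologies      # arm pairs with BPP support
```

On the tiny fixture this takes ~25 s and recovers the configured homeolog
arm pair (chromosome 1q–2q) from the mapped BPP paralogs, with a
double-crossover frequency of 0 under complete interference.  The `demo`
fixture runs the full 34-chromosome karyotype at the study's family sizes.

## Problem sizes used in the checks

The acceptance analyses use 10,000 gynogenetic-diploid offspring for the
heterozygosity limits (standard error ~0.005), a 498 cM arm for the
no-interference limit so the terminal marker is distal to essentially all
crossovers (asymptote remainder < 0.001), gamete enumeration (exact) for
the segregation ratios, and one haploid family of 46 offspring over the
34-chromosome karyotype with 30 markers per chromosome for linkage-group
recovery.  Unit and property tests run on 1–2 chromosome genomes with
90–10,000 offspring, sized so the whole suite completes in a couple of
minutes.

## Known limitations

* Matching is mismatch-only; indel-bearing reads are unassigned.
* The gene–centromere estimator assumes complete interference; under
  partial interference it underestimates distal distances.
* The centromere interval is a marker-position run, so its resolution is
  the local marker spacing; with no marker near y ≈ 0 the centromere is
  reported unresolved rather than extrapolated.
* Two-point distance summation slightly inflates map length relative to
  multipoint likelihood when genotyping error is present.
* The consensus merge drops conflicting markers rather than optimizing a
  global objective; with few shared markers per group it can keep
  family-specific groups separate.
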