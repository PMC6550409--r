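---
title: "Screening microsatellite genotypes for facultative parthenogenesis"
author: "parthenoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening microsatellite genotypes for facultative parthenogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parthenoscreen)
```

## The problem

A female reptile kept in isolation from males lays clutch after clutch of
fertile eggs. Two hypotheses compete: she stored sperm from a long-past
mating, or she reproduces by facultative parthenogenesis — development of an
embryo from a female gamete alone. Codominant microsatellite genotypes can
separate the two, because they leave opposite signatures at loci where the
mother is *heterozygous*:

* **Sperm storage / sexual reproduction**: each offspring receives one
  maternal and one paternal allele. Unless the father happens to carry the
  very allele the maternal gamete delivered, the offspring is heterozygous —
  often with an allele absent from the mother entirely.
* **Parthenogenesis with homozygosity-forcing mechanisms**: every offspring
  allele is maternal, and offspring show a *single* allele per locus.

Fragment-length genotyping cannot distinguish a true homozygote (two equal
copies) from a hemizygote (a single copy, as in a haploid individual), so
the package classifies such calls as `HOM_OR_HEMI` and carries the ambiguity
through the analysis rather than resolving it arbitrarily.

## The probability bound

Consider one offspring at one maternally heterozygous locus with alleles
$A$ and $a$. Under sexual reproduction the offspring shows a single allele
exactly when the paternal gamete matches the maternal gamete drawn
independently with probability $\tfrac12$ each:

$$
P(\text{single allele}) \;=\; \tfrac12 f_A + \tfrac12 f_a \;\le\; \tfrac12 ,
$$

where $f_A, f_a$ are the paternal population frequencies of the maternal
alleles. The maximum $\tfrac12$ is attained **iff** the paternal pool is
confined to the maternal pair ($f_A + f_a = 1$); no equal-frequency
assumption is needed, and `perLocusSexualHomProb()` implements the general
form. The package verifies maximality by randomized search rather than
hard-coding it, and verifies the multi-locus product against exhaustive
gamete enumeration on small configurations.

With $n$ single-allele observations across offspring and loci, treating
observations as independent ("unlinked") gives the worst-case bound
$0.5^n$. If instead all loci were perfectly linked, each offspring
collapses to one observation and the bound is $0.5^k$ for $k$ offspring —
the conservative alternative. Both are reported; the unlinked bound is
primary unless `assumeLinked = TRUE`. On the bundled water dragon table the
nine offspring contribute $n = 62$ informative single-allele calls (63
cells minus one missing genotype), giving $0.5^{62} = 2.17\times10^{-19}$,
and the linked bound is $0.5^{9} = 1.95\times10^{-3}$ — both below
$\alpha = 0.01$.

Counting rules that matter:

* loci at which the mother is **not** heterozygous are uninformative (the
  worst-case bound there is 1) and are excluded with a warning;
* a missing offspring call reduces $n$; it never counts for or against;
* a heterozygous offspring call at a maternal-het locus, even with
  maternal-only alleles, vetoes the all-homozygous signature, and any
  non-maternal allele vetoes the verdict outright regardless of the bound.

## Worked example

```{r example}
t4 <- waterDragonGenotypes()
t4
res <- runParthenogenesisTest(t4, "WD-10", alpha = 0.01)
res
```

The four wild reference individuals confirm the markers are polymorphic:

```{r hobs}
observedHeterozygosity(t4)$meanPooled3
```

## Mechanism reasoning

Three parthenogenesis mechanisms force complete homozygosity: terminal
fusion automixis (fusion of sister meiotic products), gamete duplication
(genome doubling of one gamete), and spontaneous haploid development. A
fully homozygous, fully maternal brood is consistent with all three and the
data cannot rank them; a heterozygous maternal-only offspring excludes
duplication and haploid development (one gamete cannot carry two alleles
without fusion) and brings central fusion automixis into play; any foreign
allele leaves only sexual reproduction (sperm storage included — it is
genetically indistinguishable from fresh mating).

```{r mech}
consistentMechanisms(res, t4)
```

Phase patterns index each offspring's retained maternal allele against the
mother's ascending-sorted pair (`FIRST`/`SECOND`; sorting makes the
labelling deterministic since true phase is unknown). If the brood's
patterns cannot all be assigned to a single complementary pair of
multilocus phases, the maternal gametes were not clonal:

```{r phase}
detectPhaseVariation(phasePatterns(t4, "WD-10"))
```

The flag is reported as "recombination **and/or** independent assortment":
without chromosome assignments for the loci, crossover cannot be separated
from assortment of different chromosomes, and the package deliberately does
not attribute the variation to either. Wildcard (unknown) cells in the
complementary-pair test are resolved by exhaustive search over candidate
phase vectors — brood sizes and locus counts in this setting are small
(the search is capped at 25 informative loci).

## The brood simulator

`simulationConfig()` + `simulateOffspring()` generate broods with the
statistical structure the analysis assumes, for calibration and power
analysis. Design choices:

* **Defaults emulate the case study**: 7 loci, brood of 9, and the
  worst-case biallelic paternal pool with equal frequencies — the
  configuration under which the $0.5^n$ bound is tight, which makes the
  simulator a *stress test* of the screen rather than an easy target.
  The mother is drawn conditioned on heterozygosity at every locus,
  mirroring informative-marker selection in a real screen.
* **No crossover map is invented.** The automictic modes take a per-locus
  heterozygosity-retention probability `hRetain` (terminal fusion retains
  with probability `hRetain`, central fusion with `1 - hRetain`), default
  0, which reproduces the fully homozygous signature. Real retention rates
  depend on locus–centromere distance, which is unknown for this species.
* **Sperm storage is simulated identically to sexual reproduction** — the
  hypotheses are genetically indistinguishable.
* **Haploid offspring are emitted as single-allele calls**, preserving the
  hemizygous ambiguity downstream.
* **Missing calls are masked uniformly at random** at a configurable rate
  (default 0), emulating genotype dropout.
* **Hierarchical seeding**: one fixed-offset substream per offspring, so
  enlarging the brood never reshuffles earlier offspring and identical
  seeds reproduce tables bit-for-bit.

What the simulator does *not* emulate: linkage between loci (no genetic map
exists), microsatellite mutation/slippage, null alleles, and any viability
differences between mechanisms. Passing tests therefore demonstrate the
statistical machinery on idealized Mendelian data, not robustness to those
real-data artifacts.

Calibration and power checks used by the test-suite (problem sizes chosen
to keep Monte-Carlo error well below the effect being measured):
per-locus homozygote fraction at 10^4 sexual offspring against the closed
form; the all-homozygous brood rate at 2×10^5 replicates against $0.5^7$;
verdict rejection of 10^4 sexual 9×7 broods. The 10^4-replicate sweep runs
through the same vectorized pass/fail kernel as
`estimateFalsePositiveRate()`, whose agreement with the full
`runParthenogenesisTest()` verdict is asserted separately on a subsample.

## The repeat miner

Marker discovery in the case study selected perfect tri-/tetranucleotide
arrays from shotgun reads. `findRepeats()` reports every maximal perfect
tandem array with at least `minRepeats` copies, scanning the
self-comparison vector $s_i = s_{i+k}$ for maximal periodic runs (linear
time per motif length). Conventions:

* **Canonical motifs** (`canonicalMotif()`): lexicographic minimum over all
  rotations of the motif and of its reverse complement, so one array is
  named identically from either strand and any phase. Motifs that are a
  repetition of a shorter unit (`ACAC`, homopolymers) are degenerate —
  they describe mono-/dinucleotide repeats — and are rejected.
* **Coordinates** are 0-based half-open; reported `motif` is the leading
  unit as observed, so `substr(seq, start+1, end)` always equals the motif
  tandemly repeated `repeats` times.
* **Collapsing**: overlapping reports of one array under rotated motifs are
  merged per canonical motif, keeping the record with most copies (earliest
  start on ties). A region supporting both a tri- and a tetra-motif
  interpretation yields both records; `filterCandidates()` resolves by
  repeat count.
* **Perfect repeats only**: interruption tolerance is out of scope, matching
  the completeness criterion used for marker selection.
* `filterCandidates()` applies the strict `repeats > 20` rule by default.
  Published marker panels occasionally include a 20-repeat locus, so the
  threshold is configurable, but the default follows the stated rule as
  printed.

The miner is validated against an independent brute-force scanner (phase-
offset chunking + run-length encoding) on hundreds of random 2 kb
sequences, plus seeded arrays at marker scale ((ACAT)₂₂, (AGAT)₂₅) with
exact counts and coordinates.

## Numerical and interface choices

* Probabilities are kept at full precision internally and rendered at 3
  significant figures in reports; H_obs and egg rates are additionally
  rounded to 3 decimals.
* Mean H_obs is computed both pooled (total het calls / total non-missing)
  and as the unweighted mean of per-individual fractions; the pooled value
  is the headline. On the bundled table both equal 22/28 because no
  reference call is missing.
* Allele sizes are exact integers; no fragment-size binning is performed
  (upstream allele calling is expected to have standardized sizes).
* Genotype CSV dialect: `id,role,<locus>,...`, alleles within a cell
  separated by `/`, missing as an empty cell or `NA` — minimal, diffable,
  spreadsheet-compatible.
* Degenerate inputs fail loudly: a mother heterozygous nowhere makes the
  test undefined (error), an empty individual subset is an error, and the
  full report flags skipped sections instead of dropping them.

## Limitations

* The bound is a worst-case screen, not a likelihood-based parentage
  analysis; it cannot estimate a father's genotype or test specific sires.
* With few informative loci the screen is underpowered by construction:
  detection requires $0.5^{n} < \alpha$, so at $\alpha = 0.01$ at least 7
  informative single-allele observations are needed (`powerCurve()` maps
  this design space).
* Mechanism reasoning is signature-based; it cannot distinguish the three
  homozygosity-forcing mechanisms from one another, and heterozygosity
  retention under automixis is parameterized, not derived from cytology.
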