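# parthenoscreen

Detection of facultative parthenogenesis from codominant microsatellite
genotype tables.

## What it does, and for whom

Zoo and wildlife geneticists occasionally face an isolated female that keeps
producing fertile eggs. `parthenoscreen` takes a genotype table (mother,
offspring, optional wild reference individuals; up to two allele fragment
sizes per locus) and answers: *could this brood plausibly come from a
mating, or was it produced parthenogenetically — and by which mechanism?*

At a locus where the mother is heterozygous with alleles A and a, a sexually
produced offspring shows a single allele only when the paternal gamete
matches the maternal one:

    P(single allele) = ½·f_A + ½·f_a ≤ ½,

with equality iff the paternal pool is confined to the maternal pair. For
*n* independent single-allele observations across offspring and loci the
worst-case probability under sexual reproduction is therefore **0.5^n**
(the "unlinked" bound); under perfect linkage each of *k* offspring
contributes a single observation, giving the conservative **0.5^k**
("linked") bound. A brood is called parthenogenetic at level α when every
offspring allele is maternal, no offspring is heterozygous at a maternally
heterozygous locus, and the applicable bound falls below α.

Around this core the package provides:

* zygosity classification that preserves the homozygous/hemizygous
  ambiguity of fragment-length data (`HOM_OR_HEMI`),
* maternal-compatibility screening and observed-heterozygosity reports,
* mechanism reasoning (terminal/central fusion automixis, gamete
  duplication, haploid development) plus a multilocus phase-variation test,
* a reproductive-mode brood simulator for calibration and power analysis,
* a perfect tri-/tetranucleotide microsatellite miner for FASTA input with
  canonical motif collapsing, candidate filtering, TSV/BED output,
* JSON/text reporting and a command-line wrapper
  (`inst/cli/parthenoscreen.R`).

## Worked example

The package bundles the genotype table of a captive female Asian water
dragon (WD-10), nine of her offspring, and four wild reference individuals
typed at seven microsatellite loci:

```r
library(parthenoscreen)
t4 <- waterDragonGenotypes()
res <- runParthenogenesisTest(t4, "WD-10", alpha = 0.01)
res
#> Parthenogenesis screen
#>   mother: WD-10; brood: 9 offspring; informative loci: 7
#>   maternally compatible: 9 / 9 offspring
#>   homozygous observations: n = 62 (missing 1, heterozygous 0)
#>   unlinked bound: 2.17e-19; linked bound: 0.00195
#>   verdict at alpha = 0.01: parthenogenesis SUPPORTED
```

Every offspring carries only maternal alleles and a single allele per locus;
62 informative observations (63 cells, one missing genotype) give an
unlinked bound of 0.5^62 = 2.17×10⁻¹⁹, and even under perfect linkage
0.5^9 = 1.95×10⁻³ stays below α = 0.01. The markers are informative: the
wild reference panel has a pooled observed heterozygosity of

```r
observedHeterozygosity(t4)$meanPooled3
#> [1] 0.786
```

The fully homozygous signature is consistent with three mechanisms, which
these data cannot rank:

```r
consistentMechanisms(res, t4)
#> [1] "TERMINAL_FUSION_AUTOMIXIS" "GAMETE_DUPLICATION"
#> [3] "HAPLOID_DEVELOPMENT"
detectPhaseVariation(phasePatterns(t4, "WD-10"))$variation
#> [1] TRUE   # maternal gametes were not clonal
```

Egg-clutch statistics round out the report:

```r
reproductionSummary(eggs = 64, fertile = 30, hatched = 2)[
  c("fertilityRate3", "hatchRate3")]
#> $fertilityRate3
#> [1] 46.875
#> $hatchRate3
#> [1] 3.125
```

See `vignettes/parthenogenesis-screening.Rmd` for the model, the simulator
design and the repeat-miner conventions.

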