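Package: parthenoscreen
Title: Detection of Facultative Parthenogenesis from Codominant Microsatellite Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring parthenogenetic reproduction from codominant
    microsatellite genotype tables. Screens offspring for maternal
    compatibility, classifies zygosity, computes worst-case probability bounds
    on an all-homozygous brood arising through sexual reproduction (with and
    without the perfect-linkage assumption), and reasons about which
    parthenogenesis mechanisms (terminal or central fusion automixis, gamete
    duplication, haploid development) are consistent with an observed brood.
    Includes a reproductive-mode brood simulator for calibration and power
    analysis, and a miner for perfect tri- and tetranucleotide microsatellite
    arrays in FASTA sequences with canonical motif collapsing and
    candidate-selection filters.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
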