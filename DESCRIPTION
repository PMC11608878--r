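Package: hzscan
Title: Per-Locus Divergence Scans for Hybrid Zones with X-Aware Genotype
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for per-locus divergence analysis between two hybridizing
    species from targeted-resequencing haplotype alignments: consensus
    genotype calling from read pileups, sex inference from X-linked
    homozygosity and collapsing of hemizygous male X genotypes, per-locus
    nucleotide diversity, Tajima's D, absolute divergence (Dxy) and relative
    differentiation (Fst) under a complete-deletion site policy,
    locus-category permutation tests with BCa bootstrap intervals,
    outgroup-calibrated mutation rates via D = 2*mu*t, four-gamete extraction
    of the longest non-recombining block and IM-format input preparation.
    Includes a two-population isolation-with-migration coalescent simulator
    (autosomal and X-linked loci, hemizygous males, per-locus migration
    barriers and sweep-like diversity reduction) used to exercise the whole
    pipeline and to contrast the relative vs absolute divergence signatures
    expected under restricted introgression versus in-situ sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
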