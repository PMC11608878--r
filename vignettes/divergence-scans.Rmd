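---
title: "Methods: per-locus divergence scans in a hybrid zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-locus divergence scans in a hybrid zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Two hybridizing cricket species (*Gryllus firmus* and *G. pennsylvanicus*)
meet in a mosaic hybrid zone. Some loci cross the species boundary freely
("introgressing"), others do not ("non-introgressing"). Two very different
histories can produce a locus with high relative differentiation
(F~ST~): a true barrier to gene flow, or an in-situ loss of
within-species diversity (a sweep or strong drift) with no gene flow at
all. The two histories separate on *absolute* divergence: a barrier locus
in an otherwise connected genome keeps accumulating D~XY~ while its
neighbours are homogenized; a sweep inflates F~ST~ without touching
D~XY~. `hzscan` implements the full per-locus workflow needed to make that
comparison from targeted-resequencing data, plus a coalescent simulator
that generates data under both histories so the contrast can be exercised
end to end.

Crickets have an X0 sex-determination system: males carry a single X. That
forces X-awareness at three places — sex must be inferred from X-linked
homozygosity (the animals cannot always be sexed morphologically), male X
genotypes must be collapsed to single haplotypes before diversity is
computed, and X-linked loci carry an inheritance scalar of 0.75 in
IM-style analyses.

# Pipeline stages and their parameters

## Consensus genotype calling

`call_consensus_base()` applies two thresholds per site: a site is called
only when total read coverage reaches `min_cov` (default 8, inclusive — the
source protocol states the rule both as "> 8" and as "a minimum depth of
8"; we adopt the inclusive reading and expose the knob), and it is called
heterozygous when the minor allele reaches `het_frac` (default 0.25,
inclusive: "at least 25%") of the reads. Modal-base ties break by the fixed
order A < C < G < T so calls are deterministic. Records whose called
fraction falls below `min_called_frac` (default 0.5) are flagged; the exact
exclusion rule used in the source study is unstated, so the floor is a
parameter, not a claim.

## Ambiguity handling and pseudo-phasing

Three-base IUPAC codes (B, D, H, V) indicate poor-quality calls and are
masked to N; two-base codes are genuine heterozygotes and are kept.
Diploid consensus sequences are expanded to haplotype pairs by *seeded
random phase assignment* rather than statistical phasing: every statistic
in scope (pi, theta~W~, Tajima's D, D~XY~, F~ST~) is a function of per-site
allele frequencies and therefore provably phase-invariant (the test suite
recomputes all of them under ten phase seeds). The only phase-sensitive
step is four-gamete trimming, which is why the phase seed is recorded in
the run manifest.

## Sex inference

Five (by default, `min_loci`) X-linked screening loci — those with the
highest mean called fraction — are scanned for heterozygous sites per
individual. An individual with at most `max_het_sites` (default 3,
"3 or fewer") heterozygous sites across the panel is classified male,
otherwise female; fewer than `min_loci` available loci gives "unknown".
The source protocol checked low-count polymorphisms "for allele quality
and frequency" by hand; the mechanical analogue here discounts
heterozygous sites whose pileup support falls below the calling
thresholds, when pileups are available. Whether the original count was of
het *sites* or het *loci* is ambiguous; we count sites and expose the
threshold. Males whose two phased X copies disagree at a called site are
flagged with a warning and copy 1 is kept.

## Site policy and the core statistics

All statistics default to *complete deletion* (a column with missing data
in any retained sequence is dropped for everyone), with gaps counted as
missing — the site-exclusion behaviour of the desktop software this
pipeline mirrors, and the policy under which its published numbers were
produced. Pairwise deletion is available for pi and D~XY~; Tajima's D is
refused (flagged NA) under pairwise deletion rather than given a
nonstandard definition.

Within-species statistics use complete deletion within the species;
between-species statistics (D~XY~, F~ST~) use the jointly usable sites, so
numerator and denominator always see the same columns.

F~ST~ defaults to the Hudson–Slatkin–Maddison form `1 - Hw/Hb` with
`Hw = (pi_A + pi_B)/2` and `Hb = Dxy` — the estimator in which the
relative-vs-absolute argument is usually stated. A pooled-total variant
(`1 - Hw/Ht`, Gst/Nst-style) is provided because the desktop software's
sequence-based F~ST~ family varies across versions. Negative values are
reported as-is, never clipped: medians are robust and clipping hides
information. Note the Hudson estimator's finite-sample behaviour: two
groups with literally identical composition give exactly `-1/(n-1)`, not
0; the ~0 expectation holds for independent samples from one pool.

Tajima's D uses the count form of pi over usable sites, with the classical
constants (`a1 = sum 1/i`, ..., `e2 = c2/(a1^2 + a2)`); it is flagged
undefined when `S = 0` or `n < 4`, never silently zero.

## Category tests

The four standard contrasts (introgression class over all loci; autosomal
vs X; class within autosomes; class within X) are tested per statistic
with a permutation test. Because the headline summaries are group
*medians*, the default test statistic is the difference of medians
(means available). When `choose(nA+nB, nA)` is at most 20,000 the full
enumeration is used and the p-value is exact (the identity relabelling
always counts, so p is never 0); otherwise 10,000 random reallocations
(the study's count) with the add-one Monte-Carlo correction
`p = (1 + #extreme)/(B + 1)` — whose floor, `10^-4` at `B = 10^4`, is
exactly the smallest p the study reports. Tests are two-sided by default
(the sidedness of the original values is unstated; the option is
exposed). No multiple-testing correction is applied, matching the
original analysis.

Bootstrap machinery: BCa intervals follow Efron (bias correction `z0`
from the bootstrap distribution's position relative to the point
estimate, acceleration from jackknife skewness); degenerate samples
collapse to the point and are flagged. The Spearman rank correlation uses
mid-ranks and a case-resampling bootstrap p-value
`2*min(P(rho* <= 0), P(rho* >= 0))`, floored at `1/(B+1)`.

## Calibration and IM preparation

Divergence times follow `D = 2*mu*t` with the standard arthropod
mitochondrial rate 0.0115 per site per My as the anchor; per-locus nuclear
rates are `mu = D_outgroup / (2*t_outgroup)`, averaged when both outgroups
are present, and omitted (as in the source workflow) when no outgroup
sequence exists. The distance model for consensus divergence is
uncorrected p-distance by default with a Jukes–Cantor option; at
divergences below 0.08 the two differ by under 6%, and the choice is
surfaced rather than hidden. Consensus ties (two-way) are encoded as
ambiguity codes and excluded from divergence counting — a tie carries no
majority signal. Generation time is fixed at one year (univoltine,
diapause-egg overwintering).

The four-gamete trimmer returns the longest contiguous window containing
no pair of biallelic, fully called segregating sites that shows all four
gametes; ties break leftmost, and a locus with no segregating sites
returns whole. Sites with missing data or more than two alleles are
ignored for pair compatibility, which is only defined for complete
biallelic pairs. The reference tool this step stands in for additionally
deletes whole sequences to enlarge the retained region; that optimization
is underspecified, so `hzscan` performs deterministic site-window trimming
only — an intentionally simpler, oracle-checkable rule that gives
conservative (never longer) blocks.

IM-format output writes one locus block per retained locus: sample counts
per species, block length, the infinite-sites model token `I`, the
inheritance scalar (1.0 autosomal, 0.75 X-linked; unknown linkage requires
an explicit default) and the calibrated per-year mutation rate when one
exists. A matching parser supports round-trip testing. Running the IM
MCMC itself is out of scope.

# The synthetic-data generator

`simulate_locus()` implements the two-population isolation-with-migration
structured coalescent in continuous time: within-deme coalescence at rate
`choose(k,2)/(2*Ne)`, per-lineage backwards migration at `m12`/`m21`, deme
merger at `T_split`, exponential waiting times throughout. Continuous time
(rather than discrete generations) was chosen because it admits exact
analytic expectations — `E[pi] = 4*Ne*mu`, isolation
`E[Dxy] = 2*mu*T + 4*Ne_anc*mu` — which the test suite verifies to within
three standard errors. Mutations are Poisson on total branch length and
placed on distinct sites (infinite sites, matching the IM model
assumption); when mutations outnumber sites the generator falls back to
placement with replacement and raises a machine-readable multi-hit
warning.

X linkage is modelled by sampling one lineage per male and two per female
and scaling Ne by 0.75; male X haplotypes can be emitted as duplicated
copies to mimic a phased diploid consensus before collapsing, which is
what the pipeline consumes. Populations within a species are labels on a
panmictic deme: the analyses pool populations by species, and no
within-species structure estimates exist to calibrate against. One master
seed derives all per-locus and per-stage seeds, so a whole multi-locus
dataset is reproducible from a single integer.

## Scenario presets and their parameter choices

Demography was set once to reproduce the observed *scales* of the
empirical system: `Ne = 2e5`, `mu = 4e-9`/site/generation (the mean
calibrated nuclear rate, one generation per year) give
`theta = 0.0032`, matching observed pi of 0.002–0.005; `T_split = 8e5`
generations (the nuclear divergence-time estimate) gives isolation
D~XY~ ≈ 0.0096, matching observed 0.008–0.013.

* `scenario_semi_permeable()`: background loci exchange migrants at
  `m = 2.5e-6` (`4*Ne*m = 2`, the textbook strong-gene-flow regime in
  which unprotected loci are substantially homogenized); barrier loci
  have migration shut off. Prediction: barrier loci high in **both**
  F~ST~ and D~XY~.
* `scenario_no_flow_sweeps()`: migration zero everywhere; "barrier"-
  category loci instead get a sweep-like multiplier of 0.25 on the
  daughter-species Ne (the ancestral size is untouched — a recent sweep
  cannot reach back into the ancestor). Prediction: F~ST~ elevated
  through reduced `Hw`, D~XY~ unchanged.

Both presets use 48 loci (12 per linkage-by-category cell, matching the
study's locus count) over 24 individuals (12 per species across 4
population labels) at 3 kb per locus; locus count, not individual count,
drives the power of the category contrasts. `scenario_study_scale()`
reproduces the full empirical design — 48 loci split 27 X / 21 autosomal
with barrier loci concentrated on the X, 96 individuals (12 per
population), ~5 kb loci — for users who want the exact shape of the
original panel.

The sweep is a local Ne multiplier rather than an explicit selective
trajectory: one parameter produces the diversity-reduction signature that
matters for the F~ST~/D~XY~ contrast. Recombination *within* a locus is
deliberately absent (loci are single gene trees, as the IM preparation
assumes); four-gamete conflicts for testing the trimmer are produced by
concatenating independent gene trees.

## What passing tests do and do not show

The simulator reproduces the statistical structure the analysis assumes:
site-frequency statistics, hemizygous X dosage, category contrasts,
pileup noise. It does not emulate alignment error, indel polymorphism,
paralogy, within-species population structure, linkage between loci, or
selection acting during the sampled history. Green tests therefore
validate the *estimators and the decision logic*, not the biological
conclusions one would draw from any particular empirical dataset.

# Numerical choices and degenerate inputs

* Statistics are flagged `NA` when undefined (empty usable set, `n < 2`,
  `S = 0`, `Hb = 0`), never silently zeroed; category tests drop `NA`
  loci per statistic and skip empty cells with a warning.
* Permutation p-values can never be 0 (exact enumeration includes the
  identity; Monte-Carlo uses add-one). Ties between a permuted and the
  observed statistic count as extreme — the validity-preserving
  convention. Because a permuted median is an order statistic of the
  pooled values, exact ties have positive probability for the median
  statistic on small samples, making the test slightly conservative
  (empirical null rejection ~0.04 at a nominal 0.05 with two groups of
  15); the difference-of-means option is tie-free on continuous data.
* BCa `z0` is clamped away from infinite values at `1/(2B)` mass;
  all-equal bootstrap distributions short-circuit to a flagged point
  interval.
* Coordinates are 0-based half-open internally, 1-based inclusive in all
  user-facing tables.
* Four-gamete tie-break: leftmost window; block compatibility is
  re-checkable by direct pair scan.
* Test problem sizes (alignment sizes, replicate counts, permutation
  counts) are scaled to keep the default suite fast while leaving
  Monte-Carlo bands at three standard errors; the acceptance script uses
  the full 10,000 permutations of the original analysis.

# Known limitations

* The trimmer never deletes sequences, so its blocks can be shorter than
  those of the reference tool on the same data.
* The pooled-total F~ST~ variant is a Gst-style denominator, not a exact
  re-implementation of any specific desktop-software version.
* Calibration assumes the mitochondrial anchor rate; all absolute times
  inherit that assumption.
* The simulator's "populations" are labels; datasets with real
  within-species structure will show higher variance than the generator's
  replicates suggest.

# A worked run

```{r, eval = FALSE}
library(hzscan)
cfg <- pipeline_config(
  output_dir = "run1",
  simulate = list(scenario = "semi_permeable", n_per_cell = 12),
  seed = 1, n_perm = 10000)
manifest <- run_pipeline(cfg)
read.delim(file.path("run1", "summary.tsv"))
```

The `summary.tsv` table has one row per contrast with F~ST~ and D~XY~
medians for both groups, cell sizes and permutation p-values; the long
`comparison.tsv` adds pi and Tajima's D per species. `manifest.json`
records the config snapshot, input digests, stage seeds and all warnings.
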