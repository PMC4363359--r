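---
title: "Pooled amplicon mutation screens: model, simulator and caller"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled amplicon mutation screens: model, simulator and caller}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscreen)
library(dplyr)
```

## The screening problem

Reverse-genetics screens of chemically mutagenized populations (TILLING)
must find which one of hundreds of individuals carries a point mutation in a
gene of interest. Sequencing every individual separately is wasteful when
mutations are rare; `poolscreen` implements the pooled alternative: each
individual's DNA enters exactly three pools — one per plate (dimension A),
one per plate column (B), one per plate row (C) — and pooled amplicons are
sequenced once, with a pool-specific barcode attached by a second PCR step.
A mutation present in one individual then surfaces as a coordinated
low-frequency allele in the three pools that intersect at that individual's
well.

With eight 96-well plates the design needs only `8 + 12 + 8 = 28` libraries
for 768 individuals. Membership arithmetic follows directly: plate and row
pools hold `8 x 12 = 96` individuals, column pools `8 x 8 = 64`, and
pairwise intersections contain `n_rows`, `n_cols` or `n_plates` wells —
facts the test suite asserts by full enumeration.

## Dilution arithmetic

Pooling is only sound if every individual contributes enough template
molecules that allele sampling in PCR is not limiting. With mass `m` (ng)
per individual and a diploid (2C) genome mass `g` (pg), one individual
contributes `m * 1000 / g / pool_size` genome copies:

```{r}
copies_per_allele(10, 0.764, 64)
copies_per_allele(10, 0.764, 96)
```

Both values sit far above the ~40-copy level usually treated as the floor
below which copy-number fluctuation between individuals threatens
detection. The 2C picogram value is used directly as the per-genome mass
(no further factor of two at the allele level): that is the arithmetic the
copies-per-allele convention in this field uses, and the one these printed
values reproduce.

The expected pool allele frequency of a single carrier is pure dosage: a
pool of `n` diploid individuals carries `2n` alleles, so one heterozygous
carrier sits at `1/(2n)` (~0.52% at `n = 96`) and a homozygous carrier at
`1/n` (~1.04%). These are the signals the caller must separate from the
platform's ~0.1% substitution error. `molecules_per_microliter()` converts
a molar library concentration physically (26 pM = 1.566e7 molecules/uL;
note that library-preparation guides sometimes print 15.5e6 for this
concentration, which the physical conversion does not reproduce).

## What the simulator emulates

`plant_mutations()` draws mutations per individual and amplicon from a
Poisson distribution with mean `density x length`, with `density`
defaulting to the canonical EMS figure of one mutation per 300 kb. A
fraction `ems_fraction = 0.99` of mutations are canonical alkylation
transitions (G>A or C>T at a G/C site); zygosity is homozygous with
probability 1/3, the expected segregation among selfed M2 carriers (2 HET :
1 HOM). Explicit mutation lists are accepted for controlled experiments.

`simulate_counts()` produces per-pool allele-count tables directly:

* **Coverage.** Depth per pool and amplicon is lognormal with mean 3000 and
  CV 0.5 — pools receive visibly unequal read shares in practice — and the
  final 10% of positions decay linearly to half depth, emulating incomplete
  3' extensions. Both knobs are in `coverage_model()`.
* **Substitution error.** Mean per-base rate 0.001 (the rate reported for
  the sequencing technology), with per-type multipliers defaulting to 2.0
  for the G>A and T>C transitions and 0.8 for the other ten types, so the
  mean multiplier is exactly 1. The 2x elevation reflects the qualitative
  observation that these transitions carry the highest substitution noise,
  visible above a 0.1% plotting floor and occasionally reaching the 0.3%
  detection point; a much larger multiplier would make random error sit at
  the operating point routinely rather than occasionally. Each run redraws
  every type's rate from a truncated normal with SD `0.4 x rate`
  (dispersion reports of 26-56% of the mean motivate the midpoint).
* **Homopolymer indels.** Positions inside runs of three or more identical
  bases receive spurious insertion/deletion observations at five times the
  mean substitution rate; elsewhere the indel rate is 0.0005. The in-run
  factor is a configurable stand-in — flow-based sequencing is known to
  concentrate indel error in homopolymers, but no quantitative rate is
  established — and the downstream homopolymer filter removes these calls
  regardless.
* **Sampling.** `"sampled"` mode draws binomial counts; `"expected"` mode
  writes rounded expectations and is fully deterministic, which gives the
  tests a closed-form oracle. Base plus indel counts sum exactly to depth.

`simulate_reads()` emits the same screen as FASTQ, with reads laid out
`barcode + universal tag + forward primer + target + revcomp(reverse
primer) + revcomp(trP1)`, ~50 bp primer-dimer junk reads at a configurable
fraction (default 20%, consistent with roughly half of raw reads failing to
map in practice), 3'-truncated incomplete extensions, and Sanger-scaled
qualities. Two deliberate simplifications: sequencing errors are applied to
the target segment only (barcode, tag, primer and adapter copies are
error-free, so demultiplexing and trimming tolerances are exercised by
dedicated unit fixtures rather than by the generator), and no GC- or
locus-dependent amplification bias is modelled (observed in practice but
unparameterized). Passing tests therefore demonstrate correctness of the
pipeline's logic under calibrated noise, not robustness to every artifact
of real libraries.

## Read processing

`demultiplex()` assigns a read to a pool only when its prefix matches
exactly one barcode within `max_mismatch` (default 0: losing a read is
cheaper than mis-pooling it). `trim_reads()` strips the fixed two-step PCR
layout and rejects inserts shorter than 30 bp, which removes primer-dimer
artifacts. `align_to_amplicons()` aligns each insert to every reference
with match +1, mismatch -2, gap -3 — the classic read-mapper cost scheme
(mismatch cost 2, insertion/deletion cost 3) — accepting alignments with at
least 80% of the read aligned at 80% identity, and breaking exact ties by a
seeded uniform choice (non-specific reads map randomly). Alignment is
*local* on both sequences: read-side clipping is what makes the
aligned-length fraction a meaningful gate (a chimeric or adapter-laden read
clips to its genuine segment and is rejected when that segment is under
80%), and reference-side locality is natural for amplicon mapping. Gap
costs are linear; the insertion and deletion costs must be equal.

`pileup()` then counts alleles per reference position under the standard
neighbourhood quality filter: a base contributes only if its own quality is
at least 20, the mean quality within +-5 read bases is at least 15, and at
most 5 gaps+mismatches fall in that window; indels are tallied at their
left-flanking reference position. With maximal qualities and error-free
reads, pileup reproduces expected-mode count simulation exactly — the
cross-module consistency test.

## The SD-band caller

`frequency_table()` reports, for positions with coverage >= 100, every
non-reference allele at frequency >= 0.1% (at most 4 alleles per pool and
position; denominator is base coverage, indels excluded).
`filter_homopolymer_indels()` removes indel variants inside or adjacent to
reference homopolymer runs >= 3 — the platform's dominant artifact —
without ever touching substitutions.

`detect_outlier_pools()` is the heart of the caller. For each (amplicon,
position, substitution) it computes the mean and standard deviation of the
frequency across **all** pools of the scheme (absent pools count as zero)
and flags a pool when three gates pass: coverage >= 500, frequency >= 0.5%,
and z-score within the band `[2, 10]`. Below the band a pool is
indistinguishable from noise; above it the signal is treated as a
systematic artifact (recurrent mismapping, homopolymer bleed-through)
rather than a one-individual allele, since even a homozygous singleton
cannot push z much past ~3 under this formula. When the SD is zero the
z-score is reported as an infinite sentinel and the frequency gate alone
decides. `call_candidates()` groups flagged pools per variant, deconvolves
them through the scheme (union within a dimension, intersection across
dimensions), and assigns ordinal confidence tiers: 99 when all three
dimensions intersect, 85 for a two-dimensional intersection (the fallback
where the whole intersection is re-sequenced), 75 for a single pool. The
tiers are labels of deconvolution resolution, not calibrated probabilities:
the screening script they mirror reported three grades whose exact
computation is not public.

Two properties of this formula deserve emphasis, both consequences of
including the scored pool (and, for a real carrier, its two sibling pools)
in the mean and SD:

* The maximum attainable z with `n` pools is `(n-1)/sqrt(n)`, about 5.1 for
  28 pools. The upper cutoff of 10 therefore never excludes anything under
  the default scoring; it becomes active in leave-one-out mode
  (`caller_config(loo = TRUE)`), where a gross artifact shoots far past 10
  while true carriers stay inside the band.
* A heterozygous singleton elevates three pools at once, inflating the SD
  roughly twofold, so its carrier z-scores centre near the lower cutoff of
  2 — and its expected pool frequency (0.52% in a 96-pool) sits exactly at
  the 0.5% gate. Tier-99 recovery of heterozygous singletons at 3000x mean
  coverage is therefore *partial by design of the thresholds*: in the
  package's own 50-replicate benchmark only about a fifth of planted HET
  singletons resolve to the exact individual at tier 99, while the
  majority surface at tier 85 through two intersecting pools — mirroring
  the screening practice of following up two-pool intersections and
  merging technical replicates (`merge_flag_tables()` unions flags across
  replicates before deconvolution precisely because single replicates
  often flag complementary pool subsets). Homozygous carriers, at twice
  the frequency, resolve far more reliably.

We deliberately did not replace the formula with a more powerful detector
(leave-three-out, robust MAD scaling, or binomial likelihoods): the SD band
is the published procedure this package re-implements, and its operating
characteristics — including the HET marginality just described — are part
of what the simulator is for. The alternatives remain available as
configuration (`loo`) or future work.

## Numerical and design choices

* Pool ids are `A1..`, `B1..`, `C1..` (plate, column, row), 1-based, as in
  the original design; schemes may carry unoccupied wells, and pools are
  computed over occupied wells only.
* When several pools of one dimension are flagged for one variant,
  deconvolution unions within the dimension before intersecting across
  dimensions and marks the result ambiguous when more than one well
  survives — two independent mutants in one run stay visible.
* Expected-mode counts are rounded expectations, so closed-form fractions
  are exact only when coverage divides the dosage denominator; tests pin
  exactness at such coverages (e.g. 1920x for 1/192) and rounding
  behaviour otherwise (52 alt reads for a homozygous singleton in a
  96-pool at 5000x).
* Barcodes are generated (length 10, pairwise Hamming distance >= 3,
  homopolymer runs <= 3, greedy randomized search under a seed) rather
  than copied from any published set, which is not available.
* Primer QC uses unified nearest-neighbour thermodynamics (50 mM
  monovalent salt, 250 nM primer) with the screening design rules: length
  19-21 nt, Tm 59-61 C, >= 2 G/C among the five 3'-terminal bases,
  homopolymer runs <= 3. The Tm model is not the Primer3 implementation,
  so verdicts are advisory; secondary-structure (hairpin/dimer) free-energy
  screening is not implemented — the published threshold is ambiguous in
  sign and nothing downstream consumes it.
* All randomness flows through explicit seeds (`withr::with_seed`), so
  identical configurations yield byte-identical artifacts; every written
  table carries a provenance header with package version, stage and seed.

## Benchmark scales

The test suite simulates full 28-pool screens with two 150 bp amplicons and
50 seeded replicates for the recovery and false-positive benchmarks, 100
replicates for the 96-pool heterozygous spike-in (median observed frequency
~0.7%, comfortably above the 0.3% operating point), and 300 replicates for
Monte-Carlo means. These sizes give stable acceptance statistics while
keeping a full run of the suite in the minutes range; all of them are
package choices and can be scaled up freely in user code.

## Known limitations

* No flowgram-level signal simulation; homopolymer error is modelled at
  the count level only.
* No amplification bias, no polyclonal artifacts, no strand-specific
  error.
* The caller scores each substitution type independently and does not
  model joint evidence across positions (e.g. haplotypes) or across
  replicate runs beyond flag unioning.
* Amino-acid consequence annotation is out of scope; candidates are
  reported at the nucleotide level (TSV and VCF 4.2).
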