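---
title: "Tracking enrichment in in-vivo SELEX campaigns with selextrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking enrichment in in-vivo SELEX campaigns with selextrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selextrack)
```

## The problem

In-vivo SELEX selects tissue-targeting aptamers by injecting a random
single-stranded DNA library into a tumour-bearing animal, recovering the
molecules retained by the tumour, amplifying them, and repeating for about
ten cycles. Next-generation sequencing of every cycle turns the campaign into
a time series of sequence populations, and the informatics questions are:
is the library enriching; which sequences are being selected; and are they
tumour-associated rather than simply cleared slowly or amplified well?

`selextrack` covers that pipeline end to end at desk scale: FASTQ ingest and
random-region extraction, per-cycle population metrics, per-sequence
trajectories and candidate ranking, a tumour/kidney partition readout, a
fully synthetic campaign generator for validation, and the two quantitative
assays that accompany such campaigns (planar fluorescence ratios and qPCR
standard curves).

## Library design and read anatomy

The default design is an 80-nt library: an 18-nt 5' constant flank
(`GCTGTGTGACTCCTGCAA`), a 43-nt random region, and a 19-nt 3' constant flank
given as the reverse complement of the reverse primer
(`GGAGACAAGATACAGCTGC`). Sequencing is 75-bp single-end, so the 3' flank is
only ever partially observed. Extraction therefore anchors on the 5' flank —
searched over the first three start positions to absorb up to 2 nt of
synthesis slippage, with up to 2 mismatches on the 18-mer — and validates the
3' flank only over the observed overlap (at least 8 bases, at most 1
mismatch, by default). Regions containing `N` are discarded rather than
corrected: for copy-number statistics, counting integrity matters more than
yield. Rejections are categorised (`no_fw`, `short`, `bad_rv`,
`ambiguous_base`) so ingest loss is auditable.

Sample indexes are taken to be 6-nt 5' prefixes; the bundled default set of
12 indexes has pairwise Hamming distance of at least 3, so demultiplexing
with one tolerated mismatch is provably unambiguous, and any index table
violating the distance condition is rejected outright. Other index layouts
are configuration upstream of the package, not code.

## Population metrics

For each cycle's counted pool the package computes:

* **Unique-sequence fractions.** "Unique sequences" is genuinely ambiguous in
  informal use: it can mean distinct sequences over total copies, or
  singletons over distinct sequences. Both are implemented
  (`unique_fraction(pool, mode)`); `distinct` is the default used for
  diversity trajectories. Both fall as a selection enriches.
* **Per-position nucleotide composition**, weighted by copies (describing
  the sequenced population, the default) or by distinct sequences
  (describing the sequence space). Columns always sum to 1.
* **Copy-number bins** at the fixed decade edges ≤10, 11–100, 101–1000,
  1001–10000, >10000, with boundary values in the lower bin; both distinct
  counts per bin and each bin's share of total copies are reported, the
  latter being the clearest enrichment signal (the top bin's share grows as
  winners take over).
* **Cross-library overlap** as shared distinct sequences over a configurable
  denominator (union by default — a reported overlap without a stated
  denominator should be recomputed under all three).

Per-sequence **trajectories** collect copies and frequencies across cycles
and fold changes between consecutive cycles. Folds are computed on
frequencies, not raw copies, so sequencing-depth differences between cycles
cancel; a pseudocount of 0.5 copies keeps folds finite when a sequence is
absent from the earlier cycle. Frequencies themselves are reported without
pseudocount.

## Candidate selection

Candidates are collected on two criteria: final-cycle frequency and
amplification-fold profile. Sequences above the 0.5% final-frequency
threshold form the `abundant` track, ranked by frequency. The remaining
sequences join the `low_frequency` track when their log2-fold profile has
cosine similarity of at least 0.8 to the centroid profile of the top 10
abundant sequences — a scale-free comparison, so a sequence enriching in
parallel at 1/1000 the abundance scores exactly like the winners — and when
they show net enrichment over the campaign (geometric-mean fold ≥ 1).

The net-enrichment condition deserves a note, because the obvious
alternative — requiring the final transition's fold to be ≥ 1 — fails in a
way the simulator exposes crisply. Once a handful of strong binders
saturate the pool, every other truly selected sequence is necessarily
declining in relative frequency (competitive exclusion, compounded by
per-species PCR-gain differences); demanding a final fold ≥ 1 excludes
precisely the crowded-out binders the low-frequency track is meant to
rescue. Averaging enrichment over the whole campaign keeps those while
still screening out background that only ever fades. All ties are broken
lexicographically, so candidate lists are deterministic.

The kidney channel complements the ranking: `tumour_kidney_ratio()` compares
a sequence's regularised frequency in the tumour pool with the matched
kidney pool of the same cycle. The kidney is the dominant clearance route
for ssDNA of this size, so ratios below 1 flag clearance-biased sequences;
a sequence absent from both pools is reported as ratio 1 with an
`uninformative` flag rather than a fabricated number.

## The synthetic campaign generator

The simulator exists so every downstream stage can be validated against
ground truth. Each species carries a tumour selection coefficient
`s ~ Normal(0, sigma_s)` acting as capture weight `w = exp(s)`, a kidney
clearance weight `k ~ LogNormal(0, 0.5)`, and a PCR efficiency
`e ~ Uniform(0.8, 1)`. One cycle is: multinomial injection from the current
pool; per-molecule partition into tumour (probability
`capture_fraction * w / mean(w)`), kidney (`kidney_fraction * k / mean(k)`)
or loss, with joint rescaling when the two probabilities would exceed 1 —
capture saturates for extreme binders; PCR amplification of the tumour
fraction by `(1 + e)^pcr_cycles` with multiplicative log-normal noise
(sd 0.05) and stochastic rounding; and a multinomial sequencing draw with
per-base substitution errors (rate 0.001, single substitution per erroneous
read, which at that rate covers essentially all of them). Molecule counts
are conserved across the partition at every round, and the sequenced pool
is the template for the next cycle. The kidney pool is a pure observation
channel: raw partition counts, neither amplified nor subsampled.

Default scale is deliberately desk-sized: 10^4 species (full 10^15 starting
diversity is out of reach and out of scope), an injection schedule
proportional to the wet protocol's 5, 2, 1, 0.5, then 0.1 nmol with
4×10^6 molecules per nmol, sequencing depths around 10^5 (the low end of a
real campaign's per-cycle yields, scaled down), capture fraction 0.1 and
kidney fraction 0.3. `pcr_cycles = 6` keeps per-species amplification bias a
real but non-dominant force relative to selection — large enough to
reproduce the caveat that abundance partly reflects amplifiability, small
enough that selection remains the main signal. All randomness flows from
one integer seed; identical seeds give byte-identical campaigns, and
`run_campaign()` can emit its tumour pools as indexed 75-bp FASTQ so the
ingest path can be tested end to end (with error rate 0, ingest reproduces
the simulated pools exactly).

What the simulator does *not* emulate: pharmacokinetics beyond a single
capture/clearance draw, spatial tissue structure, sequence-dependent
amplification chemistry, quality-score structure in reads, and indel
errors. Passing tests therefore demonstrate the correctness of the
analytics under a plausible generative model, not performance on any
particular wet campaign.

## Estimating selection coefficients

`estimate_selection_coefficients()` fits, per sequence, the least-squares
slope of log frequency against cycle over the cycles where the sequence was
observed, and centres by the mean slope so estimates are relative
fitnesses. By default each cycle is weighted by the sequence's copy number
there — the approximate inverse variance of a log frequency estimated from
counts — which matters: unweighted slopes let the noisiest (low-count, late)
cycles dominate and visibly degrade rank recovery. The estimator cannot, in
principle, separate tumour capture from per-species PCR gain using tumour
trajectories alone (both act as constant per-round multipliers); it
estimates their sum, which is also the biologically honest reading of an
enrichment slope. On simulated campaigns (1000 species, selection sd 0.5,
depth 10^6, 10 rounds) the rank agreement between true and estimated
coefficients is about 0.91 despite that confound.

## Imaging and qPCR quantification

The planar-fluorescence module implements the standard semi-quantitative
protocol: subtract the camera's intrinsic background (scalar or per-pixel —
acquisitions differ, both are accepted), clip at zero, normalise to a common
exposure time, subtract the pre-injection autofluorescence ROI mean from the
post-injection mean under the identical mask, and divide tumour by
reference-zone means. A non-positive reference mean yields a flagged `NA`
ratio, never a silent infinity — by the same logic, comparing an image with
itself gives a flagged result rather than 0/0. Ex-vivo organ ratios
(tumour/muscle) use the same path without a pre-injection image. Group
comparisons use pairwise t-tests with one pooled SD across all groups
(the one-way-ANOVA residual SD, `N - k` degrees of freedom), which reduces
to the classic pooled two-sample test for two groups; a zero pooled SD with
unequal means is flagged degenerate instead of reporting a spurious
p-value. The synthetic fixture generator plants a Gaussian tumour blob over
a diffuse circulating-probe level so the constructed ratio is known in
closed form.

The qPCR module fits Cq against log10 quantity over a standard dilution
series (duplicates averaged per quantity before fitting — the convention
when standards are run in duplicate), reports amplification efficiency
`10^(-1/slope) - 1`, flags non-negative slopes invalid, and inverts the
curve for unknowns. Stability series are expressed as percent of the
time-zero quantity; values above 100% are reported but flagged, since they
indicate quantification noise rather than synthesis. Library arithmetic uses
fixed average residue masses (A 313.21, C 289.18, G 329.21, T 304.20 Da)
with a 61.96 Da terminal correction; the correction convention varies
between references, but at whole-kDa precision the choice is immaterial —
an equimolar 80-mer is ~24.7 kDa naked and ~35.7 kDa with an 11 kDa PEG,
i.e. below and at the renal filtration threshold respectively.

## Numerical conventions and degenerate inputs

* Pool ranks break count ties lexicographically; candidate lists break
  similarity and frequency ties lexicographically — all outputs are
  deterministic given inputs.
* Copy counts are stored as doubles (post-PCR counts overflow 32-bit
  integers) but are validated to be positive integers.
* Empty pools are constructible and serialisable, but population metrics on
  them raise errors rather than returning NaN.
* The optional Hamming denoiser (`cluster_by_hamming`, off by default)
  merges a sequence into a ≥10-fold more abundant neighbour within distance
  1, processing parents in descending pre-merge count order; ratio checks
  use pre-merge counts so the outcome is order-independent. It is a
  transparent, quadratic-cost stand-in for proprietary pattern-grouping
  tools, not a reproduction of any of them.
* Extinction of the simulated tumour compartment raises a descriptive error
  (suggesting a higher capture fraction) instead of propagating empty pools.

## Validation suite sizes

The test suite validates every counting operation against brute-force
oracles on instances of up to ~10^3 elements, the simulator against a
closed-form two-species replicator recursion and 50-replicate neutrality
checks, parameter recovery at 1000 species × depth 10^6 × 10 rounds, planted
winner recovery at 10^4 species, and end-to-end FASTQ ingest at a few
thousand reads per cycle. These sizes were chosen so the whole suite runs in
well under a minute of compute per module while leaving the statistical
assertions comfortable margins.

## Known limitations

* Paired-end merging, quality-based trimming and genome alignment are out of
  scope; reads are taken as delivered.
* The candidate-profile similarity rule is a declared operationalization of
  "enrichment profiles similar to the most abundant sequences"; other
  reasonable definitions (correlation of log frequencies, dynamic time
  warping) would rank borderline candidates differently.
* Kidney pools are modelled as raw partition counts; a real campaign
  amplifies and sequences them too, adding noise the simulator does not
  represent.
* The selection-coefficient estimator ignores drift-induced autocorrelation
  within a trajectory; its centring also assumes most sequences are close
  to neutral, which fails if a campaign is dominated by a few species from
  the start.
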