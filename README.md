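# selextrack

Enrichment analytics for in-vivo SELEX aptamer campaigns.

In-vivo SELEX injects a random single-stranded DNA library into a
tumour-bearing animal, recovers the molecules retained by the tumour,
amplifies them, and repeats for ~10 cycles. Sequencing every cycle yields a
time series of sequence populations; the analysis problem is to quantify
enrichment, rank candidate aptamers, and separate tumour selection from
renal clearance and PCR bias. `selextrack` implements that pipeline for
researchers running or re-analysing such campaigns:

* **Ingest** — phred+33 FASTQ reading, index demultiplexing with a
  provably unambiguous mismatch policy, extraction of the 43-nt random
  region between constant primer flanks (75-bp reads over an 80-nt
  amplicon, so the 3' flank is validated only over its observed overlap),
  and counted pools serialised as TSV/FASTA.
* **Enrichment metrics** — distinct/singleton fractions, per-position
  nucleotide composition, copy-number binning at decade edges
  (≤10 … >10000), cross-library overlap, and per-sequence frequency
  trajectories with pseudocount-regularised fold changes,
  `fold = [(c' + ½)/(T' + ½)] / [(c + ½)/(T + ½)]`.
* **Candidate selection** — an `abundant` track (final frequency > 0.5%)
  and a `low_frequency` track for sequences whose log2-fold profile has
  cosine similarity ≥ 0.8 to the centroid of the top abundant sequences
  with net enrichment over the campaign, plus tumour/kidney partition
  ratios to flag clearance-biased sequences.
* **Simulator** — a seeded generative model of a full campaign
  (multinomial injection, per-molecule tumour/kidney/loss partition with
  capture weight `exp(s)`, per-species-efficiency PCR with multiplicative
  noise, multinomial sequencing with substitution errors) emitting pools,
  ground truth, and optionally indexed FASTQ; and a depth-weighted
  estimator recovering relative selection coefficients from log-frequency
  slopes.
* **Imaging** — planar fluorescence ratio quantification (camera-background
  subtraction, exposure normalisation, pre-injection autofluorescence
  subtraction, tumour/healthy and tumour/muscle ROI ratios) and pairwise
  t-tests with a pooled SD across all groups.
* **qPCR** — standard-curve fitting on log10 quantity with amplification
  efficiency, quantification of unknowns, serum-stability percentages, and
  ssDNA library arithmetic (molecular weight, molecule counts per nmol).

## Worked example

Simulate an enriching 10-cycle campaign with 2000 species and analyse it:

```r
library(selextrack)

cfg <- sim_config(n_species = 2000, rounds = 10, molecules_per_nmol = 4e5,
                  sequencing_depth = 5e4, sigma_s = 0.8, seed = 42)
res <- run_campaign(cfg)

for (cy in c(1, 4, 7, 10))
  cat(sprintf("cycle %2d distinct fraction: %.3f\n", cy,
              unique_fraction(res$tumour_pools[[paste0("cycle", cy)]])))
#> cycle  1 distinct fraction: 0.082
#> cycle  4 distinct fraction: 0.053
#> cycle  7 distinct fraction: 0.024
#> cycle 10 distinct fraction: 0.015

round(bin_by_copy_number(res$tumour_pools$cycle10)$copy_share_per_bin, 3)
#>       <=10     11-100   101-1000 1001-10000     >10000
#>      0.048      0.014      0.019      0.126      0.793
```

The falling distinct fraction and the growth of the >10000-copy bin's share
are the classic signatures of enrichment. Candidate ranking combines both
tracks with the kidney readout:

```r
tr <- build_trajectories(res$tumour_pools, min_total_copies = 3)
cand <- select_candidates(tr, tumour_pool = res$tumour_pools$cycle10,
                          kidney_pool = res$kidney_pools$cycle10)
table(cand$track)
#>      abundant low_frequency
#>             7             6

head(cand[, c("track", "final_frequency", "profile_similarity",
              "tumour_kidney_ratio")], 3)
#>      track final_frequency profile_similarity tumour_kidney_ratio
#> 1 abundant          0.3003              0.979               0.732
#> 2 abundant          0.2818              0.988               1.901
#> 3 abundant          0.2112              0.994               1.007
```

A `tumour_kidney_ratio` below 1 marks a sequence more associated with the
clearance organ than the tumour. Because the campaign is simulated, the
estimator can be checked against ground truth:

```r
est <- estimate_selection_coefficients(tr)
m <- merge(est, res$species, by = "sequence")
cor(m$s, m$s_hat, method = "spearman")
#> [1] 0.81
```

(Rank agreement rises to ~0.91 at sequencing depth 10^6; residual loss
reflects the per-species PCR gain that tumour trajectories cannot separate
from selection.)

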