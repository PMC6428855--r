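#' Configuration of a synthetic in-vivo selection campaign
#'
#' Desk-scale generative model of a 10-cycle in-vivo selection: each cycle
#' injects a multinomial sample of the current library, partitions every
#' molecule between tumour capture, kidney clearance and loss, amplifies the
#' tumour fraction by per-species-efficiency PCR with multiplicative noise,
#' and sequences a multinomial subsample with per-base substitution errors.
#'
#' The injected-amount schedule mirrors the wet protocol — amounts
#' proportional to 5, 2, 1, 0.5 nmol for cycles 1–4 and 0.1 nmol for cycles
#' 5–10 — rescaled by `molecules_per_nmol` to desk scale. Sequencing depths
#' default to the low end of the real campaign's per-cycle yields, scaled
#' down.
#'
#' @param n_species Number of distinct starting sequences (default 10000).
#' @param rounds Number of selection cycles (default 10).
#' @param molecules_per_nmol Desk-scale molecules representing one nmol
#'   (default 4e6, so cycle 1 injects 2e7 molecules).
#' @param injected_copies Molecules injected per cycle; default
#'   `round(c(5, 2, 1, 0.5, rep(0.1, rounds - 4)) * molecules_per_nmol)`.
#' @param capture_fraction Expected fraction of injected molecules of an
#'   average-weight species retained by the tumour (default 0.1).
#' @param kidney_fraction Ditto for kidney clearance (default 0.3; the kidney
#'   is the major clearance route, so it exceeds tumour capture).
#' @param pcr_cycles PCR cycles per round (default 6).
#' @param pcr_noise_sd SD of the multiplicative log-normal PCR noise on the
#'   log scale (default 0.05).
#' @param sequencing_depth Reads per cycle; scalar or vector of length
#'   `rounds` (default 1e5).
#' @param per_base_error_rate Substitution rate per sequenced base
#'   (default 0.001).
#' @param random_len Random-region length (default 43).
#' @param sigma_s SD of tumour selection coefficients `s` (capture weight
#'   `w = exp(s)`); default 0.5.
#' @param k_meanlog,k_sdlog Log-normal parameters of kidney clearance weights
#'   (default 0 and 0.5).
#' @param e_range Range of per-species PCR efficiencies (default
#'   `c(0.8, 1)`).
#' @param seed Integer seed; all randomness in [run_campaign()] flows from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_species = 10000L, rounds = 10L,
                       molecules_per_nmol = 4e6,
                       injected_copies = NULL,
                       capture_fraction = 0.1, kidney_fraction = 0.3,
                       pcr_cycles = 6L, pcr_noise_sd = 0.05,
                       sequencing_depth = 1e5,
                       per_base_error_rate = 0.001,
                       random_len = 43L,
                       sigma_s = 0.5, k_meanlog = 0, k_sdlog = 0.5,
                       e_range = c(0.8, 1), seed = 1L) {
  stopifnot(n_species >= 2L, rounds >= 1L,
            capture_fraction >= 0, capture_fraction <= 1,
            kidney_fraction >= 0, kidney_fraction <= 1,
            per_base_error_rate >= 0, per_base_error_rate <= 1)
  if (is.null(injected_copies)) {
    nmol <- c(5, 2, 1, 0.5, rep(0.1, max(0L, rounds - 4L)))[seq_len(rounds)]
    injected_copies <- round(nmol * molecules_per_nmol)
  }
  stopifnot(length(injected_copies) == rounds)
  sequencing_depth <- rep_len(sequencing_depth, rounds)
  stopifnot(all(sequencing_depth >= 1e3))
  structure(
    list(n_species = as.integer(n_species), rounds = as.integer(rounds),
         injected_copies = injected_copies,
         capture_fraction = capture_fraction,
         kidney_fraction = kidney_fraction,
         pcr_cycles = as.integer(pcr_cycles), pcr_noise_sd = pcr_noise_sd,
         sequencing_depth = sequencing_depth,
         per_base_error_rate = per_base_error_rate,
         random_len = as.integer(random_len),
         sigma_s = sigma_s, k_meanlog = k_meanlog, k_sdlog = k_sdlog,
         e_range = e_range, seed = as.integer(seed)),
    class = "sim_config")
}

#' Draw the starting library and its ground-truth species parameters
#'
#' Each species is a distinct random sequence with one copy ("one copy of
#' each sequence"), a tumour selection coefficient `s ~ Normal(0, sigma_s)`
#' (capture weight `w = exp(s)`), a kidney clearance weight
#' `k ~ LogNormal(k_meanlog, k_sdlog)` and a PCR efficiency
#' `e ~ Uniform(e_range)`.
#'
#' @param config A [sim_config()]. The seed is applied here; call sites that
#'   manage the RNG themselves can pass `use_seed = FALSE`.
#' @param use_seed Set the RNG from `config$seed` (default TRUE).
#' @return List with `pool` (a [sample_pool()], all counts 1) and `species`
#'   (data.frame `sequence`, `s`, `k`, `e`).
#' @export
make_initial_pool <- function(config, use_seed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (use_seed) set.seed(config$seed)
  n <- config$n_species
  seqs <- random_sequences(n, config$random_len)
  species <- data.frame(
    sequence = seqs,
    s = stats::rnorm(n, 0, config$sigma_s),
    k = stats::rlnorm(n, config$k_meanlog, config$k_sdlog),
    e = stats::runif(n, config$e_range[1L], config$e_range[2L]),
    stringsAsFactors = FALSE)
  pool <- sample_pool(stats::setNames(rep(1, n), seqs),
                      library = "SIM", cycle = 0L, tissue = "tumour")
  list(pool = pool, species = species)
}

# n distinct random sequences of given length; collisions redrawn
random_sequences <- function(n, len) {
  draw <- function(m) {
    chars <- sample(c("A", "C", "G", "T"), m * len, replace = TRUE)
    apply(matrix(chars, nrow = m), 1L, paste, collapse = "")
  }
  seqs <- unique(draw(n))
  while (length(seqs) < n) {
    seqs <- unique(c(seqs, draw(n - length(seqs))))
  }
  seqs[seq_len(n)]
}

#' Simulate one selection cycle
#'
#' Steps, in order: (1) injection — multinomial draw of
#' `injected_copies[round]` molecules from the current pool frequencies;
#' (2) tissue partition — every injected molecule of species `i` goes to the
#' tumour with probability `capture_fraction * w_i / mean(w)`, to the kidney
#' with probability `kidney_fraction * k_i / mean(k)` (jointly rescaled if
#' they would sum past 1 — capture saturates for extreme binders), and is
#' otherwise lost; (3) PCR — tumour counts `c` become
#' `c * (1 + e_i)^pcr_cycles` with multiplicative log-normal noise, rounded
#' stochastically; (4) sequencing — a multinomial draw of
#' `sequencing_depth[round]` reads with per-base substitution errors.
#' Weight normalisation uses the mean over the full ground-truth species
#' table, so expectations do not drift as species die out.
#'
#' The sequenced tumour sample is both the observation for that cycle and the
#' template for the next cycle, matching a workflow in which the amplified
#' recovered material is carried forward. The kidney pool is the raw
#' partition outcome (the kidney channel is an observation only).
#'
#' @param pool Current [sample_pool()].
#' @param species Ground-truth data.frame from [make_initial_pool()].
#' @param config A [sim_config()].
#' @param round_index Cycle number, 1-based.
#' @return List with `tumour_pool` (sequenced, cycle = `round_index`),
#'   `kidney_pool`, and `conservation` (injected / tumour / kidney / lost
#'   molecule counts at the partition step).
#' @export
simulate_round <- function(pool, species, config, round_index) {
  stopifnot(inherits(pool, "sample_pool"), round_index >= 1L,
            round_index <= config$rounds)
  if (length(pool$counts) == 0L) stop("empty pool")
  idx <- match(names(pool$counts), species$sequence)
  known <- !is.na(idx)
  # error-derived sequences absent from the ground truth behave neutrally
  w <- rep(1, length(idx)); k <- rep(1, length(idx)); e <- rep(0.9, length(idx))
  w[known] <- exp(species$s[idx[known]])
  k[known] <- species$k[idx[known]]
  e[known] <- species$e[idx[known]]
  mean_w <- mean(exp(species$s))
  mean_k <- mean(species$k)

  # (1) injection
  injected <- as.numeric(rmultinom_big(config$injected_copies[round_index],
                                       pool$counts / pool$total_copies))

  # (2) partition
  p_t <- config$capture_fraction * w / mean_w
  p_k <- config$kidney_fraction * k / mean_k
  tot <- p_t + p_k
  over <- tot > 1
  p_t[over] <- p_t[over] / tot[over]
  p_k[over] <- p_k[over] / tot[over]
  tumour <- stats::rbinom(length(injected), injected, pmin(p_t, 1))
  kidney <- stats::rbinom(length(injected), injected - tumour,
                          ifelse(p_t < 1, pmin(p_k / (1 - p_t), 1), 0))
  lost <- injected - tumour - kidney
  if (sum(tumour) == 0L)
    stop("tumour pool went extinct at round ", round_index,
         "; consider a higher capture_fraction or larger injected_copies")

  # (3) PCR with per-species efficiency and multiplicative noise
  gain <- (1 + e)^config$pcr_cycles
  noise <- stats::rlnorm(length(tumour), 0, config$pcr_noise_sd)
  amp <- tumour * gain * noise
  amp <- floor(amp) + stats::rbinom(length(amp), 1L, amp - floor(amp))

  # (4) sequencing
  seqs <- names(pool$counts)
  pos <- amp > 0
  reads <- as.numeric(rmultinom_big(config$sequencing_depth[round_index],
                                    amp[pos] / sum(amp[pos])))
  seq_counts <- stats::setNames(reads, seqs[pos])
  seq_counts <- apply_sequencing_errors(seq_counts,
                                        config$per_base_error_rate)
  seq_counts <- seq_counts[seq_counts > 0]

  kid <- stats::setNames(as.numeric(kidney), seqs)
  kid <- kid[kid > 0]

  list(
    tumour_pool = sample_pool(seq_counts, library = pool$library,
                              cycle = round_index, tissue = "tumour"),
    kidney_pool = sample_pool(kid, library = pool$library,
                              cycle = round_index, tissue = "kidney"),
    conservation = c(injected = sum(injected), tumour = sum(tumour),
                     kidney = sum(kidney), lost = sum(lost)))
}

# multinomial draw that tolerates > .Machine$integer.max trials by chunking
rmultinom_big <- function(size, prob) {
  limit <- 2^31 - 1
  if (size <= limit) return(stats::rmultinom(1L, size, prob)[, 1L])
  out <- numeric(length(prob))
  while (size > 0) {
    take <- min(size, limit)
    out <- out + stats::rmultinom(1L, take, prob)[, 1L]
    size <- size - take
  }
  out
}

# substitute random bases in a counted read pool at the given per-base rate
apply_sequencing_errors <- function(counts, rate) {
  if (rate <= 0 || length(counts) == 0L) return(counts)
  L <- nchar(names(counts)[1L])
  depth <- sum(counts)
  # number of reads carrying at least one error
  p_read <- 1 - (1 - rate)^L
  n_err <- stats::rbinom(1L, depth, p_read)
  if (n_err == 0L) return(counts)
  # pick the erroneous reads without replacement from the physical molecules
  molecules <- rep.int(seq_along(counts), counts)
  origin <- if (n_err >= length(molecules)) molecules else
    sample(molecules, n_err)
  n_err <- length(origin)
  counts <- counts - tabulate(origin, nbins = length(counts))
  mutated <- names(counts)[origin]
  # conditional on >=1 error, almost all reads carry exactly one at
  # realistic rates; model a single substitution per erroneous read
  pos <- sample.int(L, n_err, replace = TRUE)
  cur <- substr(mutated, pos, pos)
  acgt <- c("A", "C", "G", "T")
  alts <- rbind(c("C", "A", "A", "A"),
                c("G", "G", "C", "C"),
                c("T", "T", "T", "G"))  # column b: the three bases != b
  alt <- alts[cbind(sample.int(3L, n_err, replace = TRUE), match(cur, acgt))]
  substr(mutated, pos, pos) <- alt
  extra <- table(mutated)
  all_seqs <- union(names(counts), names(extra))
  out <- stats::setNames(numeric(length(all_seqs)), all_seqs)
  out[names(counts)] <- counts
  out[names(extra)] <- out[names(extra)] + as.numeric(extra)
  out
}

#' Run a full synthetic selection campaign
#'
#' Chains [simulate_round()] over all configured cycles starting from
#' [make_initial_pool()]. Fully reproducible from `config$seed`. Optionally
#' emits one FASTQ file per cycle (indexed 75-bp reads assembled as
#' index + 5' flank + region + truncated 3' flank) for end-to-end ingest
#' tests.
#'
#' @param config A [sim_config()].
#' @param fastq_dir If non-NULL, write `cycle<r>.fastq` per tumour pool into
#'   this directory, using [default_index_table()] index `r + 1` for cycle
#'   `r` and the default library design.
#' @param species Optional ground-truth data.frame (`sequence`, `s`, `k`,
#'   `e`) overriding the randomly drawn one — e.g. to plant known
#'   high-selection species for recovery experiments. The starting pool is
#'   one copy of each sequence.
#' @return Object of class `sim_result`: list with `tumour_pools` (cycles
#'   0..rounds), `kidney_pools` (cycles 1..rounds), `species` (ground truth),
#'   `conservation` (rounds x 4 matrix) and `config`.
#' @export
run_campaign <- function(config, fastq_dir = NULL, species = NULL) {
  stopifnot(inherits(config, "sim_config"))
  init <- make_initial_pool(config)  # seeds the RNG
  if (!is.null(species)) {
    stopifnot(all(c("sequence", "s", "k", "e") %in% names(species)),
              nrow(species) == config$n_species)
    init <- list(
      pool = sample_pool(stats::setNames(rep(1, nrow(species)),
                                         species$sequence),
                         library = "SIM", cycle = 0L, tissue = "tumour"),
      species = species)
  }
  tumour_pools <- vector("list", config$rounds + 1L)
  kidney_pools <- vector("list", config$rounds)
  tumour_pools[[1L]] <- init$pool
  conservation <- matrix(NA_real_, nrow = config$rounds, ncol = 4L,
                         dimnames = list(NULL, c("injected", "tumour",
                                                 "kidney", "lost")))
  for (r in seq_len(config$rounds)) {
    res <- simulate_round(tumour_pools[[r]], init$species, config, r)
    tumour_pools[[r + 1L]] <- res$tumour_pool
    kidney_pools[[r]] <- res$kidney_pool
    conservation[r, ] <- res$conservation
  }
  names(tumour_pools) <- paste0("cycle", 0:config$rounds)
  names(kidney_pools) <- paste0("cycle", seq_len(config$rounds))
  result <- structure(
    list(tumour_pools = tumour_pools, kidney_pools = kidney_pools,
         species = init$species, conservation = conservation,
         config = config),
    class = "sim_result")
  if (!is.null(fastq_dir)) emit_campaign_fastq(result, fastq_dir)
  result
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %d species, %d rounds\n",
              x$config$n_species, x$config$rounds))
  invisible(x)
}

#' Write a campaign's tumour pools as indexed FASTQ
#'
#' Reads are 75 bp: a 6-nt sample index, the 18-nt 5' flank, the 43-nt
#' region, and the first 8 nt of the 3' flank. Qualities are uniform phred
#' 40. At most 12 pools can share the default index set.
#'
#' @param result A [run_campaign()] result.
#' @param dir Output directory (created if needed).
#' @param design A [library_design()]; the default 80-nt design.
#' @return Named character vector of written paths (by cycle), invisibly.
#' @export
emit_campaign_fastq <- function(result, dir,
                                design = default_library_design()) {
  stopifnot(inherits(result, "sim_result"))
  pools <- result$tumour_pools
  if (length(pools) > 12L)
    stop("default index set supports at most 12 pools")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  index_table <- default_index_table(length(pools))
  indexes <- names(index_table)
  paths <- character(length(pools))
  for (j in seq_along(pools)) {
    pool <- pools[[j]]
    seqs <- rep(names(pool$counts), pool$counts)
    rv_obs <- 75L - 6L - nchar(design$fw_flank) - design$random_len
    bases <- paste0(indexes[j], design$fw_flank, seqs,
                    substr(design$rv_flank_sense, 1L, rv_obs))
    reads <- data.frame(
      id = sprintf("sim_c%d_%06d", pool$cycle, seq_along(seqs)),
      bases = bases, stringsAsFactors = FALSE)
    paths[j] <- file.path(dir, sprintf("cycle%d.fastq", pool$cycle))
    write_fastq(reads, paths[j])
  }
  names(paths) <- names(pools)
  invisible(paths)
}

#' Deterministic replicator expectation of pool frequencies
#'
#' Noise-free expectation of the per-cycle frequency update: one round
#' multiplies each species' frequency by its capture weight `w = exp(s)`
#' times its PCR gain `(1 + e)^pcr_cycles` and renormalises. For two species
#' with gain ratio `lambda` this is the classic replicator recursion
#' `f' = f * lambda / (f * lambda + 1 - f)`.
#'
#' @param freqs Initial frequency vector (sums to 1).
#' @param s Selection coefficients (capture weights `exp(s)`).
#' @param e PCR efficiencies (default all equal, so PCR drops out).
#' @param pcr_cycles PCR cycles per round (default 0).
#' @param rounds Number of rounds.
#' @return Matrix `(rounds + 1) x n` of frequencies, row 1 = `freqs`.
#' @export
replicator_expectation <- function(freqs, s, e = rep(0, length(freqs)),
                                   pcr_cycles = 0L, rounds = 1L) {
  stopifnot(length(freqs) == length(s), abs(sum(freqs) - 1) < 1e-12)
  gain <- exp(s) * (1 + e)^pcr_cycles
  out <- matrix(NA_real_, nrow = rounds + 1L, ncol = length(freqs))
  out[1L, ] <- freqs
  f <- freqs
  for (r in seq_len(rounds)) {
    f <- f * gain
    f <- f / sum(f)
    out[r + 1L, ] <- f
  }
  out
}

#' Estimate relative selection coefficients from trajectories
#'
#' For every sequence with at least `min_cycles` cycles of nonzero frequency,
#' fits the least-squares slope of `log(frequency)` against cycle over those
#' cycles; the pool-mean slope is subtracted so the estimates are relative
#' fitnesses (a pure change of sequencing depth or shared PCR gain cancels).
#' With `depth_aware = TRUE` (the default) each cycle is weighted by the
#' sequence's copy number there, the approximate inverse variance of a
#' log-frequency from counted data — low-count cycles are the noisiest and
#' should not dominate the slope. Estimates conflate tumour selection with
#' residual per-species PCR-gain differences — exactly the ambiguity that
#' makes amplification bias a caveat when reading enrichment as binding.
#'
#' @param trajectories A [build_trajectories()] result.
#' @param depth_aware Weight cycles by observed copy number (default TRUE);
#'   FALSE gives the ordinary unweighted slope.
#' @param min_cycles Minimum nonzero cycles required (default 3).
#' @return data.frame with columns `sequence`, `s_hat` (centred slope),
#'   `slope` (raw slope) and `n_cycles`.
#' @export
estimate_selection_coefficients <- function(trajectories, depth_aware = TRUE,
                                            min_cycles = 3L) {
  stopifnot(inherits(trajectories, "selex_trajectories"), min_cycles >= 3L)
  freq <- trajectories$frequency
  copies <- trajectories$copies
  cycles <- trajectories$cycles
  nz <- freq > 0
  usable <- which(rowSums(nz) >= min_cycles)
  slope <- vapply(usable, function(i) {
    j <- which(nz[i, ])
    x <- cycles[j]
    y <- log(freq[i, j])
    w <- if (depth_aware) copies[i, j] else rep(1, length(j))
    xm <- sum(w * x) / sum(w)
    ym <- sum(w * y) / sum(w)
    sum(w * (x - xm) * (y - ym)) / sum(w * (x - xm)^2)
  }, numeric(1L))
  data.frame(sequence = trajectories$sequences[usable],
             s_hat = slope - mean(slope),
             slope = slope,
             n_cycles = rowSums(nz)[usable],
             stringsAsFactors = FALSE, row.names = NULL)
}
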