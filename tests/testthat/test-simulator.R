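test_that("initial pools are distinct, single-copy and reproducible from the seed", {
  cfg <- sim_config(n_species = 3, rounds = 1, molecules_per_nmol = 1e3,
                    sequencing_depth = 1e3, seed = 5)
  init <- make_initial_pool(cfg)
  expect_equal(length(init$pool$counts), 3)
  expect_true(all(init$pool$counts == 1))
  expect_equal(init$pool$total_copies, 3)

  init2 <- make_initial_pool(cfg)
  expect_identical(init, init2)

  cfg_big <- sim_config(n_species = 1e4, rounds = 1,
                        molecules_per_nmol = 1e3,
                        sequencing_depth = 1e3, random_len = 43, seed = 6)
  big <- make_initial_pool(cfg_big)
  seqs <- big$species$sequence
  expect_equal(length(unique(seqs)), 1e4)
  expect_true(all(nchar(seqs) == 43))
  expect_false(any(grepl("[^ACGT]", seqs)))
  expect_true(all(big$species$e > 0.5 & big$species$e <= 1))
  expect_true(all(big$species$k > 0))
})

test_that("identical seeds give byte-identical campaigns", {
  cfg <- sim_config(n_species = 100, rounds = 3, molecules_per_nmol = 1e4,
                    sequencing_depth = 5e3, seed = 9)
  expect_identical(run_campaign(cfg), run_campaign(cfg))
})

test_that("molecules are conserved across the tissue partition every round", {
  cfg <- sim_config(n_species = 200, rounds = 6, molecules_per_nmol = 2e4,
                    sequencing_depth = 5e3, seed = 10)
  res <- run_campaign(cfg)
  cons <- res$conservation
  expect_equal(cons[, "tumour"] + cons[, "kidney"] + cons[, "lost"],
               cons[, "injected"], ignore_attr = TRUE)
  expect_equal(unname(cons[, "injected"]), cfg$injected_copies)
})

test_that("a neutral campaign shows no systematic frequency drift", {
  # all species share s, k, e; replicate one round many times and check the
  # mean frequency change stays inside the sampling bound
  n <- 50
  n_rep <- 50
  delta <- matrix(NA_real_, n_rep, n)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_species = n, rounds = 1, molecules_per_nmol = 4e3,
                      sequencing_depth = 1e4, sigma_s = 0, k_sdlog = 0,
                      e_range = c(0.9, 0.9), pcr_noise_sd = 0,
                      per_base_error_rate = 0, seed = 500 + r)
    res <- run_campaign(cfg)
    f0 <- rep(1 / n, n)
    f1 <- res$tumour_pools$cycle1$counts[res$species$sequence]
    f1[is.na(f1)] <- 0
    delta[r, ] <- f1 / res$tumour_pools$cycle1$total_copies - f0
  }
  mean_delta <- colMeans(delta)
  f <- 1 / n
  inj <- 2e4
  var_one <- f * (1 - f) * (1 / inj + 1 / (inj * 0.1) + 1 / 1e4)
  bound <- 4 * sqrt(var_one / n_rep)
  expect_true(all(abs(mean_delta) < bound))
})

test_that("the deterministic replicator recursion gives the closed-form frequency", {
  # two species, gain ratio lambda = 2: f_r = f0 2^r / (f0 2^r + 1 - f0)
  out <- replicator_expectation(c(0.5, 0.5), s = c(log(2), 0), rounds = 3)
  expect_equal(out[4, 1], 8 / 9, tolerance = 1e-9)
  r <- 5
  f0 <- 0.2
  out <- replicator_expectation(c(f0, 1 - f0), s = c(log(3), 0), rounds = r)
  expect_equal(out[r + 1, 1], f0 * 3^r / (f0 * 3^r + 1 - f0),
               tolerance = 1e-12)
  # PCR gain enters the same way as selection
  out_pcr <- replicator_expectation(c(0.5, 0.5), s = c(0, 0),
                                    e = c(1, 0.5), pcr_cycles = 1, rounds = 1)
  expect_equal(out_pcr[2, 1], (2 / 1.5) / (2 / 1.5 + 1))
})

test_that("a species with strong clearance dominates the kidney relative to the tumour", {
  cfg <- sim_config(n_species = 40, rounds = 1, molecules_per_nmol = 2e4,
                    sequencing_depth = 1e4, sigma_s = 0, k_sdlog = 0,
                    per_base_error_rate = 0, seed = 12)
  init <- make_initial_pool(cfg)
  init$species$k[1] <- 30
  res <- run_campaign(cfg, species = init$species)
  target <- init$species$sequence[1]
  kid <- res$kidney_pools$cycle1
  tum <- res$tumour_pools$cycle1
  f_kid <- unname(kid$counts[target]) / kid$total_copies
  f_tum_raw <- tum$counts[target]
  f_tum <- if (is.na(f_tum_raw)) 0 else unname(f_tum_raw) / tum$total_copies
  expect_gt(f_kid, f_tum)
})

test_that("selection-coefficient estimates are unbiased for neutral species and exact on deterministic data", {
  # neutral: estimates hover near zero
  cfg <- sim_config(n_species = 100, rounds = 8, molecules_per_nmol = 1e5,
                    sequencing_depth = 1e5, sigma_s = 0, k_sdlog = 0,
                    e_range = c(0.9, 0.9), pcr_noise_sd = 0,
                    per_base_error_rate = 0, seed = 13)
  res <- run_campaign(cfg)
  tr <- build_trajectories(res$tumour_pools)
  est <- estimate_selection_coefficients(tr)
  se <- stats::sd(est$s_hat)
  expect_lt(max(abs(est$s_hat)), 5 * se)
  expect_lt(abs(mean(est$s_hat)), 1e-12)  # centred by construction

  # two-species deterministic trajectories doubling in ratio each cycle:
  # counts (2^j, 1) make the frequency ratio exactly 2^j
  pools <- lapply(0:4, function(j)
    sample_pool(c(AAAA = 2^j, CCCC = 1), cycle = j + 1))
  trd <- build_trajectories(pools, pseudocount = 0)
  estu <- estimate_selection_coefficients(trd, depth_aware = FALSE)
  diffu <- estu$s_hat[estu$sequence == "AAAA"] -
    estu$s_hat[estu$sequence == "CCCC"]
  expect_equal(diffu, log(2), tolerance = 1e-9)
  # the depth-weighted variant agrees closely on clean data
  estd <- estimate_selection_coefficients(trd)
  diffd <- estd$s_hat[estd$sequence == "AAAA"] -
    estd$s_hat[estd$sequence == "CCCC"]
  expect_equal(diffd, log(2), tolerance = 0.1)
})

test_that("error-free emitted FASTQ demultiplexes and extracts back to the exact pools", {
  fq_dir <- withr::local_tempdir()
  cfg <- sim_config(n_species = 80, rounds = 4, molecules_per_nmol = 4e3,
                    sequencing_depth = 2e3, per_base_error_rate = 0,
                    seed = 14)
  res <- run_campaign(cfg, fastq_dir = fq_dir)
  files <- list.files(fq_dir, pattern = "\\.fastq$", full.names = TRUE)
  reads <- do.call(rbind, lapply(files, read_fastq))
  out <- demultiplex(reads, default_index_table(5))
  expect_equal(unname(out$tally["undetermined"]), 0L)
  for (j in 0:4) {
    sample_id <- sprintf("S%02d", j + 1)
    ex <- extract_random_region(out$samples[[sample_id]]$bases)
    expect_false(anyNA(ex$region))
    rebuilt <- build_pool(ex$region, cycle = j, tissue = "tumour")
    expect_equal(rebuilt$counts,
                 res$tumour_pools[[paste0("cycle", j)]]$counts)
  }
})

test_that("an extinct tumour compartment raises a descriptive error", {
  cfg <- sim_config(n_species = 10, rounds = 1, molecules_per_nmol = 1e3,
                    injected_copies = 1e3,
                    capture_fraction = 0, kidney_fraction = 0.5,
                    sequencing_depth = 1e3, seed = 15)
  init <- make_initial_pool(cfg)
  expect_error(simulate_round(init$pool, init$species, cfg, 1),
               "extinct")
})
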