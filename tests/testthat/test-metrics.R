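test_that("unique-sequence fractions follow both definitions", {
  p <- sample_pool(c(AAAA = 1, CCCC = 2))
  expect_equal(unique_fraction(p, "distinct"), 2 / 3)
  expect_equal(unique_fraction(p, "singleton"), 1 / 2)

  all_singletons <- sample_pool(c(AAAA = 1, CCCC = 1, GGGG = 1))
  expect_equal(unique_fraction(all_singletons, "distinct"), 1)
  expect_equal(unique_fraction(all_singletons, "singleton"), 1)

  set.seed(21)
  counts <- random_pool_counts(50, 5000)
  p <- sample_pool(counts)
  expect_equal(unique_fraction(p, "distinct"), length(counts) / sum(counts))
  expect_equal(unique_fraction(p, "singleton"),
               sum(counts == 1) / length(counts))
  expect_error(unique_fraction(sample_pool(setNames(numeric(0),
                                                    character(0)))),
               "empty")
})

test_that("nucleotide composition honours copy and distinct weighting", {
  p <- sample_pool(c(ACG = 2, AAA = 1))
  by_copies <- nucleotide_composition(p, "by_copies")
  expect_equal(by_copies["A", 1], 1)
  expect_equal(by_copies["C", 2], 2 / 3)
  expect_equal(by_copies["A", 2], 1 / 3)
  expect_equal(by_copies["G", 3], 2 / 3)
  by_distinct <- nucleotide_composition(p, "by_distinct")
  expect_equal(by_distinct["C", 2], 1 / 2)
  expect_equal(by_distinct["A", 2], 1 / 2)
  expect_equal(colSums(by_copies), rep(1, 3), tolerance = 1e-9,
               ignore_attr = TRUE)

  # a uniform random pool should be flat at 0.25 within binomial error
  set.seed(22)
  seqs <- replicate(1e4, paste(sample(c("A", "C", "G", "T"), 43,
                                      replace = TRUE), collapse = ""))
  comp <- nucleotide_composition(build_pool(seqs))
  bound <- 5 * sqrt(0.25 * 0.75 / 1e4)
  expect_true(all(abs(comp - 0.25) < bound))

  set.seed(23)
  counts <- random_pool_counts(80, 2000)
  comp <- nucleotide_composition(sample_pool(counts))
  expect_equal(comp, oracle_composition(counts), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("copy-number bins put boundary values in the lower bin", {
  p <- sample_pool(c(AAAA = 10, CCCC = 11, GGGG = 100, TTTT = 101,
                     ACGT = 10000, TGCA = 10001))
  b <- bin_by_copy_number(p)
  expect_equal(unname(b$distinct_per_bin), c(1L, 2L, 1L, 1L, 1L))
  expect_equal(sum(b$copy_share_per_bin), 1, tolerance = 1e-9)

  single <- bin_by_copy_number(sample_pool(c(AAAA = 5)))
  expect_equal(unname(single$distinct_per_bin), c(1L, 0L, 0L, 0L, 0L))
  expect_equal(unname(single$copy_share_per_bin), c(1, 0, 0, 0, 0))
})

test_that("binning matches the brute-force oracle, also on merged pools", {
  set.seed(24)
  a <- random_pool_counts(100, 2e4)
  b <- random_pool_counts(100, 5e4)
  for (counts in list(a, b)) {
    got <- bin_by_copy_number(sample_pool(counts))
    exp <- oracle_bin(counts)
    expect_equal(unname(got$distinct_per_bin), exp$distinct)
    expect_equal(unname(got$copy_share_per_bin), exp$share)
  }
  # consistency under union: binning the merged counts directly
  merged <- c(a, b[setdiff(names(b), names(a))])
  shared <- intersect(names(a), names(b))
  merged[shared] <- a[shared] + b[shared]
  got <- bin_by_copy_number(sample_pool(merged))
  exp <- oracle_bin(merged)
  expect_equal(unname(got$distinct_per_bin), exp$distinct)
  expect_equal(unname(got$copy_share_per_bin), exp$share)
})

test_that("pool overlap counts shared distinct sequences over the chosen denominator", {
  a <- sample_pool(c(AAAA = 1, CCCC = 1))
  b <- sample_pool(c(CCCC = 5, GGGG = 2))
  expect_equal(pool_overlap(a, b, "union"), 1 / 3)
  expect_equal(pool_overlap(a, b, "A"), 1 / 2)
  expect_equal(pool_overlap(a, a, "union"), 1)
  expect_equal(pool_overlap(a, a, "B"), 1)

  set.seed(25)
  x <- sample_pool(random_pool_counts(60, 600))
  y <- sample_pool(random_pool_counts(60, 600))
  shared <- length(intersect(names(x$counts), names(y$counts)))
  expect_equal(pool_overlap(x, y, "union"),
               shared / length(union(names(x$counts), names(y$counts))))
})

test_that("trajectories report frequencies, and folds follow the pseudocount rule", {
  # hand-computed spreadsheet over three cycles, five sequences
  p1 <- sample_pool(c(AA = 2, CC = 4, GG = 2, TT = 1, AC = 1), cycle = 1)
  p2 <- sample_pool(c(AA = 8, CC = 1, GG = 1), cycle = 2)
  tr <- build_trajectories(list(p1, p2), pseudocount = 0)
  expect_equal(tr$frequency["AA", ], c(0.2, 0.8), ignore_attr = TRUE)
  expect_equal(tr$folds["AA", 1], 4)           # 2e-1 -> 8e-1
  expect_equal(tr$folds["CC", 1], (1 / 10) / (4 / 10))
  expect_equal(tr$frequency["TT", 2], 0)

  # absent-then-present stays finite with the default pseudocount
  tr05 <- build_trajectories(list(p2, sample_pool(c(TT = 5, AA = 5),
                                                  cycle = 3)))
  f_tt <- ((5 + 0.5) / (10 + 0.5)) / ((0 + 0.5) / (10 + 0.5))
  expect_equal(tr05$folds["TT", 1], f_tt)
  expect_true(all(is.finite(tr05$folds)))

  expect_error(build_trajectories(list(p2, p1)), "strictly increasing")
})

test_that("trajectory folds equal hand-computed frequency ratios on a simulated campaign", {
  cfg <- sim_config(n_species = 100, rounds = 4, molecules_per_nmol = 1e4,
                    sequencing_depth = 1e4, seed = 31)
  res <- run_campaign(cfg)
  tr <- build_trajectories(res$tumour_pools, pseudocount = 0.5)
  pools <- res$tumour_pools
  picks <- tr$sequences[round(seq(1, length(tr$sequences), length.out = 5))]
  for (s in picks) {
    for (j in seq_len(length(pools) - 1)) {
      c0 <- pools[[j]]$counts[s]; c0 <- if (is.na(c0)) 0 else unname(c0)
      c1 <- pools[[j + 1]]$counts[s]; c1 <- if (is.na(c1)) 0 else unname(c1)
      expected <- ((c1 + 0.5) / (pools[[j + 1]]$total_copies + 0.5)) /
        ((c0 + 0.5) / (pools[[j]]$total_copies + 0.5))
      expect_equal(unname(tr$folds[s, j]), expected, tolerance = 1e-12)
    }
  }
})

test_that("enrichment concentrates copies: distinct fraction falls over a selective campaign", {
  cfg <- sim_config(n_species = 500, rounds = 6, molecules_per_nmol = 4e4,
                    sequencing_depth = 2e4, sigma_s = 1, seed = 32)
  res <- run_campaign(cfg)
  d1 <- unique_fraction(res$tumour_pools$cycle1)
  d6 <- unique_fraction(res$tumour_pools$cycle6)
  expect_lt(d6, d1)
})

test_that("Hamming denoising merges low-count neighbours into abundant parents", {
  p <- sample_pool(c(AAAA = 100, AAAT = 2))
  out <- cluster_by_hamming(p, max_dist = 1, min_parent_ratio = 10)
  expect_equal(out$counts, c(AAAA = 102))

  p2 <- sample_pool(c(AAAA = 100, TTTT = 2))
  expect_equal(cluster_by_hamming(p2)$counts, p2$counts)

  set.seed(26)
  base <- random_pool_counts(40, 5000, len = 6)
  # sprinkle 1-mismatch children around the heavy sequences
  children <- setNames(numeric(0), character(0))
  for (s in names(base)[base > 50]) {
    ch <- strsplit(s, "")[[1]]
    ch[1] <- setdiff(c("A", "C", "G", "T"), ch[1])[1]
    child <- paste(ch, collapse = "")
    if (!child %in% names(base)) children[child] <- sample(1:3, 1)
  }
  counts <- c(base, children)
  got <- cluster_by_hamming(sample_pool(counts))$counts
  exp <- oracle_cluster(counts)
  exp <- exp[order(names(exp))]
  expect_equal(got, exp)
})
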