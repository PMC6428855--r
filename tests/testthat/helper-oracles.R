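# Independent brute-force oracles used across tests. Everything here is
# written as plainly as possible (explicit loops, no shared code with the
# package internals) so it can serve as a second opinion.

oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  sum(ca != cb)
}

# nearest-index scan: returns the sample id, or NA for undetermined
oracle_demux_one <- function(read, index_table, max_mismatch) {
  indexes <- names(index_table)
  len <- nchar(indexes[1])
  if (nchar(read) < len) return(NA_character_)
  prefix <- substr(read, 1, len)
  d <- vapply(indexes, function(ix) oracle_hamming(prefix, ix), numeric(1))
  best <- which.min(d)
  if (d[best] <= max_mismatch) unname(index_table[best]) else NA_character_
}

# exhaustive sliding-window extraction decision, mirroring the documented
# contract: best flank offset in 1..3, then region, 3' overlap, N check
oracle_extract_one <- function(read, design, max_mismatch_fw = 2,
                               min_rv_overlap = 8, max_mismatch_rv = 1) {
  fw <- design$fw_flank
  fw_len <- nchar(fw)
  best_off <- NA; best_mm <- Inf
  for (off in 1:3) {
    if (off + fw_len - 1 > nchar(read)) next
    mm <- oracle_hamming(substr(read, off, off + fw_len - 1), fw)
    if (mm <= max_mismatch_fw && mm < best_mm) { best_off <- off; best_mm <- mm }
  }
  if (is.na(best_off)) return(list(region = NA, reason = "no_fw"))
  start <- best_off + fw_len
  end <- start + design$random_len - 1
  if (end > nchar(read)) return(list(region = NA, reason = "short"))
  region <- substr(read, start, end)
  tail <- substr(read, end + 1, nchar(read))
  ov <- min(nchar(tail), nchar(design$rv_flank_sense))
  if (ov >= min_rv_overlap) {
    mm <- oracle_hamming(substr(tail, 1, ov),
                         substr(design$rv_flank_sense, 1, ov))
    if (mm > max_mismatch_rv) return(list(region = NA, reason = "bad_rv"))
  }
  if (grepl("N", region)) return(list(region = NA, reason = "ambiguous_base"))
  list(region = region, reason = NA)
}

oracle_bin <- function(counts) {
  distinct <- integer(5)
  copies <- numeric(5)
  for (cnt in counts) {
    b <- if (cnt <= 10) 1 else if (cnt <= 100) 2 else if (cnt <= 1000) 3 else
      if (cnt <= 10000) 4 else 5
    distinct[b] <- distinct[b] + 1L
    copies[b] <- copies[b] + cnt
  }
  list(distinct = distinct, share = copies / sum(counts))
}

oracle_composition <- function(counts, weighting = "by_copies") {
  seqs <- names(counts)
  L <- nchar(seqs[1])
  out <- matrix(0, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  total <- 0
  for (i in seq_along(seqs)) {
    w <- if (weighting == "by_copies") counts[[i]] else 1
    ch <- strsplit(seqs[i], "")[[1]]
    for (p in seq_len(L)) out[ch[p], p] <- out[ch[p], p] + w
    total <- total + w
  }
  out / total
}

oracle_cluster <- function(counts, max_dist = 1, min_parent_ratio = 10) {
  seqs <- names(counts)
  orig <- as.numeric(counts)
  ord <- order(-orig, seqs)
  parent <- seq_along(seqs)
  merged <- rep(FALSE, length(seqs))
  for (p in ord) {
    if (merged[p]) next
    for (q in seq_along(seqs)) {
      if (q == p || merged[q]) next
      if (oracle_hamming(seqs[p], seqs[q]) <= max_dist &&
          orig[p] >= min_parent_ratio * orig[q]) {
        parent[q] <- p
        merged[q] <- TRUE
      }
    }
  }
  out <- tapply(orig, parent, sum)
  setNames(as.numeric(out), seqs[as.integer(names(out))])
}

random_pool_counts <- function(n_species, total, len = 8) {
  seqs <- unique(replicate(n_species * 2, paste(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")))
  seqs <- seqs[seq_len(min(n_species, length(seqs)))]
  probs <- rexp(length(seqs))
  counts <- as.numeric(rmultinom(1, total, probs / sum(probs)))
  keep <- counts > 0
  setNames(counts[keep], seqs[keep])
}
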