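#' Unique-sequence fraction of a pool
#'
#' Two readings of "unique sequences" are in circulation and both are
#' provided: `distinct` is the number of different sequences divided by the
#' total copy number (the default, the usual library-diversity trajectory);
#' `singleton` is the share of distinct sequences seen exactly once.
#' Both decline as a selection enriches.
#'
#' @param pool A [sample_pool()].
#' @param mode `"distinct"` or `"singleton"`.
#' @return A fraction in `[0, 1]`.
#' @export
unique_fraction <- function(pool, mode = c("distinct", "singleton")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pool, "sample_pool"))
  if (length(pool$counts) == 0L) stop("empty pool")
  n_distinct <- length(pool$counts)
  switch(mode,
         distinct = n_distinct / pool$total_copies,
         singleton = sum(pool$counts == 1) / n_distinct)
}

#' Per-position nucleotide composition
#'
#' @param pool A [sample_pool()].
#' @param weighting `"by_copies"` weights each sequence by its copy number
#'   (describes the sequenced population; the default), `"by_distinct"`
#'   weights each distinct sequence once.
#' @return 4 x L matrix (rows A, C, G, T) of per-position base frequencies;
#'   every column sums to 1.
#' @export
nucleotide_composition <- function(pool,
                                   weighting = c("by_copies", "by_distinct")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(pool, "sample_pool"))
  if (length(pool$counts) == 0L) stop("empty pool")
  seqs <- names(pool$counts)
  L <- nchar(seqs[1L])
  w <- if (weighting == "by_copies") unname(pool$counts) else
    rep(1, length(seqs))
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  ncol = L, byrow = TRUE)
  freqs <- t(vapply(c("A", "C", "G", "T"),
                    function(b) colSums((chars == b) * w),
                    numeric(L)))
  freqs <- freqs / sum(w)
  dimnames(freqs) <- list(c("A", "C", "G", "T"), seq_len(L))
  freqs
}

#' Copy-number binning of a pool
#'
#' Groups distinct sequences into the fixed abundance classes
#' 1–10, 11–100, 101–1000, 1001–10000 and >10000 copies (a boundary value
#' falls in the lower bin), and reports both the number of distinct sequences
#' per bin and each bin's share of total copies.
#'
#' @param pool A [sample_pool()].
#' @return List with `bin_labels`, `distinct_per_bin` (integer, length 5) and
#'   `copy_share_per_bin` (fractions summing to 1).
#' @export
bin_by_copy_number <- function(pool) {
  stopifnot(inherits(pool, "sample_pool"))
  if (length(pool$counts) == 0L) stop("empty pool")
  edges <- c(0, 10, 100, 1000, 10000, Inf)
  labels <- c("<=10", "11-100", "101-1000", "1001-10000", ">10000")
  bin <- cut(pool$counts, breaks = edges, labels = labels)
  distinct <- as.integer(table(bin))
  copies <- as.numeric(tapply(pool$counts, bin, sum, default = 0))
  list(bin_labels = labels,
       distinct_per_bin = stats::setNames(distinct, labels),
       copy_share_per_bin = stats::setNames(copies / pool$total_copies,
                                            labels))
}

#' Fraction of sequences shared between two pools
#'
#' @param pool_a,pool_b [sample_pool()] objects.
#' @param denominator Set used for the denominator: `"union"` (default),
#'   `"A"` or `"B"` (the distinct sequences of that pool).
#' @return Fraction of distinct sequences present in both pools.
#' @export
pool_overlap <- function(pool_a, pool_b,
                         denominator = c("union", "A", "B")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(pool_a, "sample_pool"), inherits(pool_b, "sample_pool"))
  if (length(pool_a$counts) == 0L || length(pool_b$counts) == 0L)
    stop("empty pool")
  a <- names(pool_a$counts)
  b <- names(pool_b$counts)
  shared <- length(intersect(a, b))
  denom <- switch(denominator,
                  union = length(union(a, b)),
                  A = length(a),
                  B = length(b))
  shared / denom
}

#' Per-sequence abundance trajectories across selection cycles
#'
#' Collects, for every sequence seen in at least one pool, its copies and
#' frequencies per cycle and the frequency fold change between consecutive
#' cycles. Folds are computed on pseudocount-regularised frequencies
#' `(copies + pc) / (total + pc)` so a sequence absent in the earlier cycle
#' still gets a finite fold; frequencies themselves are reported without
#' pseudocount (0 where absent). Folds are defined on frequencies rather than
#' raw copy numbers to cancel sequencing-depth differences between cycles.
#'
#' @param pools List of [sample_pool()]s from the same library/tissue with
#'   strictly increasing cycles.
#' @param min_total_copies Drop sequences whose copies summed over all cycles
#'   fall below this (default 1 = keep everything); useful to shed
#'   sequencing-error singletons in large campaigns.
#' @param pseudocount Pseudocount in copies used for folds (default 0.5).
#' @return Object of class `selex_trajectories`: list with `sequences`,
#'   `cycles`, `copies` (S x C matrix), `totals`, `frequency` (S x C),
#'   `folds` (S x (C-1)) and `pseudocount`.
#' @export
build_trajectories <- function(pools, min_total_copies = 1, pseudocount = 0.5) {
  stopifnot(length(pools) >= 2L,
            all(vapply(pools, inherits, logical(1L), "sample_pool")))
  cycles <- vapply(pools, function(p) p$cycle, integer(1L))
  if (any(diff(cycles) <= 0L)) stop("pool cycles must be strictly increasing")
  totals <- vapply(pools, function(p) p$total_copies, numeric(1L))

  seqs <- sort(unique(unlist(lapply(pools, function(p) names(p$counts)),
                             use.names = FALSE)))
  copies <- matrix(0, nrow = length(seqs), ncol = length(pools),
                   dimnames = list(seqs, cycles))
  for (j in seq_along(pools)) {
    cnt <- pools[[j]]$counts
    copies[names(cnt), j] <- unname(cnt)
  }
  keep <- rowSums(copies) >= min_total_copies
  copies <- copies[keep, , drop = FALSE]
  seqs <- seqs[keep]

  freq <- sweep(copies, 2L, totals, "/")
  reg <- sweep(copies + pseudocount, 2L, totals + pseudocount, "/")
  C <- length(pools)
  folds <- reg[, -1L, drop = FALSE] / reg[, -C, drop = FALSE]
  colnames(folds) <- paste0(cycles[-C], "->", cycles[-1L])

  structure(
    list(sequences = seqs, cycles = cycles, copies = copies, totals = totals,
         frequency = freq, folds = folds, pseudocount = pseudocount),
    class = "selex_trajectories")
}

#' @export
print.selex_trajectories <- function(x, ...) {
  cat(sprintf("selex_trajectories: %d sequences over cycles %s\n",
              length(x$sequences), paste(x$cycles, collapse = ", ")))
  invisible(x)
}

#' Merge near-identical sequences into their abundant parent
#'
#' Optional denoising step: a sequence within `max_dist` Hamming distance of
#' a sequence at least `min_parent_ratio` times more abundant is treated as a
#' read error or synthesis variant of that parent and its copies are added to
#' the parent. Parents are considered in descending (pre-merge) count order,
#' ties broken lexicographically; ratio comparisons use pre-merge counts, so
#' the outcome does not depend on merge order. Off by default in all other
#' functions; quadratic in the number of distinct sequences.
#'
#' @param pool A [sample_pool()].
#' @param max_dist Maximum Hamming distance to a parent (default 1).
#' @param min_parent_ratio Minimum parent/child count ratio (default 10).
#' @return A denoised [sample_pool()].
#' @export
cluster_by_hamming <- function(pool, max_dist = 1L, min_parent_ratio = 10) {
  stopifnot(inherits(pool, "sample_pool"))
  counts <- pool$counts
  if (length(counts) <= 1L) return(pool)
  seqs <- names(counts)
  ord <- order(-counts, seqs)
  orig <- unname(counts)
  merged_into <- rep(NA_integer_, length(seqs))
  L <- nchar(seqs[1L])
  ints <- matrix(unlist(lapply(seqs, utf8ToInt), use.names = FALSE),
                 nrow = L)
  for (p in ord) {
    if (!is.na(merged_into[p])) next
    d <- colSums(ints != ints[, p])
    child <- which(is.na(merged_into) & d > 0 & d <= max_dist &
                     orig[p] >= min_parent_ratio * orig)
    merged_into[child] <- p
  }
  parent <- ifelse(is.na(merged_into), seq_along(seqs), merged_into)
  new_counts <- tapply(orig, parent, sum)
  out <- stats::setNames(as.numeric(new_counts),
                         seqs[as.integer(names(new_counts))])
  sample_pool(out, library = pool$library, cycle = pool$cycle,
              tissue = pool$tissue)
}
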