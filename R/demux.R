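#' Demultiplex indexed amplicon reads
#'
#' Assigns each read to the unique sample whose index sequence lies within
#' `max_mismatch` of the read's 5' prefix, then strips the prefix (bases and
#' qualities). Reads matching no index are routed to an `"undetermined"` bin.
#' Indexes are assumed to be a 5' prefix on the read; other layouts are a
#' matter of configuration upstream, not of this function.
#'
#' The index table is rejected outright if any two indexes are closer than
#' `2 * max_mismatch + 1` in Hamming distance, which would make assignment
#' ambiguous.
#'
#' @param reads data.frame as returned by [read_fastq()].
#' @param index_table Named character vector mapping index sequence to
#'   sample id, all indexes the same length.
#' @param max_mismatch Maximum Hamming mismatches tolerated between an index
#'   and the read prefix (default 1).
#' @return A list with elements `samples` (named list of read data.frames,
#'   prefix removed), `undetermined` (read data.frame) and `tally` (named
#'   integer vector of assignment counts, including `undetermined`).
#' @examples
#' idx <- c(AAAACT = "s1", CCATGT = "s2")
#' reads <- data.frame(id = "r1", bases = "AAAACTGGGG", quals = "IIIIIIIIII")
#' demultiplex(reads, idx)$samples$s1$bases  # "GGGG"
#' @export
demultiplex <- function(reads, index_table, max_mismatch = 1L) {
  stopifnot(is.character(index_table), !is.null(names(index_table)))
  indexes <- names(index_table)
  index_len <- unique(nchar(indexes))
  if (length(index_len) != 1L)
    stop("all index sequences must have the same length")
  if (length(indexes) > 1L) {
    d <- outer(indexes, indexes, function(a, b)
      mapply(function(x, y) hamming(x, y), a, b))
    if (min(d[upper.tri(d)]) <= 2L * max_mismatch)
      stop("ambiguous index table: minimum pairwise Hamming distance must ",
           "exceed 2 * max_mismatch")
  }
  samples <- unname(index_table)

  prefixes <- substr(reads$bases, 1L, index_len)
  # mismatches of every read prefix against every index, position by position
  mm <- matrix(0L, nrow = nrow(reads), ncol = length(indexes))
  for (p in seq_len(index_len)) {
    rp <- substr(prefixes, p, p)
    for (j in seq_along(indexes)) {
      mm[, j] <- mm[, j] + (rp != substr(indexes[j], p, p))
    }
  }
  short <- nchar(reads$bases) < index_len
  best <- max.col(-mm, ties.method = "first")
  best_mm <- mm[cbind(seq_len(nrow(mm)), best)]
  assigned <- !short & best_mm <= max_mismatch
  # the distance precondition guarantees at most one index within range

  strip <- function(df) {
    df$bases <- substr(df$bases, index_len + 1L, nchar(df$bases))
    df$quals <- substr(df$quals, index_len + 1L, nchar(df$quals))
    rownames(df) <- NULL
    df
  }
  out <- lapply(seq_along(indexes), function(j)
    strip(reads[assigned & best == j, , drop = FALSE]))
  names(out) <- samples
  und <- reads[!assigned, , drop = FALSE]
  rownames(und) <- NULL
  tally <- c(vapply(out, nrow, integer(1L)), undetermined = nrow(und))
  list(samples = out, undetermined = und, tally = tally)
}

#' Default 12-sample index set
#'
#' Twelve 6-nt indexes with pairwise Hamming distance of at least 3, so
#' demultiplexing with one tolerated mismatch is unambiguous. Up to 12 samples
#' per sequencing run is the multiplexing level the ingest defaults assume.
#'
#' @param n Number of indexes to return (1..12).
#' @return Named character vector index -> sample id (`S01`, `S02`, ...).
#' @export
default_index_table <- function(n = 12L) {
  codes <- c("AAAACT", "CCATGT", "CCGGAA", "GTAGAA", "TCTTGC", "ACTCGG",
             "CATATC", "ACCCCC", "TGCACG", "AGTACA", "ATATTC", "GTTCTA")
  stopifnot(n >= 1L, n <= length(codes))
  stats::setNames(sprintf("S%02d", seq_len(n)), codes[seq_len(n)])
}
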