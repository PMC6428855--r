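#' Counted sequence pool for one selection-cycle sample
#'
#' A `sample_pool` is a multiset of random-region sequences with copy counts
#' for one (library, cycle, tissue) sample — the unit every population metric
#' operates on.
#'
#' @param counts Named positive integer vector; names are sequences over
#'   A/C/G/T, all the same length.
#' @param library Library label, e.g. "D3", "D3P" or "SIM".
#' @param cycle Selection cycle, 0..10 (0 = starting library).
#' @param tissue One of "tumour", "kidney", "none".
#' @return Object of class `sample_pool` with fields `counts`, `library`,
#'   `cycle`, `tissue`, `total_copies`.
#' @export
sample_pool <- function(counts, library = "SIM", cycle = 0L,
                        tissue = c("none", "tumour", "kidney")) {
  tissue <- match.arg(tissue)
  cycle <- as.integer(cycle)
  stopifnot(cycle >= 0L)
  if (length(counts) == 0L) counts <- stats::setNames(numeric(0), character(0))
  counts <- counts[order(names(counts))]
  storage.mode(counts) <- "double"  # copy numbers can exceed .Machine$integer.max after PCR
  if (length(counts)) {
    seqs <- names(counts)
    if (is.null(seqs) || any(seqs == "")) stop("counts must be named by sequence")
    if (length(unique(nchar(seqs))) > 1L)
      stop("all sequences in a pool must have the same length")
    if (any(grepl("[^ACGT]", seqs)))
      stop("pool sequences must contain only A, C, G, T")
    if (any(counts < 1) || any(counts != round(counts)))
      stop("counts must be positive integers")
  }
  structure(
    list(counts = counts, library = library, cycle = cycle, tissue = tissue,
         total_copies = sum(counts)),
    class = "sample_pool")
}

#' Build a pool from a stream of extracted sequences
#'
#' @param sequences Character vector of equal-length sequences (one entry per
#'   molecule; duplicates are counted).
#' @inheritParams sample_pool
#' @return A [sample_pool()].
#' @export
build_pool <- function(sequences, library = "SIM", cycle = 0L,
                       tissue = "none") {
  if (length(sequences) && length(unique(nchar(sequences))) > 1L)
    stop("sequences of mixed length cannot form a pool")
  counts <- table(sequences)
  sample_pool(stats::setNames(as.numeric(counts), names(counts)),
              library = library, cycle = cycle, tissue = tissue)
}

#' @export
print.sample_pool <- function(x, ...) {
  cat(sprintf("sample_pool: %s cycle %d (%s)\n", x$library, x$cycle, x$tissue))
  cat(sprintf("  %d distinct sequences, %.0f total copies\n",
              length(x$counts), x$total_copies))
  invisible(x)
}

#' Pool as a ranked table
#'
#' @param pool A [sample_pool()].
#' @return data.frame with columns `sequence`, `count`, `frequency`, `rank`
#'   (rank 1 = most copies; ties broken lexicographically), ordered by rank.
#' @export
pool_table <- function(pool) {
  stopifnot(inherits(pool, "sample_pool"))
  seqs <- names(pool$counts)
  ord <- order(-pool$counts, seqs)
  data.frame(sequence = seqs[ord],
             count = unname(pool$counts[ord]),
             frequency = unname(pool$counts[ord]) / pool$total_copies,
             rank = seq_along(ord),
             stringsAsFactors = FALSE)
}

#' Write / read a pool as TSV
#'
#' The TSV carries the sample metadata in `#`-prefixed header lines followed
#' by the columns `sequence`, `count`, `frequency`, `rank`, so
#' `read_pool(write_pool(p))` restores `p` exactly.
#'
#' @param pool A [sample_pool()].
#' @param path File path.
#' @return `write_pool` returns `path` invisibly; `read_pool` returns a
#'   [sample_pool()].
#' @export
write_pool <- function(pool, path) {
  tab <- pool_table(pool)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# library: ", pool$library),
               paste0("# cycle: ", pool$cycle),
               paste0("# tissue: ", pool$tissue),
               paste(c("sequence", "count", "frequency", "rank"),
                     collapse = "\t")), con)
  writeLines(sprintf("%s\t%.0f\t%.10g\t%d",
                     tab$sequence, tab$count, tab$frequency, tab$rank), con)
  invisible(path)
}

#' @rdname write_pool
#' @export
read_pool <- function(path) {
  lines <- readLines(path)
  meta <- list(library = "SIM", cycle = 0L, tissue = "none")
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    kv <- sub("^#\\s*", "", lines[i])
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    if (key %in% names(meta)) meta[[key]] <- val
    i <- i + 1L
  }
  if (i > length(lines) || lines[i] != "sequence\tcount\tfrequency\trank")
    stop("malformed pool TSV: missing header at line ", i)
  header_at <- i
  body <- lines[-seq_len(i)]
  counts <- numeric(0)
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 4L))
      stop("malformed pool TSV: expected 4 fields at line ",
           header_at + which(nf != 4L)[1L])
    seqs <- vapply(parts, `[[`, character(1L), 1L)
    cnt <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1L), 2L)))
    if (anyNA(cnt))
      stop("malformed pool TSV: non-numeric count at line ",
           header_at + which(is.na(cnt))[1L])
    counts <- stats::setNames(cnt, seqs)
  }
  sample_pool(counts, library = meta$library, cycle = as.integer(meta$cycle),
              tissue = meta$tissue)
}

#' Write a pool as ranked FASTA
#'
#' Headers are `rank-count`, e.g. `>1-5021` for the most abundant sequence.
#'
#' @inheritParams write_pool
#' @export
write_pool_fasta <- function(pool, path) {
  tab <- pool_table(pool)
  x <- Biostrings::DNAStringSet(tab$sequence)
  names(x) <- sprintf("%d-%.0f", tab$rank, tab$count)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
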