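#' Read a phred+33 FASTQ file
#'
#' Minimal validating reader for 4-line FASTQ records. Malformed records abort
#' with the offending line number, so truncated or shifted files fail loudly
#' instead of silently contaminating downstream counts.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return A data.frame with columns `id` (without the leading `@`),
#'   `bases` and `quals` (phred+33 encoded string), one row per record,
#'   in file order.
#' @seealso [phred_scores()] to decode a quality string.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(data.frame(id = character(0), bases = character(0),
                      quals = character(0), stringsAsFactors = FALSE))
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: truncated record at line ", length(lines))
  idx <- seq(1L, length(lines), by = 4L)
  ids <- lines[idx]
  bases <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  quals <- lines[idx + 3L]

  bad <- which(!startsWith(ids, "@"))
  if (length(bad))
    stop("malformed FASTQ: expected '@' header at line ", idx[bad[1L]])
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ: expected '+' separator at line ", idx[bad[1L]] + 2L)
  bad <- which(nchar(bases) == 0L)
  if (length(bad))
    stop("malformed FASTQ: empty sequence at line ", idx[bad[1L]] + 1L)
  bad <- which(nchar(bases) != nchar(quals))
  if (length(bad))
    stop("malformed FASTQ: quality length != sequence length at line ",
         idx[bad[1L]] + 3L)
  bad <- which(grepl("[^ACGTN]", bases))
  if (length(bad))
    stop("malformed FASTQ: non-ACGTN base at line ", idx[bad[1L]] + 1L)

  data.frame(id = sub("^@", "", ids), bases = bases, quals = quals,
             stringsAsFactors = FALSE)
}

#' Decode a phred+33 quality string
#'
#' @param qual A single quality string.
#' @return Integer vector of phred scores.
#' @export
phred_scores <- function(qual) {
  utf8ToInt(qual) - 33L
}

#' Write reads to a FASTQ file
#'
#' @param reads data.frame with columns `id`, `bases` and optionally `quals`;
#'   missing qualities are written as maximal ("I", phred 40).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  quals <- if (!is.null(reads$quals)) reads$quals else
    vapply(nchar(reads$bases), function(n) strrep("I", n), character(1L))
  out <- as.vector(rbind(paste0("@", reads$id), reads$bases, "+", quals))
  writeLines(out, path)
  invisible(path)
}
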