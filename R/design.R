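#' Amplicon library design
#'
#' Describes the layout of a single-stranded DNA selection library:
#' a 5' constant flank, a random region, and a 3' constant flank, all given
#' on the sense strand. The 3' flank equals the reverse complement of the
#' reverse primer.
#'
#' @param fw_flank 5' constant region (sense strand), A/C/G/T only.
#' @param rv_flank_sense 3' constant region on the sense strand, i.e. the
#'   reverse complement of the reverse primer, A/C/G/T only.
#' @param random_len Length of the random region in nucleotides.
#'
#' @return An object of class `library_design` with fields `fw_flank`,
#'   `rv_flank_sense`, `random_len` and `total_len`.
#'
#' @examples
#' design <- default_library_design()
#' design$total_len  # 80
#'
#' @export
library_design <- function(fw_flank, rv_flank_sense, random_len) {
  stopifnot(is.character(fw_flank), length(fw_flank) == 1L,
            is.character(rv_flank_sense), length(rv_flank_sense) == 1L)
  random_len <- as.integer(random_len)
  if (is.na(random_len) || random_len < 1L)
    stop("random_len must be a positive integer")
  for (fl in c(fw = fw_flank, rv = rv_flank_sense)) {
    if (nchar(fl) == 0L || grepl("[^ACGT]", fl))
      stop("flanks must be non-empty and contain only A, C, G, T")
  }
  structure(
    list(fw_flank = fw_flank,
         rv_flank_sense = rv_flank_sense,
         random_len = random_len,
         total_len = nchar(fw_flank) + random_len + nchar(rv_flank_sense)),
    class = "library_design")
}

#' @rdname library_design
#' @details `default_library_design()` returns the design of the D3/D3P
#'   libraries: an 18-nt forward-primer flank, a 43-nt random region and a
#'   19-nt 3' flank (reverse complement of the reverse primer), 80 nt total.
#' @export
default_library_design <- function() {
  library_design(
    fw_flank = "GCTGTGTGACTCCTGCAA",
    rv_flank_sense = reverse_complement("GGAGACAAGATACAGCTGC"),
    random_len = 43L)
}

#' @export
print.library_design <- function(x, ...) {
  cat("Library design (", x$total_len, " nt)\n", sep = "")
  cat("  5' flank : ", x$fw_flank, "\n", sep = "")
  cat("  random   : N x ", x$random_len, "\n", sep = "")
  cat("  3' flank : ", x$rv_flank_sense, "\n", sep = "")
  invisible(x)
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Fraction of a given base in a sequence
#'
#' @param sequence A single DNA string.
#' @param base One of "A", "C", "G", "T".
#' @return Fraction of positions equal to `base`, in `[0, 1]`.
#' @examples
#' base_fraction("GGAT", "G")  # 0.5
#' @export
base_fraction <- function(sequence, base = "G") {
  stopifnot(length(sequence) == 1L, nchar(sequence) > 0L,
            base %in% c("A", "C", "G", "T"))
  n <- Biostrings::letterFrequency(Biostrings::DNAString(sequence), base)
  as.numeric(n) / nchar(sequence)
}

# Hamming distance between equal-length strings; `x` may be a vector.
hamming <- function(x, y) {
  stopifnot(all(nchar(x) == nchar(y)))
  iy <- utf8ToInt(y)
  vapply(x, function(a) sum(utf8ToInt(a) != iy), integer(1L), USE.NAMES = FALSE)
}
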