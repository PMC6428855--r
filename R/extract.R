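#' Extract the random region from amplicon reads
#'
#' Locates the 5' constant flank near the start of each read (allowing a
#' little synthesis slippage), takes the following `random_len` bases as the
#' random region, and checks whatever part of the 3' flank is still visible.
#' With 75-bp reads over an 80-nt amplicon only a truncated 3' flank can ever
#' be observed, so agreement is required only over the observed overlap.
#'
#' Rejection reasons:
#' \describe{
#'   \item{no_fw}{5' flank not found within the allowed window/mismatches.}
#'   \item{short}{read too short to contain a full random region.}
#'   \item{bad_rv}{observed 3'-flank overlap disagrees beyond tolerance.}
#'   \item{ambiguous_base}{extracted region contains N.}
#' }
#' Checks are applied in that order; the first failure is reported.
#'
#' @param bases Character vector of read sequences (index already stripped).
#' @param design A [library_design()].
#' @param max_mismatch_fw Mismatches tolerated in the 5' flank (default 2).
#' @param min_rv_overlap Minimum number of 3'-flank bases that must be present
#'   after the region before the 3' check applies (default 8).
#' @param max_mismatch_rv Mismatches tolerated in the observed 3'-flank
#'   overlap (default 1).
#' @return data.frame with columns `region` (the extracted sequence, NA on
#'   rejection) and `reason` (NA on acceptance, otherwise one of the reasons
#'   above).
#' @export
extract_random_region <- function(bases, design = default_library_design(),
                                  max_mismatch_fw = 2L, min_rv_overlap = 8L,
                                  max_mismatch_rv = 1L) {
  fw <- design$fw_flank
  rv <- design$rv_flank_sense
  fw_len <- nchar(fw)
  rlen <- design$random_len

  n <- length(bases)
  region <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  # flank must start within the first 3 positions so that it lies entirely
  # inside the first fw_len + 2 bases of the read (+-2 nt slippage window);
  # the best-matching offset wins, earliest on ties
  starts <- rep(NA_integer_, n)
  best_mm <- rep(.Machine$integer.max, n)
  for (off in 1:3) {
    cand <- substr(bases, off, off + fw_len - 1L)
    ok <- nchar(cand) == fw_len
    mm <- rep(.Machine$integer.max, n)
    if (any(ok)) mm[ok] <- hamming(cand[ok], fw)
    better <- mm <= max_mismatch_fw & mm < best_mm
    starts[better] <- off
    best_mm[better] <- mm[better]
  }
  no_fw <- is.na(starts)
  reason[no_fw] <- "no_fw"

  i <- which(!no_fw)
  reg_start <- starts[i] + fw_len
  reg_end <- reg_start + rlen - 1L
  too_short <- reg_end > nchar(bases[i])
  reason[i[too_short]] <- "short"
  i <- i[!too_short]
  reg_start <- reg_start[!too_short]
  reg_end <- reg_end[!too_short]

  regions <- substr(bases[i], reg_start, reg_end)

  # 3' flank check over the observed overlap
  tails <- substr(bases[i], reg_end + 1L, nchar(bases[i]))
  overlap <- pmin(nchar(tails), nchar(rv))
  check <- overlap >= min_rv_overlap
  bad_rv <- rep(FALSE, length(i))
  if (any(check)) {
    obs <- substr(tails[check], 1L, overlap[check])
    exp_rv <- substr(rep(rv, sum(check)), 1L, overlap[check])
    mm_rv <- mapply(function(a, b) hamming(a, b), obs, exp_rv,
                    USE.NAMES = FALSE)
    bad_rv[check] <- mm_rv > max_mismatch_rv
  }
  reason[i[bad_rv]] <- "bad_rv"
  i2 <- !bad_rv

  amb <- grepl("N", regions, fixed = TRUE)
  reason[i[i2 & amb]] <- "ambiguous_base"
  keep <- i2 & !amb
  region[i[keep]] <- regions[keep]

  data.frame(region = region, reason = reason, stringsAsFactors = FALSE)
}
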