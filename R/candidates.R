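#' Rank sequences for downstream screening
#'
#' Implements the two-criterion candidate collection used after a multi-cycle
#' selection: (i) abundance — sequences whose final-cycle frequency exceeds
#' `freq_threshold` form the `abundant` track, ranked by final frequency; and
#' (ii) enrichment profile — remaining sequences whose log2 fold-change
#' profile resembles that of the abundant winners join the `low_frequency`
#' track. "Resembles" is operationalised as cosine similarity of the log2-fold
#' vector against the centroid profile of the `top_n_reference` abundant
#' sequences, requiring similarity at or above `similarity_threshold` and net
#' enrichment over the campaign (geometric-mean fold of at least 1). The net
#' enrichment condition screens out fading background while keeping truly
#' selected sequences whose growth has saturated by the final cycles.
#'
#' @param trajectories A [build_trajectories()] result.
#' @param freq_threshold Final-cycle frequency separating the tracks
#'   (default 0.005, i.e. 0.5%).
#' @param similarity_threshold Minimum cosine similarity to the abundant
#'   centroid for the low-frequency track (default 0.8).
#' @param top_n_reference Number of top abundant sequences defining the
#'   centroid profile (default 10).
#' @param tumour_pool,kidney_pool Optional same-cycle [sample_pool()]s; when
#'   both are given the tumour/kidney partition ratio is added per candidate.
#' @return data.frame of candidates (abundant track first, then
#'   low-frequency), with columns `sequence`, `track`, `final_frequency`,
#'   `max_fold`, `max_fold_transition`, `profile_similarity` and
#'   `tumour_kidney_ratio` (NA unless both pools are supplied). Ties are
#'   broken lexicographically, so the list is deterministic.
#' @export
select_candidates <- function(trajectories, freq_threshold = 0.005,
                              similarity_threshold = 0.8,
                              top_n_reference = 10L,
                              tumour_pool = NULL, kidney_pool = NULL) {
  stopifnot(inherits(trajectories, "selex_trajectories"))
  freq <- trajectories$frequency
  folds <- trajectories$folds
  if (ncol(folds) < 1L) stop("need at least 2 cycles")
  final_freq <- freq[, ncol(freq)]
  lf <- log2(folds)

  max_j <- max.col(folds, ties.method = "first")
  rec <- data.frame(
    sequence = trajectories$sequences,
    final_frequency = unname(final_freq),
    max_fold = folds[cbind(seq_len(nrow(folds)), max_j)],
    max_fold_transition = colnames(folds)[max_j],
    profile_similarity = NA_real_,
    tumour_kidney_ratio = NA_real_,
    stringsAsFactors = FALSE)

  abundant <- which(rec$final_frequency > freq_threshold)
  if (length(abundant) == 0L) {
    warning("no sequence exceeds the abundance threshold; ",
            "low-frequency track is empty (no reference profile)")
    empty <- cbind(rec[0L, , drop = FALSE], track = character(0))
    return(empty[, c("sequence", "track", "final_frequency", "max_fold",
                     "max_fold_transition", "profile_similarity",
                     "tumour_kidney_ratio")])
  }
  ab_ord <- abundant[order(-rec$final_frequency[abundant],
                           rec$sequence[abundant])]
  ref <- ab_ord[seq_len(min(top_n_reference, length(ab_ord)))]
  centroid <- colMeans(lf[ref, , drop = FALSE])
  cn <- sqrt(sum(centroid^2))

  cosine <- if (cn == 0) rep(0, nrow(lf)) else {
    num <- as.numeric(lf %*% centroid)
    den <- sqrt(rowSums(lf^2)) * cn
    ifelse(den == 0, 0, num / den)
  }
  rec$profile_similarity <- cosine

  rest <- setdiff(seq_len(nrow(rec)), abundant)
  net_enriching <- rowMeans(lf) >= 0  # geometric-mean fold >= 1
  lowfreq <- rest[cosine[rest] >= similarity_threshold & net_enriching[rest]]
  lf_ord <- lowfreq[order(-cosine[lowfreq], rec$sequence[lowfreq])]

  ab <- rec[ab_ord, , drop = FALSE]
  ab$track <- rep("abundant", nrow(ab))
  lo <- rec[lf_ord, , drop = FALSE]
  lo$track <- rep("low_frequency", nrow(lo))
  out <- rbind(ab, lo)
  out <- out[, c("sequence", "track", "final_frequency", "max_fold",
                 "max_fold_transition", "profile_similarity",
                 "tumour_kidney_ratio")]
  rownames(out) <- NULL

  if (!is.null(tumour_pool) && !is.null(kidney_pool)) {
    tk <- tumour_kidney_ratio(tumour_pool, kidney_pool, out$sequence)
    out$tumour_kidney_ratio <- tk$ratio
  }
  out
}

#' Tumour/kidney partition ratio of a sequence
#'
#' Compares a sequence's pseudocount-regularised frequency in the tumour pool
#' with its frequency in the matched kidney pool of the same cycle. Ratios
#' below 1 flag clearance-biased sequences — more strongly associated with
#' the kidney (the major elimination route) than with the tumour.
#'
#' @param tumour_pool,kidney_pool Same-cycle, same-library [sample_pool()]s.
#' @param sequences Character vector of sequences to score.
#' @param pseudocount Pseudocount in copies (default 0.5).
#' @return data.frame with columns `sequence`, `tumour_frequency`,
#'   `kidney_frequency`, `ratio` and `uninformative` (TRUE when the sequence
#'   is absent from both pools, in which case the ratio is reported as 1).
#' @export
tumour_kidney_ratio <- function(tumour_pool, kidney_pool, sequences,
                                pseudocount = 0.5) {
  stopifnot(inherits(tumour_pool, "sample_pool"),
            inherits(kidney_pool, "sample_pool"))
  ct <- tumour_pool$counts[sequences]
  ck <- kidney_pool$counts[sequences]
  ct[is.na(ct)] <- 0
  ck[is.na(ck)] <- 0
  ft <- (ct + pseudocount) / (tumour_pool$total_copies + pseudocount)
  fk <- (ck + pseudocount) / (kidney_pool$total_copies + pseudocount)
  uninformative <- ct == 0 & ck == 0
  ratio <- ft / fk
  ratio[uninformative] <- 1
  data.frame(sequence = sequences,
             tumour_frequency = unname(ct / tumour_pool$total_copies),
             kidney_frequency = unname(ck / kidney_pool$total_copies),
             ratio = unname(ratio),
             uninformative = unname(uninformative),
             stringsAsFactors = FALSE)
}
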