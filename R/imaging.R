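#' Exposure-stamped planar fluorescence image
#'
#' @param pixels Numeric matrix of non-negative intensities.
#' @param exposure_ms Exposure time in milliseconds (> 0).
#' @param timepoint_min Acquisition time in minutes post injection
#'   (0 = pre-injection).
#' @return Object of class `planar_image`.
#' @export
planar_image <- function(pixels, exposure_ms, timepoint_min = 0) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)),
            is.numeric(exposure_ms), length(exposure_ms) == 1L)
  if (exposure_ms <= 0) stop("exposure_ms must be positive")
  structure(list(pixels = pixels, exposure_ms = exposure_ms,
                 timepoint_min = timepoint_min),
            class = "planar_image")
}

#' @export
print.planar_image <- function(x, ...) {
  cat(sprintf("planar_image: %d x %d px, %g ms exposure, t = %g min\n",
              nrow(x$pixels), ncol(x$pixels), x$exposure_ms, x$timepoint_min))
  invisible(x)
}

#' Read a single-channel TIFF as a planar image
#'
#' @param path TIFF path.
#' @param exposure_ms Exposure time of the acquisition.
#' @param timepoint_min Acquisition timepoint in minutes.
#' @return A [planar_image()]; multi-channel rasters are rejected.
#' @export
read_planar_tiff <- function(path, exposure_ms, timepoint_min = 0) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3L] != 1L) stop("expected a single-channel TIFF")
    px <- px[, , 1L]
  }
  planar_image(px, exposure_ms, timepoint_min)
}

#' Camera-background subtraction and exposure normalisation
#'
#' Subtracts the intrinsic camera background (a scalar or a same-shape
#' per-pixel grid), clips negative values to zero, and rescales intensities
#' to a common reference exposure:
#' `pixels' = max(pixels - background, 0) * reference_exposure_ms / exposure_ms`.
#'
#' @param img A [planar_image()].
#' @param camera_background Scalar or matrix matching the image shape
#'   (default 0).
#' @param reference_exposure_ms Target exposure time.
#' @return A [planar_image()] at the reference exposure.
#' @export
normalize_image <- function(img, camera_background = 0,
                            reference_exposure_ms) {
  stopifnot(inherits(img, "planar_image"))
  if (reference_exposure_ms <= 0) stop("reference exposure must be positive")
  bg <- camera_background
  if (is.matrix(bg) && !all(dim(bg) == dim(img$pixels)))
    stop("background grid shape does not match the image")
  px <- pmax(img$pixels - bg, 0) * reference_exposure_ms / img$exposure_ms
  planar_image(px, reference_exposure_ms, img$timepoint_min)
}

#' Mean intensity over a region of interest
#'
#' @param img A [planar_image()] or a plain matrix.
#' @param mask Logical matrix of the same shape with at least one TRUE pixel.
#' @return Arithmetic mean of the pixels inside the mask.
#' @export
roi_mean <- function(img, mask) {
  px <- if (inherits(img, "planar_image")) img$pixels else img
  stopifnot(is.matrix(px), is.logical(mask), all(dim(mask) == dim(px)))
  if (!any(mask)) stop("ROI mask is empty")
  mean(px[mask])
}

#' Tumour-to-reference fluorescence ratio
#'
#' Semi-quantitative tumour-targeting readout: both images are
#' background-subtracted and normalised to a common exposure, the
#' pre-injection (autofluorescence) ROI mean is subtracted from the
#' post-injection ROI mean for the same mask, and the tumour value is divided
#' by the reference-zone value. In `ex_vivo` mode (tumour vs muscle on
#' resected organs) no pre-injection image exists and no subtraction is done;
#' pass `img_t0 = NULL`.
#'
#' @param img_t Post-injection [planar_image()].
#' @param img_t0 Pre-injection image (same animal/masks), or NULL for
#'   ex-vivo mode.
#' @param tumour_mask,reference_mask Logical ROI masks (tumour; healthy zone
#'   or muscle).
#' @param camera_background Scalar or per-pixel camera background (default 0).
#' @param reference_exposure_ms Exposure to normalise to (default: exposure
#'   of `img_t`).
#' @return List with `tumour_mean`, `reference_mean`, `ratio`,
#'   `timepoint_min` and `flag` (`"ok"`, or `"undefined_reference"` when the
#'   reference mean is not positive — the ratio is NA then, never a silent
#'   infinity).
#' @export
tumour_ratio <- function(img_t, img_t0, tumour_mask, reference_mask,
                         camera_background = 0,
                         reference_exposure_ms = img_t$exposure_ms) {
  stopifnot(inherits(img_t, "planar_image"))
  nt <- normalize_image(img_t, camera_background, reference_exposure_ms)
  tumour_mean <- roi_mean(nt, tumour_mask)
  reference_mean <- roi_mean(nt, reference_mask)
  if (!is.null(img_t0)) {
    n0 <- normalize_image(img_t0, camera_background, reference_exposure_ms)
    tumour_mean <- tumour_mean - roi_mean(n0, tumour_mask)
    reference_mean <- reference_mean - roi_mean(n0, reference_mask)
  }
  if (reference_mean <= 0) {
    return(list(tumour_mean = tumour_mean, reference_mean = reference_mean,
                ratio = NA_real_, timepoint_min = img_t$timepoint_min,
                flag = "undefined_reference"))
  }
  list(tumour_mean = tumour_mean, reference_mean = reference_mean,
       ratio = tumour_mean / reference_mean,
       timepoint_min = img_t$timepoint_min, flag = "ok")
}

#' Pairwise t-tests with a pooled standard deviation
#'
#' Unpaired t-tests assuming all groups share one standard deviation: the
#' pooled SD is the one-way-ANOVA residual SD across all groups, each
#' pairwise statistic is `(mean_a - mean_b) / (sd_pooled * sqrt(1/n_a +
#' 1/n_b))` with `N - k` degrees of freedom, and p-values are two-sided.
#' With two groups this reduces to the classic pooled two-sample t-test.
#'
#' @param groups Named list of numeric vectors, each of length >= 2.
#' @return data.frame with one row per pair: `group1`, `group2`,
#'   `mean_diff`, `t`, `df`, `p`, `degenerate` (TRUE when the pooled SD is
#'   zero; then `p` is 1 for equal means and 0 otherwise).
#' @export
pooled_sd_ttest <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(lengths(groups) >= 2L))
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1L))
  sse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1L)))
  df <- N - k
  sd_pooled <- sqrt(sse / df)
  pairs <- utils::combn(k, 2L)
  res <- apply(pairs, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    diff <- means[i] - means[j]
    se <- sd_pooled * sqrt(1 / n[i] + 1 / n[j])
    if (sd_pooled == 0) {
      t <- if (diff == 0) 0 else Inf * sign(diff)
      p <- if (diff == 0) 1 else 0
      degenerate <- TRUE
    } else {
      t <- diff / se
      p <- 2 * stats::pt(-abs(t), df)
      degenerate <- FALSE
    }
    data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
               mean_diff = diff, t = t, df = df, p = p,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Synthetic planar-fluorescence fixture
#'
#' Builds a pre-/post-injection image pair with a Gaussian tumour blob over a
#' diffuse circulating-probe level and an autofluorescence background, plus
#' optional Gaussian pixel noise, together with disk-shaped tumour and
#' reference ROI masks. The post-injection reference zone carries only the
#' diffuse level, so the planted post-subtraction ratio is
#' `(diffuse + blob ROI mean) / diffuse`.
#'
#' @param shape `c(rows, cols)` (default `c(64, 64)`).
#' @param tumour_center,reference_center `c(row, col)` centres of the two
#'   ROIs.
#' @param tumour_amplitude Peak blob intensity above the diffuse level.
#' @param tumour_sigma Gaussian width of the blob in pixels.
#' @param roi_radius ROI disk radius in pixels (default `2 * tumour_sigma`).
#' @param diffuse_level Circulating-probe intensity present everywhere post
#'   injection.
#' @param autofluorescence Tissue background present in both images.
#' @param camera_background Constant camera offset added to both images.
#' @param noise_sd SD of additive Gaussian noise (0 = noiseless).
#' @param exposure_ms Exposure stamp of both images.
#' @param seed RNG seed.
#' @return List with `img_t0`, `img_t`, noiseless `clean_t0`/`clean_t`,
#'   `tumour_mask`, `reference_mask`.
#' @export
make_synthetic_fri <- function(shape = c(64L, 64L),
                               tumour_center = c(20, 20),
                               reference_center = c(44, 44),
                               tumour_amplitude = 50, tumour_sigma = 4,
                               roi_radius = 2 * tumour_sigma,
                               diffuse_level = 10, autofluorescence = 5,
                               camera_background = 0,
                               noise_sd = 0, exposure_ms = 1000, seed = 1L) {
  set.seed(seed)
  rows <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  cols <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  blob <- tumour_amplitude *
    exp(-((rows - tumour_center[1L])^2 + (cols - tumour_center[2L])^2) /
          (2 * tumour_sigma^2))
  clean_t0 <- matrix(autofluorescence + camera_background,
                     shape[1L], shape[2L])
  clean_t <- clean_t0 + diffuse_level + blob
  noise <- function() if (noise_sd > 0)
    matrix(stats::rnorm(prod(shape), 0, noise_sd), shape[1L]) else 0
  disk <- function(center)
    (rows - center[1L])^2 + (cols - center[2L])^2 <= roi_radius^2
  list(img_t0 = planar_image(pmax(clean_t0 + noise(), 0), exposure_ms, 0),
       img_t = planar_image(pmax(clean_t + noise(), 0), exposure_ms, 180),
       clean_t0 = planar_image(clean_t0, exposure_ms, 0),
       clean_t = planar_image(clean_t, exposure_ms, 180),
       tumour_mask = disk(tumour_center),
       reference_mask = disk(reference_center))
}
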