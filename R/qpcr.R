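#' Fit a qPCR standard curve
#'
#' Least-squares fit of Cq against log10(quantity) over a dilution series
#' (e.g. 20 to 0.002 fmol in 1:10 steps). Replicate Cq values at the same
#' quantity are averaged before fitting. The amplification efficiency is
#' `10^(-1/slope) - 1`; a perfect doubling per cycle gives slope
#' `-1/log10(2) = -3.3219` and efficiency 1.
#'
#' @param standards data.frame with columns `quantity_fmol` (> 0) and `cq`.
#' @return Object of class `standard_curve` with `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `valid` (FALSE when the slope is
#'   non-negative) and `fit` (the underlying `lm`).
#' @export
fit_standard_curve <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("quantity_fmol", "cq") %in% names(standards)))
  if (any(standards$quantity_fmol <= 0))
    stop("standard quantities must be positive")
  agg <- stats::aggregate(cq ~ quantity_fmol, data = standards, FUN = mean)
  if (nrow(agg) < 3L)
    stop("need at least 3 distinct standard quantities")
  agg$log_q <- log10(agg$quantity_fmol)
  fit <- stats::lm(cq ~ log_q, data = agg)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  valid <- slope < 0
  if (!valid)
    warning("non-negative slope: standard curve flagged invalid")
  sst <- sum((agg$cq - mean(agg$cq))^2)
  r_squared <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(
    list(slope = slope, intercept = intercept,
         r_squared = r_squared,
         efficiency = 10^(-1 / slope) - 1,
         valid = valid, fit = fit),
    class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard_curve: Cq = %.4f %+.4f * log10(fmol)  (R^2 = %.4f, eff = %.3f%s)\n",
    x$intercept, x$slope, x$r_squared, x$efficiency,
    if (x$valid) "" else ", INVALID"))
  invisible(x)
}

#' Quantify samples from Cq values
#'
#' @param curve A valid [fit_standard_curve()] result.
#' @param cq Numeric vector of quantification cycles.
#' @return Quantities in fmol: `10^((cq - intercept) / slope)`.
#' @export
quantify <- function(curve, cq) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!curve$valid) stop("cannot quantify from an invalid standard curve")
  10^((cq - curve$intercept) / curve$slope)
}

#' Fraction of material remaining relative to time zero
#'
#' @param quant_t Quantity at time t (fmol).
#' @param quant_0 Quantity at time 0 (fmol, > 0).
#' @return Percent `100 * quant_t / quant_0`. Values above 100 (possible
#'   with qPCR noise) are reported as-is but flagged with a warning.
#' @export
stability_fraction <- function(quant_t, quant_0) {
  stopifnot(length(quant_0) == 1L)
  if (quant_0 <= 0) stop("quant_0 must be positive")
  pct <- 100 * quant_t / quant_0
  if (any(pct > 100))
    warning("recovery above 100% — quantification noise exceeds decay")
  pct
}

# average residue masses of deoxynucleotide monophosphates, Da
.dnmp_mass <- c(A = 313.21, C = 289.18, G = 329.21, T = 304.20)
.terminal_correction_da <- 61.96

#' Molecular weight of a single-stranded DNA
#'
#' Sum of average deoxynucleotide-monophosphate residue masses (A 313.21,
#' C 289.18, G 329.21, T 304.20 Da) minus a 61.96 Da terminal correction,
#' plus an optional PEG moiety. An 80-nt equimolar library comes to
#' ~24.7 kDa (~25 kDa), and ~35.7 kDa (~36 kDa) with an 11 kDa PEG — the
#' difference that puts the pegylated library at the renal filtration
#' threshold while the naked one is cleared.
#'
#' @param length_nt Sequence length in nucleotides (>= 1).
#' @param composition `"equimolar"` (default) or a named vector of base
#'   counts (A/C/G/T) summing to `length_nt`.
#' @param peg_kda Mass of an attached PEG moiety in kDa (>= 0, default 0).
#' @return Molecular weight in kDa.
#' @examples
#' ssdna_molecular_weight(80)            # ~24.65
#' ssdna_molecular_weight(80, peg_kda = 11)  # ~35.65
#' @export
ssdna_molecular_weight <- function(length_nt, composition = "equimolar",
                                   peg_kda = 0) {
  stopifnot(length_nt >= 1L, peg_kda >= 0)
  if (identical(composition, "equimolar")) {
    residue_da <- length_nt * mean(.dnmp_mass)
  } else {
    stopifnot(is.numeric(composition),
              all(names(composition) %in% names(.dnmp_mass)))
    if (sum(composition) != length_nt)
      stop("composition counts must sum to length_nt")
    residue_da <- sum(.dnmp_mass[names(composition)] * composition)
  }
  (residue_da - .terminal_correction_da + peg_kda * 1000) / 1000
}

#' Number of molecules in an injected amount
#'
#' For a library injected as "one copy of each sequence", the molecule count
#' of an amount in nmol is also its sequence diversity: 5 nmol is
#' ~3.01e15 molecules, order of magnitude 10^15.
#'
#' @param nmol Amount in nanomoles (> 0).
#' @return List with `count` (molecules) and `order_of_magnitude`
#'   (`10^floor(log10(count))`).
#' @export
diversity_from_amount <- function(nmol) {
  stopifnot(nmol > 0)
  avogadro <- 6.02214076e23
  count <- nmol * 1e-9 * avogadro
  list(count = count, order_of_magnitude = 10^floor(log10(count)))
}
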