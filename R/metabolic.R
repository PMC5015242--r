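#' Derive VLDL and LDL cholesterol from a measured lipid panel
#'
#' Friedewald-style derivation: \code{VLDL-C = TG / 5} and
#' \code{LDL-C = TotChol - HDL-C - VLDL-C} (all mg/dl). The formula is
#' applied unconditionally; a negative derived LDL-C (possible for
#' pathological inputs, e.g. very high triglycerides) is flagged rather
#' than clipped.
#'
#' @param tg Triglycerides (mg/dl, >= 0).
#' @param tot Total cholesterol (mg/dl, >= 0).
#' @param hdl HDL cholesterol (mg/dl, >= 0).
#' @return data.frame with \code{vldl}, \code{ldl} and a
#'   \code{ldl_negative} flag. Values are exact; round for report output.
#' @export
derive_lipids <- function(tg, tot, hdl) {
  if (any(c(tg, tot, hdl) < 0)) stop("lipid inputs must be >= 0")
  vldl <- tg / 5
  ldl <- tot - hdl - vldl
  data.frame(vldl = vldl, ldl = ldl, ldl_negative = ldl < 0)
}

#' Area under a tolerance-test curve by the trapezoidal rule
#'
#' Composite trapezoid over the sampled timepoints of a glucose (or
#' insulin) tolerance test; exact for piecewise-linear curves and additive
#' over partitions of the time axis. Total area above zero by default; with
#' \code{baseline} set, the baseline is subtracted first (incremental AUC,
#' which may be negative).
#'
#' @param time Timepoints in minutes, strictly increasing, length >= 2.
#' @param conc Concentrations (mg/dl), same length, non-negative.
#' @param baseline Optional baseline concentration to subtract.
#' @return Area in mg/dl x min.
#' @export
auc_trapezoid <- function(time, conc, baseline = NULL) {
  if (length(time) < 2) stop("need >= 2 timepoints")
  if (length(time) != length(conc)) stop("time and conc lengths differ")
  if (any(diff(time) <= 0)) stop("timepoints must be strictly increasing")
  if (any(conc < 0)) stop("concentrations must be >= 0")
  y <- if (is.null(baseline)) conc else conc - baseline
  pracma::trapz(time, y)
}

#' Relative expression by the delta-delta-Ct method
#'
#' qPCR relative quantification: the target gene's Ct is normalized to a
#' reference gene within each condition, and the treated condition to the
#' calibrator; fold change is \code{2^(-ddCt)} with
#' \code{ddCt = (Ct_target_s - Ct_ref_s) - (Ct_target_c - Ct_ref_c)}.
#' Invariant to adding a constant to all four Cts.
#'
#' @param ct_target_s,ct_ref_s Target and reference Ct in the sample
#'   (treated) condition.
#' @param ct_target_c,ct_ref_c Target and reference Ct in the calibrator
#'   (control) condition.
#' @return Fold change (positive real).
#' @export
ddct_fold_change <- function(ct_target_s, ct_ref_s, ct_target_c,
                             ct_ref_c) {
  if (any(!is.finite(c(ct_target_s, ct_ref_s, ct_target_c, ct_ref_c))))
    stop("Ct values must be finite")
  ddct <- (ct_target_s - ct_ref_s) - (ct_target_c - ct_ref_c)
  2^(-ddct)
}

#' Daily solute dose from fluid intake
#'
#' Dose ingested per day when a solute is delivered through drinking fluid:
#' \code{dose [mg/day] = volume [mL/day] * concentration [ug/mL] / 1000}.
#' The default concentration is the 200 ug/mL nicotine-salt drinking-water
#' formulation; the dose refers to the salt as dissolved (no free-base
#' conversion).
#'
#' @param volume Fluid intake (mL/day, >= 0).
#' @param conc Solute concentration (ug/mL, default 200).
#' @return Dose in mg/day.
#' @export
daily_dose <- function(volume, conc = 200) {
  if (any(volume < 0)) stop("volume must be >= 0")
  volume * conc / 1000
}
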