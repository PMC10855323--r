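# Plate-reader and flow-cytometry summary computations: kinetics AUC, DNA
# normalization, per-experiment z-standardization, phagocytic metrics.

#' Area under a kinetics trace
#'
#' Trapezoidal integral of the baseline-subtracted signal from the
#' activator-addition time to `t_end`. The baseline is the mean of the
#' pre-activation samples (or the first sample if none exist). A warning is
#' issued when `t_end` does not exceed the burst peak time.
#'
#' @param trace A data.frame with `time_s` and `signal` (e.g. a
#'   [simulate_kinetics_trace()] result), or two vectors via `time_s`.
#' @param t_end End of the integration window, s.
#' @param t_act Activator-addition time, s; defaults to the trace attribute.
#' @return Area in signal * s.
#' @export
kinetics_auc <- function(trace, t_end, t_act = attr(trace, "t_act_s")) {
  stopifnot(is.data.frame(trace), all(c("time_s", "signal") %in% names(trace)))
  tt <- trace$time_s
  if (any(diff(tt) <= 0)) abort_domain("time must be strictly increasing")
  if (is.null(t_act)) t_act <- tt[1]
  if (t_end <= t_act) abort_domain("t_end must exceed the activator time")
  if (t_end > tt[length(tt)]) abort_domain("t_end beyond the trace")
  pre <- trace$signal[tt < t_act]
  baseline <- if (length(pre)) mean(pre) else trace$signal[1]
  sig <- trace$signal - baseline
  i_peak <- which.max(sig)
  if (t_end < tt[i_peak])
    warning("t_end precedes the signal peak; AUC window should exceed the peak time")
  # integrate on [t_act, t_end] with interpolated endpoints
  inside <- tt > t_act & tt < t_end
  xs <- c(t_act, tt[inside], t_end)
  ys <- c(approx(tt, sig, t_act, rule = 2)$y, sig[inside],
          approx(tt, sig, t_end, rule = 2)$y)
  pracma::trapz(xs, ys)
}

#' Normalize activity values to DNA content
#'
#' Divides per-well activity (e.g. a chemiluminescence AUC) by the DNA
#' concentration of the well, making wells with different cell numbers
#' comparable. Wells with non-positive DNA are excluded (NA) with a warning.
#'
#' @param values Numeric activities per well.
#' @param dna_ng_ml DNA concentration per well (ng/mL), > 0.
#' @return `values / dna_ng_ml`, with NA for excluded wells.
#' @export
dna_normalize <- function(values, dna_ng_ml) {
  stopifnot(length(values) == length(dna_ng_ml))
  bad <- !is.finite(dna_ng_ml) | dna_ng_ml <= 0
  if (any(bad))
    warning(sum(bad), " well(s) with non-positive DNA excluded")
  out <- values / dna_ng_ml
  out[bad] <- NA_real_
  out
}

#' Per-experiment z-standardization
#'
#' Standardizes each row (biological experiment) of a measurement matrix to
#' mean 0 and sample SD 1 (n - 1 denominator), removing between-donor scale
#' differences so condition effects can be compared across experiments.
#' Constant rows yield NA with a warning.
#'
#' @param x Numeric matrix or data.frame; rows = experiments, columns =
#'   condition groups (>= 2 values per row).
#' @return Matrix of z-scores with the input dimnames.
#' @export
zscore_standardize <- function(x) {
  m <- as.matrix(x)
  if (ncol(m) < 2) abort_domain("need >= 2 values per experiment row")
  sds <- apply(m, 1, sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0))
    warning("constant row(s) produced NA z-scores")
  out <- t(apply(m, 1, function(r) {
    s <- sd(r, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(rep(NA_real_, length(r)))
    (r - mean(r, na.rm = TRUE)) / s
  }))
  dimnames(out) <- dimnames(m)
  out
}

#' Phagocytic affinity and capacity
#'
#' Gates a fluorescence-intensity sample against a matched no-particle
#' control: the threshold is a high quantile of the control distribution
#' (99.5th percentile by default, emulating a gate placed above the
#' autofluorescence mode). Affinity is the percentage of events above the
#' gate; capacity is the median (or mean) fluorescence intensity of the
#' gated events, a proxy for particles engulfed per cell.
#'
#' @param sample Numeric event intensities (>= 100 events).
#' @param control Matched no-particle control intensities (used for the
#'   threshold unless `threshold` is given).
#' @param threshold Explicit gate value (optional).
#' @param control_quantile Quantile of the control used as the gate.
#' @param stat `"median"` (cytometry convention for MFI) or `"mean"`.
#' @return List with `affinity_pct`, `capacity_mfi` (NA when no events pass
#'   the gate), `threshold`, `n_events`, `n_positive`.
#' @export
phagocytic_metrics <- function(sample, control = NULL, threshold = NULL,
                               control_quantile = 0.995,
                               stat = c("median", "mean")) {
  stat <- match.arg(stat)
  x <- as.numeric(sample)
  if (length(x) < 100) abort_domain("need >= 100 events")
  if (any(x < 0)) abort_domain("intensities must be >= 0")
  if (is.null(threshold)) {
    if (is.null(control))
      abort_config("either a control sample or an explicit threshold is required")
    threshold <- quantile(as.numeric(control), control_quantile, names = FALSE)
  }
  pos <- x > threshold
  affinity <- 100 * mean(pos)
  capacity <- if (any(pos)) {
    if (stat == "median") median(x[pos]) else mean(x[pos])
  } else NA_real_
  list(affinity_pct = affinity, capacity_mfi = capacity,
       threshold = threshold, n_events = length(x), n_positive = sum(pos))
}
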