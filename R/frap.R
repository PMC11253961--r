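# FRAP trace normalization.  The region-of-interest signal is background
# subtracted using an extracellular ROI and divided by a reference
# compartment (whole cell for free GFP-NLS, whole nucleus for GapR-GFP)
# to correct for acquisition photobleaching; the result is rescaled so
# the pre-bleach mean is 1.

#' Normalize a FRAP trace
#'
#' Per frame, the corrected recovery ratio is
#' `(roi - background) / (reference - background)`; the `norm` column
#' additionally rescales this ratio so that the mean over all frames
#' strictly before `bleach_frame` equals 1.  Both the raw ratio and the
#' pre-bleach-normalized series are returned, since reports differ in
#' which of the two they plot.
#'
#' @param trace data frame with columns `time_s`, `roi`, `reference`,
#'   `background` (equal length, times strictly increasing).
#' @param bleach_frame index of the first post-bleach frame (at least 2,
#'   so a pre-bleach window exists).
#' @return tibble `time_s`, `ratio`, `norm`, `phase`
#'   (`"pre"`/`"post"`), with `bleach_frame` attached as an attribute.
#' @export
normalize_trace <- function(trace, bleach_frame) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "roi", "reference", "background") %in% names(trace)))
  n <- nrow(trace)
  if (any(diff(trace$time_s) <= 0)) abort("`time_s` must be strictly increasing.")
  if (bleach_frame < 2 || bleach_frame > n) {
    abort("`bleach_frame` must lie in [2, n] so a pre-bleach window exists.")
  }
  ref_corr <- trace$reference - trace$background
  if (any(ref_corr <= 0)) {
    abort(sprintf("corrected reference is non-positive at frame %d.",
                  which(ref_corr <= 0)[1]))
  }
  ratio <- (trace$roi - trace$background) / ref_corr
  pre <- seq_len(bleach_frame - 1)
  scale <- mean(ratio[pre])
  out <- tibble(
    time_s = trace$time_s,
    ratio = ratio,
    norm = ratio / scale,
    phase = ifelse(seq_len(n) < bleach_frame, "pre", "post")
  )
  attr(out, "bleach_frame") <- bleach_frame
  out
}

#' Plateau estimate of a normalized recovery curve
#'
#' Mean of the final `tail_fraction` of frames of the `norm` series.  No
#' kinetic model is fitted; the plateau is a robust summary of the
#' recovered fraction when acquisition extends well past the recovery
#' half-time.
#'
#' @param trace output of [normalize_trace()].
#' @param tail_fraction fraction of trailing frames averaged.
#' @return scalar plateau estimate.
#' @export
frap_plateau <- function(trace, tail_fraction = 0.1) {
  stopifnot(is.data.frame(trace), "norm" %in% names(trace))
  n <- nrow(trace)
  k <- max(1L, ceiling(tail_fraction * n))
  mean(tail(trace$norm, k))
}

#' Average recovery across cells
#'
#' Pointwise mean and sample standard deviation over a set of normalized
#' traces.  Traces on different time bases are resampled onto the first
#' trace's time base by linear interpolation; time points outside a
#' trace's range are dropped from that trace's contribution.
#'
#' @param traces list of [normalize_trace()] outputs.
#' @return a `frap_summary` tibble: `time_s`, `mean`, `sd`, `n`.
#' @export
average_recovery <- function(traces) {
  if (length(traces) == 0L) abort("`traces` is empty.")
  base <- traces[[1]]$time_s
  mat <- vapply(traces, function(tr) {
    if (identical(tr$time_s, base)) {
      tr$norm
    } else {
      approx(tr$time_s, tr$norm, xout = base, rule = 1)$y
    }
  }, numeric(length(base)))
  mat <- matrix(mat, nrow = length(base))
  out <- tibble(
    time_s = base,
    mean = rowMeans(mat, na.rm = TRUE),
    sd = apply(mat, 1, sd, na.rm = TRUE),
    n = apply(mat, 1, function(r) sum(!is.na(r)))
  )
  class(out) <- c("frap_summary", class(out))
  out
}
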