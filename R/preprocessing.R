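#' Band-pass filter into the fast-ripple band
#'
#' Causal (forward-only) Butterworth band-pass filtering. The default
#' 250-500 Hz band and order-2 design approximate the Tow-Thomas analog
#' filters of the neuromorphic front end; filtering is causal because the
#' emulated device runs in real time. The order is that of the low-pass
#' prototype, so the band-pass transfer function has `2 * order` poles and
#' its gain is 1/sqrt(2) at both band edges.
#'
#' @param x numeric signal (microvolts).
#' @param fs sampling rate (Hz); must exceed `2 * high`.
#' @param low,high band edges in Hz (defaults 250 and 500).
#' @param order low-pass prototype order (default 2).
#' @return Filtered signal, same length as `x`.
#' @examples
#' fs <- 2000
#' x <- sin(2 * pi * 375 * seq(0, 1, by = 1 / fs))
#' y <- bandpassFilter(x, fs)
#' @export
bandpassFilter <- function(x, fs, low = 250, high = 500, order = 2) {
  if (!(low > 0 && low < high))
    stop("band edges must satisfy 0 < low < high")
  if (fs <= 2 * high)
    stop("sampling rate must exceed twice the upper band edge (Nyquist)")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filter(bf, x))
}

#' Estimate the per-channel baseline amplitude
#'
#' From a window of the band-passed signal (default: its first second),
#' stores the maximum absolute amplitude of consecutive non-overlapping
#' 50 ms sub-windows and returns the mean of the lowest quartile of those
#' maxima as the baseline amplitude. With the default 1 s / 50 ms split
#' there are 20 maxima and the lowest quartile is the 5 smallest; for other
#' counts the lowest quartile is `floor(n / 4)` values, at least 1.
#'
#' @param filtered band-passed signal (microvolts).
#' @param fs sampling rate (Hz).
#' @param windowS baseline window length in seconds (default 1).
#' @param subwindowS sub-window length in seconds (default 0.05).
#' @return A list of class `baselineEstimate` with elements `amplitude`
#'   (microvolts), `subMaxima`, `windowS`, `subwindowS`, `quartileFraction`.
#' @export
estimateBaseline <- function(filtered, fs, windowS = 1, subwindowS = 0.05) {
  nWin <- round(windowS * fs)
  if (length(filtered) < nWin)
    stop("signal shorter than the baseline window (", windowS, " s)")
  nSub <- round(subwindowS * fs)
  nBlocks <- floor(nWin / nSub)
  seg <- abs(filtered[seq_len(nBlocks * nSub)])
  maxima <- vapply(seq_len(nBlocks), function(b)
    max(seg[((b - 1) * nSub + 1):(b * nSub)]), 0)
  k <- max(1L, floor(nBlocks / 4))
  amp <- mean(sort(maxima)[seq_len(k)])
  structure(list(amplitude = amp, subMaxima = maxima, windowS = windowS,
                 subwindowS = subwindowS, quartileFraction = 0.25),
            class = "baselineEstimate")
}

#' Delta-modulator threshold from the baseline amplitude
#'
#' The signal-to-spike threshold is set at a fixed fraction (default 50%)
#' of the pre-recorded baseline amplitude. A flat channel (zero baseline)
#' cannot be encoded and raises a degenerate-channel error, which the
#' pipeline catches to skip the channel with a warning.
#'
#' @param baseline a `baselineEstimate` (from [estimateBaseline()]) or a
#'   bare non-negative amplitude in microvolts.
#' @param fraction fraction of the baseline amplitude (default 0.5).
#' @return Threshold in microvolts.
#' @export
deltaThreshold <- function(baseline, fraction = 0.5) {
  amp <- if (inherits(baseline, "baselineEstimate")) baseline$amplitude
         else as.numeric(baseline)
  if (!is.finite(amp) || amp < 0) stop("invalid baseline amplitude")
  if (amp == 0)
    stop(degenerateChannelError("flat channel: zero baseline amplitude"))
  fraction * amp
}

degenerateChannelError <- function(msg) {
  structure(class = c("snnHFO_degenerate_channel", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' @export
print.baselineEstimate <- function(x, ...) {
  cat(sprintf("Baseline amplitude: %.4g uV (mean of lowest quartile of %d sub-window maxima)\n",
              x$amplitude, length(x$subMaxima)))
  invisible(x)
}
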