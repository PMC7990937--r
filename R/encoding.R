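#' Upsample a signal by linear interpolation
#'
#' Linearly interpolates onto a uniform grid at `fsOut` spanning the same
#' time interval as the input. The delta-modulator emulation approximates an
#' asynchronous converter on a dense grid, so the signal is over-sampled
#' (default 35 kHz) before encoding; the over-sampling period must be much
#' smaller than the modulator's refractory period.
#'
#' @param x numeric signal.
#' @param fsIn input sampling rate (Hz).
#' @param fsOut output sampling rate (Hz); must exceed `fsIn`.
#' @return The interpolated signal on the `fsOut` grid.
#' @export
upsampleSignal <- function(x, fsIn, fsOut = 35000) {
  if (fsOut <= fsIn)
    stop("fsOut must exceed fsIn")
  n <- length(x)
  if (n < 2) return(x)
  tIn <- (seq_len(n) - 1) / fsIn
  tOut <- seq(0, tIn[n], by = 1 / fsOut)
  stats::approx(tIn, x, xout = tOut, method = "linear")$y
}

#' Encode a signal into UP/DN spike trains (delta modulation)
#'
#' Emulates an analog delta modulator on the over-sampled grid: an error
#' signal tracks the input relative to its value at the last tracking reset;
#' when the error rises above `+threshold` an UP spike is emitted, when it
#' falls below `-threshold` a DN spike. After each spike the error is held at
#' zero for the refractory period (default 300 microseconds), after which
#' tracking resumes from the signal value at refractory expiry. One modulator
#' serves both polarities, so UP and DN share the refractory clock.
#'
#' Spike times are scale invariant: encoding `c * x` with threshold
#' `c * threshold` reproduces the spike times of `x` with `threshold`
#' exactly, which makes the whole detector amplitude-scale invariant.
#'
#' @param x signal on the over-sampled grid (microvolts).
#' @param fs sampling rate of `x` (Hz, default 35000).
#' @param threshold delta threshold (microvolts), positive.
#' @param refractory refractory hold in seconds (default 3e-4).
#' @return A [SpikeTrain-class].
#' @examples
#' x <- sin(2 * pi * 300 * seq(0, 0.1, by = 1 / 35000))
#' st <- admEncode(x, threshold = 0.4)
#' length(upTimes(st))
#' @export
admEncode <- function(x, fs = 35000, threshold, refractory = 3e-4) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0)
    stop("threshold must be a single positive number")
  if (refractory < 0) stop("refractory must be >= 0")
  if (refractory > 0 && 1 / fs > refractory / 2)
    warning("over-sampling period is not much smaller than the refractory period")
  res <- adm_encode_cpp(as.numeric(x), fs, threshold, refractory)
  SpikeTrain(up = res$up, dn = res$dn, duration = length(x) / fs,
             threshold = threshold, refractory = refractory,
             fsOversample = fs)
}

#' Read/write a spike train as TSV
#'
#' Serialization of a [SpikeTrain-class] as a two-column TSV
#' (`time_s`, `polarity` with values `UP`/`DN`).
#'
#' @param st a [SpikeTrain-class].
#' @param path output file.
#' @return `writeSpikeTrain()` returns `path` invisibly; `readSpikeTrain()`
#'   returns a [SpikeTrain-class].
#' @export
writeSpikeTrain <- function(st, path) {
  stopifnot(is(st, "SpikeTrain"))
  df <- rbind(
    data.frame(time_s = upTimes(st), polarity = "UP"),
    data.frame(time_s = dnTimes(st), polarity = "DN"))
  df <- df[order(df$time_s), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpikeTrain
#' @param duration duration in seconds; when `NULL`, taken as just past the
#'   last spike.
#' @param threshold,refractory,fsOversample metadata for the reconstructed
#'   train (not stored in the TSV).
#' @export
readSpikeTrain <- function(path, duration = NULL, threshold = NA_real_,
                           refractory = 3e-4, fsOversample = 35000) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("numeric", "character"))
  if (is.null(duration))
    duration <- if (nrow(df)) max(df$time_s) + 1 / fsOversample else 0
  SpikeTrain(up = sort(df$time_s[df$polarity == "UP"]),
             dn = sort(df$time_s[df$polarity == "DN"]),
             duration = duration, threshold = threshold,
             refractory = refractory, fsOversample = fsOversample)
}
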