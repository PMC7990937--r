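#' Specification of a synthetic ECoG benchmark
#'
#' Parameters of the synthetic-data generator. The defaults emulate the
#' regime the artifact-rejection stage was calibrated for: 1/f-shaped
#' background noise at ECoG-like amplitude, fast-ripple bursts with duration
#' drawn around a 24 ms median (producing about 6 UP-DN spike cycles after
#' encoding) and sharp biphasic transients of 2-3 ms width (producing at
#' most a couple of cycles of filter ringing).
#'
#' @param fs sampling rate in Hz (default 2000).
#' @param duration recording duration in seconds (default 180).
#' @param nChannels number of channels (default 4).
#' @param backgroundRms background noise RMS in microvolts (default 15).
#' @param spectralSlope power-spectral slope magnitude of the background
#'   (default 1, i.e. 1/f power).
#' @param nHfo,nTransient number of injected events (defaults 50 and 50).
#' @param hfoDurationMeanMs,hfoDurationSdMs normal distribution of HFO burst
#'   durations in ms (defaults 24 and 4, truncated at 10 ms).
#' @param hfoFreqRange oscillation frequency range in Hz (default 250-500).
#' @param hfoRelAmplitude HFO peak amplitude relative to the channel's
#'   filtered baseline amplitude (default 3).
#' @param transientWidthRangeMs biphasic transient width range in ms
#'   (default 2-3; below ~2 ms the post-filter ringing falls outside the
#'   fast-ripple band and yields almost no spike cycles).
#' @param transientRelAmplitude transient peak amplitude relative to the
#'   channel's filtered baseline (default 6).
#' @param guardS events are kept this far from the recording edges and the
#'   baseline-estimation second (default 1.5 s) and from each other.
#' @param seed integer seed; the full benchmark is reproducible from it.
#' @return A list of class `syntheticSpec`.
#' @export
syntheticSpec <- function(fs = 2000, duration = 180, nChannels = 4,
                          backgroundRms = 15, spectralSlope = 1,
                          nHfo = 50, nTransient = 50,
                          hfoDurationMeanMs = 24, hfoDurationSdMs = 4,
                          hfoFreqRange = c(250, 500), hfoRelAmplitude = 3,
                          transientWidthRangeMs = c(2, 3),
                          transientRelAmplitude = 6,
                          guardS = 1.5, seed = 1) {
  spec <- as.list(environment())
  class(spec) <- "syntheticSpec"
  spec
}

#' Generate 1/f background noise
#'
#' Gaussian noise shaped in the frequency domain so that the periodogram
#' falls off as `1/f^spectralSlope`, scaled to the configured RMS per
#' channel. Identical seeds give identical samples.
#'
#' @param spec a [syntheticSpec()].
#' @return A [Recording-class] in microvolts.
#' @export
generateBackground <- function(spec) {
  set.seed(as.integer(spec$seed))
  n <- round(spec$fs * spec$duration)
  x <- matrix(0, nrow = spec$nChannels, ncol = n)
  if (spec$backgroundRms > 0) {
    freqs <- seq_len(floor(n / 2))
    shape <- freqs^(-spec$spectralSlope / 2)
    for (ch in seq_len(spec$nChannels)) {
      white <- stats::rnorm(n)
      sp <- stats::fft(white)
      scale <- numeric(n)
      scale[1] <- 0                       # no DC
      scale[freqs + 1] <- shape
      # mirror for the conjugate half (indices n, n-1, ...)
      scale[n + 1 - freqs] <- shape
      y <- Re(stats::fft(sp * scale, inverse = TRUE)) / n
      y <- y / stats::sd(y) * spec$backgroundRms
      x[ch, ] <- y
    }
  }
  Recording(x, fs = spec$fs,
            channelLabels = paste0("ch", seq_len(spec$nChannels)))
}

channelBaselineAmplitude <- function(rec, channel) {
  x <- samples(rec)[channel, ]
  filt <- bandpassFilter(x, samplingRate(rec))
  estimateBaseline(filt, samplingRate(rec))$amplitude
}

#' Inject a fast-ripple burst
#'
#' Adds a Hann-windowed sinusoidal burst at a fast-ripple frequency, scaled
#' to a multiple of the channel's filtered-baseline amplitude. Samples
#' outside the burst are untouched.
#'
#' @param rec a [Recording-class].
#' @param channel channel label or index.
#' @param t onset in seconds.
#' @param durationMs burst duration in ms.
#' @param freqHz oscillation frequency, must lie in 250-500 Hz.
#' @param relAmplitude peak amplitude relative to the channel's filtered
#'   baseline; `baselineAmp` can pre-supply that baseline (microvolts).
#' @param baselineAmp optional precomputed baseline amplitude.
#' @return list with `recording` (modified) and `truth` (one-row data.frame
#'   `channel`, `start_s`, `end_s`, `kind = "hfo"`).
#' @export
injectHfo <- function(rec, channel, t, durationMs, freqHz, relAmplitude,
                      baselineAmp = NULL) {
  if (freqHz < 250 || freqHz > 500)
    stop("HFO frequency must lie in the fast-ripple band (250-500 Hz)")
  fs <- samplingRate(rec)
  durS <- durationMs * 1e-3
  if (t < 0 || t + durS > duration(rec))
    stop("burst does not fit inside the recording")
  chIdx <- if (is.character(channel)) match(channel, channelLabels(rec))
           else as.integer(channel)
  if (is.na(chIdx)) stop("unknown channel")
  if (relAmplitude != 0) {
    if (is.null(baselineAmp))
      baselineAmp <- channelBaselineAmplitude(rec, chIdx)
    i0 <- round(t * fs) + 1
    nb <- max(2L, round(durS * fs))
    tau <- (seq_len(nb) - 1) / fs
    hann <- 0.5 * (1 - cos(2 * pi * (seq_len(nb) - 1) / (nb - 1)))
    burst <- relAmplitude * baselineAmp * hann * sin(2 * pi * freqHz * tau)
    rec@samples[chIdx, i0:(i0 + nb - 1)] <-
      rec@samples[chIdx, i0:(i0 + nb - 1)] + burst
  }
  list(recording = rec,
       truth = data.frame(channel = channelLabels(rec)[chIdx],
                          start_s = t, end_s = t + durS, kind = "hfo"))
}

#' Inject a sharp biphasic transient
#'
#' Adds a single-cycle windowed sine deflection of the given width --- a
#' sharp biphasic artifact which, after band-pass filtering into the
#' fast-ripple band, rings for only about two UP-DN cycles.
#'
#' @inheritParams injectHfo
#' @param widthMs total width of the biphasic deflection in ms.
#' @return list with `recording` and `truth` (`kind = "transient"`).
#' @export
injectTransient <- function(rec, channel, t, widthMs, relAmplitude,
                            baselineAmp = NULL) {
  fs <- samplingRate(rec)
  widthS <- widthMs * 1e-3
  if (t < 0 || t + widthS > duration(rec))
    stop("transient does not fit inside the recording")
  chIdx <- if (is.character(channel)) match(channel, channelLabels(rec))
           else as.integer(channel)
  if (is.na(chIdx)) stop("unknown channel")
  if (relAmplitude != 0) {
    if (is.null(baselineAmp))
      baselineAmp <- channelBaselineAmplitude(rec, chIdx)
    i0 <- round(t * fs) + 1
    nb <- max(2L, round(widthS * fs))
    ph <- (seq_len(nb) - 1) / (nb - 1)
    hann <- 0.5 * (1 - cos(2 * pi * ph))
    pulse <- relAmplitude * baselineAmp * hann * sin(2 * pi * ph)
    rec@samples[chIdx, i0:(i0 + nb - 1)] <-
      rec@samples[chIdx, i0:(i0 + nb - 1)] + pulse
  }
  list(recording = rec,
       truth = data.frame(channel = channelLabels(rec)[chIdx],
                          start_s = t, end_s = t + widthS,
                          kind = "transient"))
}

#' Build the ground-truthed synthetic benchmark
#'
#' Generates the background, then injects the configured numbers of
#' fast-ripple bursts and sharp transients at random, non-overlapping
#' positions (events keep `guardS` seconds from the edges, from the
#' baseline-estimation window and from each other on the same channel).
#' Event amplitudes are scaled to each channel's filtered-baseline amplitude
#' computed on the clean background, so injection order does not matter.
#' Everything is reproducible from `spec$seed`.
#'
#' @param spec a [syntheticSpec()].
#' @return A list with `recording` ([Recording-class]), `truth` (data.frame
#'   `channel`, `start_s`, `end_s`, `kind`, sorted) and `spec`.
#' @export
makeBenchmark <- function(spec = syntheticSpec()) {
  rec <- generateBackground(spec)
  # RNG state continues from generateBackground's seed; re-seed for layout
  set.seed(as.integer(spec$seed) + 1L)
  base <- vapply(seq_len(spec$nChannels),
                 function(ch) channelBaselineAmplitude(rec, ch), 0)
  nEv <- spec$nHfo + spec$nTransient
  kind <- c(rep("hfo", spec$nHfo), rep("transient", spec$nTransient))
  durS <- numeric(nEv)
  freq <- width <- numeric(nEv)
  for (i in seq_len(nEv)) {
    if (kind[i] == "hfo") {
      durS[i] <- max(10, stats::rnorm(1, spec$hfoDurationMeanMs,
                                      spec$hfoDurationSdMs)) * 1e-3
      freq[i] <- stats::runif(1, spec$hfoFreqRange[1], spec$hfoFreqRange[2])
    } else {
      width[i] <- stats::runif(1, spec$transientWidthRangeMs[1],
                               spec$transientWidthRangeMs[2])
      durS[i] <- width[i] * 1e-3
    }
  }
  chan <- rep(seq_len(spec$nChannels), length.out = nEv)
  chan <- chan[sample(nEv)]
  lo <- spec$guardS
  hi <- spec$duration - spec$guardS
  onset <- numeric(nEv)
  placed <- vector("list", spec$nChannels)
  for (i in seq_len(nEv)) {
    ok <- FALSE
    for (try in 1:500) {
      t0 <- stats::runif(1, lo, hi - durS[i])
      iv <- c(t0 - spec$guardS, t0 + durS[i] + spec$guardS)
      clash <- any(vapply(placed[[chan[i]]], function(p)
        iv[1] < p[2] && p[1] < iv[2], TRUE))
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place events without overlap; reduce the event count")
    onset[i] <- t0
    placed[[chan[i]]] <- c(placed[[chan[i]]], list(c(t0, t0 + durS[i])))
  }
  truth <- NULL
  for (i in seq_len(nEv)) {
    res <- if (kind[i] == "hfo") {
      injectHfo(rec, chan[i], onset[i], durS[i] * 1e3, freq[i],
                spec$hfoRelAmplitude, baselineAmp = base[chan[i]])
    } else {
      injectTransient(rec, chan[i], onset[i], width[i],
                      spec$transientRelAmplitude, baselineAmp = base[chan[i]])
    }
    rec <- res$recording
    truth <- rbind(truth, res$truth)
  }
  truth <- truth[order(truth$channel, truth$start_s), , drop = FALSE]
  rownames(truth) <- NULL
  list(recording = rec, truth = truth, spec = spec)
}

#' Write/read a ground-truth manifest
#'
#' BED-like TSV with columns `channel`, `start_s`, `end_s`, `kind`.
#'
#' @param truth data.frame as produced by [makeBenchmark()].
#' @param path TSV file.
#' @return `path` invisibly, or the manifest data.frame.
#' @export
writeManifest <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "numeric", "numeric",
                                   "character"))
}

#' Deterministic fixture spike trains
#'
#' Idealized UP-DN trains mimicking the encoded snippets the network was
#' calibrated on. `hfoSpikeTrain()` reproduces the fast-ripple regime
#' (default 6 cycles of 2.6 ms repeating every 4.28 ms: a 24 ms train),
#' `transientSpikeTrain()` the sharp-transient regime (2 cycles of 3.2 ms
#' spanning 9 ms). Each cycle is a burst of UP spikes followed by a burst of
#' DN spikes; intra-burst ISIs respect the 300 microsecond encoder
#' refractory.
#'
#' @param nCycles number of UP-DN cycles.
#' @param cycleMs duration of one cycle (first UP to last DN spike), ms.
#' @param periodMs cycle repetition period, ms.
#' @param isiMs intra-burst inter-spike interval, ms.
#' @param spikesPerBurst spikes per UP and per DN burst.
#' @param start onset of the first cycle in seconds.
#' @param duration train container duration in seconds.
#' @return A [SpikeTrain-class].
#' @examples
#' st <- hfoSpikeTrain()
#' nrow(extractCycles(st))  # 6
#' @export
cycleTrain <- function(nCycles, cycleMs, periodMs, isiMs, spikesPerBurst = 3,
                       start = 0.01, duration = 0.06) {
  upOff <- (seq_len(spikesPerBurst) - 1) * isiMs
  dnOff <- cycleMs - rev(upOff)
  up <- dn <- numeric(0)
  for (k in seq_len(nCycles) - 1) {
    up <- c(up, start + (k * periodMs + upOff) * 1e-3)
    dn <- c(dn, start + (k * periodMs + dnOff) * 1e-3)
  }
  SpikeTrain(up = up, dn = dn, duration = duration)
}

#' @rdname cycleTrain
#' @export
hfoSpikeTrain <- function(nCycles = 6, cycleMs = 2.6, periodMs = 4.28,
                          isiMs = 0.4, spikesPerBurst = 3, start = 0.01,
                          duration = 0.06) {
  cycleTrain(nCycles, cycleMs, periodMs, isiMs, spikesPerBurst, start,
             duration)
}

#' @rdname cycleTrain
#' @export
transientSpikeTrain <- function(nCycles = 2, cycleMs = 3.2, periodMs = 5.8,
                                isiMs = 0.6, spikesPerBurst = 3,
                                start = 0.01, duration = 0.06) {
  cycleTrain(nCycles, cycleMs, periodMs, isiMs, spikesPerBurst, start,
             duration)
}
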