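#' Detection pipeline configuration
#'
#' Collects every tunable of the per-channel detection pipeline: band-pass
#' filter, baseline estimation, delta-modulator encoding, network
#' configuration and event marking. All randomness flows from the single
#' `seed`; per-channel Poisson drives use `seed + channel index`.
#'
#' @param low,high,order band-pass specification (defaults 250 Hz, 500 Hz,
#'   order 2).
#' @param windowS,subwindowS baseline estimation windows in seconds.
#' @param thresholdFraction delta threshold as a fraction of the baseline
#'   amplitude (default 0.5).
#' @param baselineMode `"static"` estimates the baseline once from the first
#'   `windowS` seconds; `"blockwise"` re-estimates it for every consecutive
#'   block of `windowS` seconds and encodes each block with its own
#'   threshold.
#' @param fsOversample encoder grid rate in Hz (default 35000).
#' @param refractory encoder refractory in seconds (default 3e-4).
#' @param eventWindowS event marking window in seconds (default 0.015).
#' @param network a [NetworkConfig-class] (default [defaultNetworkConfig()]).
#' @param seed top-level integer seed.
#' @return A list of class `detectConfig`.
#' @export
detectConfig <- function(low = 250, high = 500, order = 2,
                         windowS = 1, subwindowS = 0.05,
                         thresholdFraction = 0.5,
                         baselineMode = c("static", "blockwise"),
                         fsOversample = 35000, refractory = 3e-4,
                         eventWindowS = 0.015,
                         network = defaultNetworkConfig(), seed = 1) {
  baselineMode <- match.arg(baselineMode)
  cfg <- as.list(environment())
  class(cfg) <- "detectConfig"
  cfg
}

encodeChannel <- function(x, fs, cfg) {
  filt <- bandpassFilter(x, fs, cfg$low, cfg$high, cfg$order)
  if (cfg$baselineMode == "static") {
    bl <- estimateBaseline(filt, fs, cfg$windowS, cfg$subwindowS)
    thr <- deltaThreshold(bl, cfg$thresholdFraction)
    upx <- upsampleSignal(filt, fs, cfg$fsOversample)
    st <- admEncode(upx, cfg$fsOversample, thr, cfg$refractory)
    return(list(train = st, baseline = bl$amplitude, threshold = thr))
  }
  # blockwise: encode each baseline window with its own threshold and
  # shift the spikes back to recording time (refractory is not carried
  # across block boundaries)
  nBlock <- round(cfg$windowS * fs)
  nBlocks <- floor(length(x) / nBlock)
  if (nBlocks < 1) stop("recording shorter than one baseline window")
  up <- dn <- numeric(0)
  bl1 <- thr1 <- NA_real_
  for (b in seq_len(nBlocks)) {
    idx <- ((b - 1) * nBlock + 1):(if (b == nBlocks) length(x) else b * nBlock)
    seg <- filt[idx]
    bl <- estimateBaseline(seg, fs, cfg$windowS, cfg$subwindowS)
    thr <- deltaThreshold(bl, cfg$thresholdFraction)
    if (b == 1) { bl1 <- bl$amplitude; thr1 <- thr }
    upx <- upsampleSignal(seg, fs, cfg$fsOversample)
    st <- admEncode(upx, cfg$fsOversample, thr, cfg$refractory)
    off <- (b - 1) * nBlock / fs
    up <- c(up, upTimes(st) + off)
    dn <- c(dn, dnTimes(st) + off)
  }
  list(train = SpikeTrain(up, dn, duration = length(x) / fs,
                          threshold = thr1, refractory = 0,
                          fsOversample = cfg$fsOversample),
       baseline = bl1, threshold = thr1)
}

#' Run the full HFO detection pipeline on a recording
#'
#' For every channel independently: band-pass filter into the fast-ripple
#' band, estimate the baseline amplitude, set the delta threshold, upsample,
#' encode to UP/DN spikes, simulate the spiking network, and mark HFO events
#' from the second-layer raster. Channels with a flat baseline are skipped
#' with a warning. Detections are invariant to a positive rescaling of the
#' input, because the threshold scales with the baseline and the encoder is
#' scale invariant.
#'
#' @param rec a [Recording-class].
#' @param config a [detectConfig()].
#' @param verbose print per-channel baseline, threshold, spike and event
#'   counts.
#' @return A list of class `hfoDetection` with `events` (data.frame across
#'   channels), `rates` (from [computeRates()], all channels), `channels`
#'   (per-channel details: baseline, threshold, spike counts, events) and
#'   `config`.
#' @examples
#' \donttest{
#' bm <- makeBenchmark(syntheticSpec(duration = 20, nHfo = 3, nTransient = 3))
#' det <- detectHfo(bm$recording)
#' det$rates
#' }
#' @export
detectHfo <- function(rec, config = detectConfig(), verbose = FALSE) {
  stopifnot(is(rec, "Recording"))
  net <- buildNetwork(config$network)
  labels <- channelLabels(rec)
  fs <- samplingRate(rec)
  dur <- duration(rec)
  allEvents <- NULL
  chInfo <- vector("list", nChannels(rec))
  names(chInfo) <- labels
  for (ci in seq_along(labels)) {
    enc <- tryCatch(encodeChannel(samples(rec)[ci, ], fs, config),
                    snnHFO_degenerate_channel = function(e) e)
    if (inherits(enc, "condition")) {
      warning("channel ", labels[ci], " skipped: ", conditionMessage(enc))
      chInfo[[ci]] <- list(skipped = TRUE, reason = conditionMessage(enc))
      next
    }
    act <- simulateNetwork(net, enc$train, duration = dur,
                           seed = config$seed + ci)
    slTimes <- secondLayerSpikes(act)
    ev <- markEvents(slTimes, dur, config$eventWindowS, channel = labels[ci])
    allEvents <- rbind(allEvents, ev)
    chInfo[[ci]] <- list(skipped = FALSE, baseline = enc$baseline,
                         threshold = enc$threshold,
                         n_up = length(upTimes(enc$train)),
                         n_dn = length(dnTimes(enc$train)),
                         n_sl_spikes = length(slTimes),
                         n_events = nrow(ev))
    if (verbose)
      message(sprintf(
        "channel %s: baseline %.3g uV, threshold %.3g uV, %d UP / %d DN spikes, %d SL spikes, %d events",
        labels[ci], enc$baseline, enc$threshold,
        length(upTimes(enc$train)), length(dnTimes(enc$train)),
        length(slTimes), nrow(ev)))
  }
  if (is.null(allEvents))
    allEvents <- data.frame(channel = character(0), start_s = numeric(0),
                            end_s = numeric(0))
  active <- labels[!vapply(chInfo, function(x) isTRUE(x$skipped), TRUE)]
  rates <- computeRates(allEvents, dur, channels = active)
  structure(list(events = allEvents, rates = rates, channels = chInfo,
                 config = config),
            class = "hfoDetection")
}

#' @export
print.hfoDetection <- function(x, ...) {
  cat(sprintf("HFO detection: %d event(s) on %d channel(s)\n",
              nrow(x$events), nrow(x$rates)))
  print(x$rates)
  invisible(x)
}

#' Score detections against a ground-truth manifest
#'
#' An injected event counts as hit when at least one detected event on the
#' same channel overlaps its `[start_s, end_s)` interval. Sensitivity is the
#' hit fraction of injected HFOs; the transient false-marking rate is the
#' hit fraction of injected transients.
#'
#' @param events detected events (data.frame `channel`, `start_s`, `end_s`).
#' @param truth manifest data.frame (`channel`, `start_s`, `end_s`, `kind`).
#' @param toleranceS slack added around each truth interval when testing
#'   overlap (default 0.015 s, one marking window).
#' @return A list with `sensitivity`, `transient_false_rate`, `n_hfo`,
#'   `n_hfo_hit`, `n_transient`, `n_transient_hit`, and the per-event `hit`
#'   vector.
#' @export
evaluateBenchmark <- function(events, truth, toleranceS = 0.015) {
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    ev <- events[events$channel == truth$channel[i], , drop = FALSE]
    any(ev$start_s < truth$end_s[i] + toleranceS &
        ev$end_s > truth$start_s[i] - toleranceS)
  }, TRUE)
  isH <- truth$kind == "hfo"
  list(sensitivity = if (any(isH)) mean(hit[isH]) else NA_real_,
       transient_false_rate = if (any(!isH)) mean(hit[!isH]) else NA_real_,
       n_hfo = sum(isH), n_hfo_hit = sum(hit & isH),
       n_transient = sum(!isH), n_transient_hit = sum(hit & !isH),
       hit = hit)
}

#' Dump a resolved configuration as JSON
#'
#' Serializes a [detectConfig()] (including the full network
#' parameterization) next to pipeline outputs, as the provenance record of
#' a run.
#'
#' @param config a [detectConfig()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
writeConfig <- function(config, path) {
  net <- config$network
  netList <- lapply(slotNames(net), function(s) slot(net, s))
  names(netList) <- slotNames(net)
  out <- config
  out$network <- netList
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
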