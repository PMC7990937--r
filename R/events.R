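#' Mark HFO events from second-layer spikes
#'
#' Partitions `[0, duration)` into consecutive 15 ms windows anchored at the
#' recording start; a window containing any second-layer spike is active,
#' and maximal runs of consecutive active windows are concatenated into
#' single HFO events. Event boundaries therefore lie on the window grid and
#' every spike falls inside exactly one event.
#'
#' @param spikeTimes pooled second-layer spike times in seconds (may be an
#'   `snnActivity`, whose pooled spikes are used).
#' @param duration recording duration in seconds.
#' @param windowS marking window in seconds (default 0.015).
#' @param channel channel label attached to the events.
#' @return data.frame with columns `channel`, `start_s`, `end_s` (half-open
#'   intervals, pairwise disjoint, sorted).
#' @examples
#' markEvents(c(0.010, 0.020), duration = 1)  # one event [0, 0.030)
#' @export
markEvents <- function(spikeTimes, duration, windowS = 0.015,
                       channel = NA_character_) {
  if (inherits(spikeTimes, "snnActivity"))
    spikeTimes <- secondLayerSpikes(spikeTimes)
  spikeTimes <- as.numeric(spikeTimes)
  empty <- data.frame(channel = character(0), start_s = numeric(0),
                      end_s = numeric(0))
  if (!length(spikeTimes)) return(empty)
  if (min(spikeTimes) < 0 || max(spikeTimes) >= duration)
    stop("spike times must lie within [0, duration)")
  win <- sort(unique(floor(spikeTimes / windowS)))
  runStart <- win[c(TRUE, diff(win) > 1)]
  runEnd <- win[c(diff(win) > 1, TRUE)]
  data.frame(channel = channel,
             start_s = runStart * windowS,
             end_s = (runEnd + 1) * windowS)
}

#' Per-channel HFO rates
#'
#' The HFO rate of a channel is the number of detected events divided by the
#' recording duration in minutes.
#'
#' @param events data.frame of events (`channel`, `start_s`, `end_s`).
#' @param duration recording duration in seconds (> 0).
#' @param channels optional vector of all channel labels, so channels with
#'   zero events are reported too.
#' @return data.frame with columns `channel`, `n_events`, `duration_min`,
#'   `rate_per_min`.
#' @export
computeRates <- function(events, duration, channels = NULL) {
  if (duration <= 0) stop("duration must be positive")
  if (is.null(channels)) channels <- unique(events$channel)
  counts <- vapply(channels, function(ch) sum(events$channel == ch), 0L)
  data.frame(channel = as.character(channels),
             n_events = as.integer(counts),
             duration_min = rep(duration / 60, length(channels)),
             rate_per_min = counts / (duration / 60),
             row.names = NULL)
}

#' Channel with the maximal HFO rate
#'
#' Selects the recording channel with the highest HFO rate; ties are broken
#' by the lexicographically first label.
#'
#' @param rates data.frame from [computeRates()] (>= 1 row).
#' @return The selected single-row data.frame.
#' @export
maxChannelRate <- function(rates) {
  if (!nrow(rates)) stop("no channels to select from")
  best <- rates[rates$rate_per_min == max(rates$rate_per_min), , drop = FALSE]
  best <- best[order(best$channel), , drop = FALSE]
  best[1, , drop = FALSE]
}

#' Write detected events as BED-like TSV
#'
#' @param events data.frame of events.
#' @param path output TSV with columns `channel`, `start_s`, `end_s`.
#' @return `path`, invisibly.
#' @export
writeEvents <- function(events, path) {
  utils::write.table(events[, c("channel", "start_s", "end_s")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
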