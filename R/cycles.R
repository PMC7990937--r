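#' Extract UP-DN cycles from a spike train
#'
#' Merges the UP and DN streams in time order and run-length encodes the
#' polarity sequence: a burst is a maximal run of same-polarity spikes, and
#' an UP-DN cycle is an UP burst immediately followed by a DN burst. The
#' cycle duration runs from the first UP spike of the cycle to the last DN
#' spike. A DN burst preceding the first UP burst closes no cycle, and a
#' trailing unmatched UP burst is ignored.
#'
#' @param train a [SpikeTrain-class].
#' @return data.frame with one row per cycle: `start_s`, `end_s`,
#'   `duration_s`, `n_up`, `n_dn`.
#' @examples
#' st <- SpikeTrain(up = c(1, 2, 5) * 1e-3, dn = c(3, 4, 6) * 1e-3,
#'                  duration = 0.01, refractory = 0)
#' extractCycles(st)  # 2 cycles
#' @export
extractCycles <- function(train) {
  stopifnot(is(train, "SpikeTrain"))
  t <- c(upTimes(train), dnTimes(train))
  pol <- rep(c(1L, -1L), c(length(upTimes(train)), length(dnTimes(train))))
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), n_up = integer(0),
                      n_dn = integer(0))
  if (length(t) < 2) return(empty)
  o <- order(t)
  t <- t[o]; pol <- pol[o]
  r <- rle(pol)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  isCycle <- which(r$values[-length(r$values)] == 1L &
                   r$values[-1] == -1L)
  if (!length(isCycle)) return(empty)
  data.frame(
    start_s = t[starts[isCycle]],
    end_s = t[ends[isCycle + 1]],
    duration_s = t[ends[isCycle + 1]] - t[starts[isCycle]],
    n_up = r$lengths[isCycle],
    n_dn = r$lengths[isCycle + 1])
}

#' Within-burst inter-spike intervals of a train
#'
#' Inter-spike intervals computed inside each same-polarity burst (runs of
#' length one contribute none).
#'
#' @param train a [SpikeTrain-class].
#' @return Numeric vector of ISIs in seconds.
#' @export
burstISIs <- function(train) {
  t <- c(upTimes(train), dnTimes(train))
  pol <- rep(c(1L, -1L), c(length(upTimes(train)), length(dnTimes(train))))
  if (length(t) < 2) return(numeric(0))
  o <- order(t)
  t <- t[o]; pol <- pol[o]
  d <- diff(t)
  d[pol[-1] == pol[-length(pol)]]
}

#' Summary statistics of encoded snippets
#'
#' For a set of encoded snippets, quantifies (1) the spike-train duration
#' (last spike minus first spike), (2) the number of UP-DN cycles and
#' (3) the cycle durations, reporting medians: durations and cycle counts
#' across trains, cycle durations pooled across all cycles of all trains
#' (per-train medians are available via `pool = FALSE`). These statistics
#' characterize the separation the artifact-rejection stage exploits:
#' genuine fast-ripple oscillations yield long trains of many short cycles,
#' sharp transients yield short trains of few, longer cycles.
#'
#' @param trains list of [SpikeTrain-class] objects (>= 1).
#' @param pool pool cycle durations across trains (default) or median the
#'   per-train medians.
#' @return A list with `median_train_duration_ms`, `median_n_cycles`,
#'   `median_cycle_duration_ms`, `median_isi_ms`, `n_trains`, `n_cycles`.
#' @export
snippetStats <- function(trains, pool = TRUE) {
  if (!length(trains)) stop("need at least one spike train")
  durs <- vapply(trains, function(tr) {
    t <- c(upTimes(tr), dnTimes(tr))
    if (length(t) < 2) 0 else max(t) - min(t)
  }, 0)
  cyc <- lapply(trains, extractCycles)
  counts <- vapply(cyc, nrow, 0L)
  cycDur <- if (pool) unlist(lapply(cyc, `[[`, "duration_s"))
            else vapply(cyc, function(cd)
              if (nrow(cd)) stats::median(cd$duration_s) else NA_real_, 0)
  isis <- unlist(lapply(trains, burstISIs))
  list(median_train_duration_ms = stats::median(durs) * 1e3,
       median_n_cycles = stats::median(counts),
       median_cycle_duration_ms =
         if (length(cycDur)) stats::median(cycDur, na.rm = TRUE) * 1e3 else NA_real_,
       median_isi_ms = if (length(isis)) stats::median(isis) * 1e3 else NA_real_,
       n_trains = length(trains), n_cycles = sum(counts))
}
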