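#' Read a multichannel recording
#'
#' Reads either the package's matrix container (a raw little-endian float64
#' array with a JSON sidecar holding `fs`, `labels` and `units`) or an
#' EDF/EDF+ file. Samples are always returned in microvolts in a referential
#' montage; EDF physical dimensions of V/mV/uV are rescaled on read.
#'
#' @param path for `format = "matrix"` the path prefix (the files
#'   `<path>.dat` and `<path>.json` are read); for `format = "edf"` the EDF
#'   file itself.
#' @param format `"matrix"` or `"edf"`; defaults to `"edf"` when `path` ends
#'   in `.edf`.
#' @return A [Recording-class] in microvolts, referential montage.
#' @seealso [writeRecording()]
#' @export
readRecording <- function(path, format = c("auto", "matrix", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  if (format == "edf") return(readEDF(path))
  jsonPath <- paste0(path, ".json")
  datPath <- paste0(path, ".dat")
  if (!file.exists(jsonPath) || !file.exists(datPath))
    stop("matrix container not found at prefix '", path, "'")
  meta <- jsonlite::fromJSON(jsonPath)
  for (f in c("fs", "labels", "units", "n_channels", "n_samples"))
    if (is.null(meta[[f]])) stop("matrix container sidecar misses field '", f, "'")
  if (!is.numeric(meta$fs) || length(meta$fs) != 1 || meta$fs <= 0)
    stop("matrix container declares an invalid sampling rate")
  nch <- as.integer(meta$n_channels)
  ns <- as.integer(meta$n_samples)
  vals <- readBin(datPath, what = "double", n = nch * ns, size = 8,
                  endian = "little")
  if (length(vals) != nch * ns)
    stop("matrix container payload is truncated")
  x <- matrix(vals, nrow = nch, byrow = FALSE)
  scale <- unitScaleToMicrovolt(meta$units)
  Recording(x * scale, fs = meta$fs, channelLabels = meta$labels,
            montage = if (!is.null(meta$montage)) meta$montage else "referential")
}

#' Write a recording to the matrix container
#'
#' @param rec a [Recording-class].
#' @param path path prefix; writes `<path>.dat` (float64 little-endian,
#'   channel-major) and `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "Recording"))
  writeBin(as.numeric(samples(rec)), paste0(path, ".dat"), size = 8,
           endian = "little")
  meta <- list(fs = samplingRate(rec), labels = channelLabels(rec),
               units = "uV", n_channels = nChannels(rec),
               n_samples = nSamples(rec), montage = montage(rec),
               storage = "float64 little-endian, channel-major (column = channel)")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

unitScaleToMicrovolt <- function(units) {
  u <- tolower(trimws(units))
  u <- sub("µ", "u", u)
  switch(u,
         "uv" = 1, "mv" = 1e3, "v" = 1e6,
         stop("unsupported physical unit '", units, "'"))
}

# Minimal EDF/EDF+ reader: ASCII header plus int16 little-endian data
# records, linear digital-to-physical scaling per signal. All signals must
# share one sampling rate (heterogeneous-rate files are rejected).
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) {
    raw <- readBin(con, "raw", n = nchars)
    if (length(raw) < nchars) stop("EDF header truncated")
    trimws(rawToChar(raw))
  }
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)            # patient, recording, date, time
  rd(8)                                   # header length
  rd(44)                                  # reserved
  nRecords <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  nSig <- as.integer(rd(4))
  if (is.na(nSig) || nSig < 1) stop("EDF declares no signals")
  if (is.na(recDur) || recDur <= 0)
    stop("EDF declares a missing or contradictory record duration")
  labels <- vapply(seq_len(nSig), function(i) rd(16), "")
  for (i in seq_len(nSig)) rd(80)         # transducer
  physDim <- vapply(seq_len(nSig), function(i) rd(8), "")
  physMin <- vapply(seq_len(nSig), function(i) as.numeric(rd(8)), 0)
  physMax <- vapply(seq_len(nSig), function(i) as.numeric(rd(8)), 0)
  digMin <- vapply(seq_len(nSig), function(i) as.numeric(rd(8)), 0)
  digMax <- vapply(seq_len(nSig), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(nSig)) rd(80)         # prefilter
  spr <- vapply(seq_len(nSig), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(nSig)) rd(32)         # reserved
  keep <- labels != "EDF Annotations"
  if (!any(keep)) stop("EDF contains no data signals")
  if (length(unique(spr[keep])) != 1)
    stop("EDF signals have heterogeneous sampling rates; not supported")
  if (any(digMax[keep] == digMin[keep]))
    stop("EDF declares a degenerate digital range")
  fs <- spr[keep][1] / recDur
  out <- matrix(0, nrow = sum(keep), ncol = nRecords * spr[keep][1])
  rowOf <- cumsum(keep)
  for (r in seq_len(nRecords)) {
    for (s in seq_len(nSig)) {
      vals <- readBin(con, "integer", n = spr[s], size = 2, signed = TRUE,
                      endian = "little")
      if (length(vals) < spr[s]) stop("EDF data records truncated")
      if (keep[s]) {
        phys <- (vals - digMin[s]) * (physMax[s] - physMin[s]) /
          (digMax[s] - digMin[s]) + physMin[s]
        out[rowOf[s], ((r - 1) * spr[s] + 1):(r * spr[s])] <-
          phys * unitScaleToMicrovolt(physDim[s])
      }
    }
  }
  Recording(out, fs = fs, channelLabels = labels[keep],
            montage = "referential")
}

#' Re-reference to a bipolar montage along the grid
#'
#' Derives bipolar channels as differences of adjacent contacts along each
#' row of the electrode grid (the "length" of the grid): a row
#' `c1 c2 c3` yields channels `c1-c2 = x1 - x2` and `c2-c3 = x2 - x3`.
#' Pairs never wrap across grid rows, so an r x c grid yields r * (c - 1)
#' bipolar channels.
#'
#' @param rec a referential [Recording-class].
#' @param gridLayout character matrix (rows x cols) of contact labels giving
#'   the physical grid geometry; every label must exist in `rec`.
#' @return A [Recording-class] with `montage = "bipolar"` and labels `A-B`.
#' @export
toBipolar <- function(rec, gridLayout) {
  stopifnot(is(rec, "Recording"))
  gridLayout <- as.matrix(gridLayout)
  missing <- setdiff(as.character(gridLayout), channelLabels(rec))
  if (length(missing))
    stop("grid labels absent from recording: ", paste(missing, collapse = ", "))
  x <- samples(rec)
  rows <- nrow(gridLayout); cols <- ncol(gridLayout)
  if (cols < 2) stop("grid must have at least two contacts per row")
  outLabels <- character(0)
  out <- matrix(0, nrow = rows * (cols - 1), ncol = nSamples(rec))
  k <- 0
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols - 1)) {
      a <- gridLayout[r, cc]; b <- gridLayout[r, cc + 1]
      k <- k + 1
      out[k, ] <- x[a, ] - x[b, ]
      outLabels <- c(outLabels, paste0(a, "-", b))
    }
  }
  Recording(out, fs = samplingRate(rec), channelLabels = outLabels,
            montage = "bipolar")
}

#' Drop channels from a recording
#'
#' Removes channels affected by continuous interference or not recording
#' from brain tissue. The order of the remaining channels is preserved;
#' excluding every channel is an error because downstream per-channel rate
#' computation is undefined on an empty recording.
#'
#' @param rec a [Recording-class].
#' @param labels character vector of labels to drop (may be empty).
#' @return The [Recording-class] without the listed channels.
#' @export
excludeChannels <- function(rec, labels) {
  stopifnot(is(rec, "Recording"))
  labels <- as.character(labels)
  unknown <- setdiff(labels, channelLabels(rec))
  if (length(unknown))
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "))
  keep <- !channelLabels(rec) %in% labels
  if (!any(keep))
    stop("excluding every channel leaves an empty recording")
  Recording(samples(rec)[keep, , drop = FALSE], fs = samplingRate(rec),
            channelLabels = channelLabels(rec)[keep], montage = montage(rec))
}
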