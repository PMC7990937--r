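# small deterministic recordings and an independently assembled EDF file

testRecording <- function(nch = 2, fs = 2000, dur = 2, seed = 7) {
  set.seed(seed)
  Recording(matrix(rnorm(nch * fs * dur), nrow = nch), fs = fs)
}

# Assemble an EDF file byte by byte, directly from the published layout
# (256-byte fixed header, 256 bytes per signal, int16 little-endian data
# records) -- independent of the package's reader.
writeTinyEDF <- function(path, signals, fs, physDim = "uV",
                         physMin = -1000, physMax = 1000,
                         digMin = -32768, digMax = 32767) {
  nSig <- nrow(signals)
  spr <- ncol(signals)                    # one data record
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, n) {
    s <- sprintf(paste0("%-", n, "s"), as.character(x))
    writeBin(charToRaw(substr(s, 1, n)), con)
  }
  pad("0", 8)                             # version
  pad("test patient", 80)
  pad("test recording", 80)
  pad("01.01.20", 8); pad("00.00.00", 8)
  pad(256 + 256 * nSig, 8)                # header bytes
  pad("", 44)
  pad(1, 8)                               # n data records
  pad(format(spr / fs), 8)                # record duration (s)
  pad(nSig, 4)
  for (i in seq_len(nSig)) pad(paste0("sig", i), 16)
  for (i in seq_len(nSig)) pad("test", 80)
  for (i in seq_len(nSig)) pad(physDim, 8)
  for (i in seq_len(nSig)) pad(physMin, 8)
  for (i in seq_len(nSig)) pad(physMax, 8)
  for (i in seq_len(nSig)) pad(digMin, 8)
  for (i in seq_len(nSig)) pad(digMax, 8)
  for (i in seq_len(nSig)) pad("", 80)
  for (i in seq_len(nSig)) pad(spr, 8)
  for (i in seq_len(nSig)) pad("", 32)
  for (i in seq_len(nSig)) {
    dig <- round((signals[i, ] - physMin) / (physMax - physMin) *
                   (digMax - digMin) + digMin)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

# brute-force window-concatenation oracle for event marking
oracleMarkEvents <- function(times, dur, win = 0.015) {
  nWin <- ceiling(dur / win)
  active <- rep(FALSE, nWin)
  for (t in times) active[floor(t / win) + 1] <- TRUE
  ev <- NULL
  i <- 1
  while (i <= nWin) {
    if (active[i]) {
      j <- i
      while (j < nWin && active[j + 1]) j <- j + 1
      ev <- rbind(ev, data.frame(start_s = (i - 1) * win, end_s = j * win))
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(ev)) data.frame(start_s = numeric(0), end_s = numeric(0)) else ev
}

# brute-force run-length cycle oracle
oracleCycles <- function(up, dn) {
  t <- c(up, dn); pol <- c(rep("U", length(up)), rep("D", length(dn)))
  o <- order(t); t <- t[o]; pol <- pol[o]
  n <- 0
  i <- 1
  while (i <= length(t)) {
    j <- i
    while (j < length(t) && pol[j + 1] == pol[i]) j <- j + 1
    if (pol[i] == "U" && j < length(t)) n <- n + 1  # followed by a D run
    i <- j + 1
  }
  n
}

randomTrain <- function(n, dur = 1, seed = 1) {
  set.seed(seed)
  t <- sort(runif(n, 0, dur))
  pol <- sample(c(TRUE, FALSE), n, replace = TRUE)
  SpikeTrain(up = t[pol], dn = t[!pol], duration = dur, refractory = 0)
}
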