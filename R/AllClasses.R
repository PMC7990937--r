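#' @import methods
NULL

#' Multichannel ECoG recording
#'
#' Container for a multichannel electrocorticography recording. Samples are
#' stored as a channels x time numeric matrix in microvolts; the montage slot
#' records whether channels are referential contacts or bipolar derivations.
#'
#' @slot samples numeric matrix, channels x time, in microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector of unique channel labels, one per row.
#' @slot montage either `"referential"` or `"bipolar"`.
#'
#' @seealso [Recording()], [readRecording()], [toBipolar()]
#' @exportClass Recording
setClass("Recording",
  representation(
    samples = "matrix",
    fs = "numeric",
    channelLabels = "character",
    montage = "character"
  )
)

setValidity("Recording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (!is.numeric(object@samples))
    msg <- c(msg, "samples must be a numeric matrix")
  if (nrow(object@samples) != length(object@channelLabels))
    msg <- c(msg, "one channel label per sample row is required")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (length(object@montage) != 1L ||
      !object@montage %in% c("referential", "bipolar"))
    msg <- c(msg, "montage must be 'referential' or 'bipolar'")
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param samples channels x time numeric matrix (microvolts).
#' @param fs sampling rate in Hz.
#' @param channelLabels character vector of channel labels; defaults to
#'   `ch1, ch2, ...`.
#' @param montage `"referential"` (default) or `"bipolar"`.
#' @return A [Recording-class] object.
#' @examples
#' rec <- Recording(matrix(rnorm(4000), nrow = 2), fs = 2000)
#' duration(rec)
#' @export
Recording <- function(samples, fs, channelLabels = NULL,
                      montage = "referential") {
  samples <- as.matrix(samples)
  if (is.null(channelLabels)) {
    channelLabels <- rownames(samples)
    if (is.null(channelLabels))
      channelLabels <- paste0("ch", seq_len(nrow(samples)))
  }
  rownames(samples) <- channelLabels
  new("Recording", samples = samples, fs = as.numeric(fs),
      channelLabels = as.character(channelLabels), montage = montage)
}

#' UP/DN spike train from delta-modulator encoding
#'
#' Timestamped UP and DN event streams produced by the analog-delta-modulator
#' encoding of one channel. A single modulator serves both polarities, so the
#' merged stream respects the shared refractory period.
#'
#' @slot up sorted UP spike times in seconds.
#' @slot dn sorted DN spike times in seconds.
#' @slot duration duration of the encoded segment in seconds.
#' @slot threshold delta threshold in microvolts.
#' @slot refractory refractory hold in seconds (default 300 microseconds).
#' @slot fsOversample sampling rate of the encoding grid in Hz.
#'
#' @seealso [SpikeTrain()], [admEncode()], [extractCycles()]
#' @exportClass SpikeTrain
setClass("SpikeTrain",
  representation(
    up = "numeric",
    dn = "numeric",
    duration = "numeric",
    threshold = "numeric",
    refractory = "numeric",
    fsOversample = "numeric"
  )
)

setValidity("SpikeTrain", function(object) {
  msg <- character()
  if (is.unsorted(object@up) || is.unsorted(object@dn))
    msg <- c(msg, "spike times must be sorted")
  all_t <- c(object@up, object@dn)
  if (length(all_t) && (min(all_t) < 0 || max(all_t) >= object@duration))
    msg <- c(msg, "spike times must lie in [0, duration)")
  if (object@refractory > 0 && length(all_t) > 1) {
    if (min(diff(sort(all_t))) < object@refractory - 1e-9)
      msg <- c(msg, "merged UP+DN stream violates the refractory period")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpikeTrain
#'
#' @param up,dn sorted spike times (seconds) of the UP and DN streams.
#' @param duration duration of the encoded segment (seconds).
#' @param threshold delta threshold (microvolts); `NA` when unknown.
#' @param refractory shared refractory period (seconds).
#' @param fsOversample encoding grid rate (Hz).
#' @return A [SpikeTrain-class] object.
#' @export
SpikeTrain <- function(up, dn, duration, threshold = NA_real_,
                       refractory = 3e-4, fsOversample = 35000) {
  new("SpikeTrain", up = as.numeric(up), dn = as.numeric(dn),
      duration = as.numeric(duration), threshold = as.numeric(threshold),
      refractory = as.numeric(refractory),
      fsOversample = as.numeric(fsOversample))
}

#' Parameterization of the spiking network
#'
#' Full parameterization of the two-layer integrate-and-fire network with its
#' dis-inhibitory artifact-rejection stage. Synaptic strengths are currents in
#' femtoamperes and time constants are in milliseconds, matching the
#' current-mode neuromorphic circuits the simulation emulates. The canonical
#' published ranges are: UP-to-second-layer strength in [7, 14] fA
#' (excitatory) with tau in [3, 6] ms; DN-to-second-layer strength in
#' [7, 14] fA (inhibitory) with tau smaller than the UP tau by 0.1-1 ms;
#' UP/DN-to-dis-inhibitory 21 fA excitatory, tau 5 ms; dis-inhibitory-to-
#' global-inhibitory 17.5 fA inhibitory, tau 20 ms; Poisson-to-global-
#' inhibitory excitatory, tau 5 ms (strength is a calibration parameter);
#' global-inhibitory-to-second-layer 24.5 fA inhibitory, tau 5 ms.
#'
#' @slot nSecondLayer number of second-layer neurons.
#' @slot wUp,tauUpMs per-neuron UP synapse strength (fA) and tau (ms).
#' @slot wDn,tauDnMs per-neuron DN synapse strength (fA) and tau (ms).
#' @slot wUpDi,wDnDi,tauDiMs input synapses onto the dis-inhibitory neuron.
#' @slot wDiGi,tauDiGiMs dis-inhibitory to global-inhibitory synapse.
#' @slot wPoissGi,tauPoissMs Poisson drive onto the global-inhibitory neuron.
#' @slot wGiSl,tauGiSlMs global-inhibitory to second-layer synapse.
#' @slot poissonRate rate of the Poisson drive (Hz).
#' @slot tauMemSlMs,thrSl,refSlMs second-layer membrane tau (ms), spike
#'   threshold (fA) and refractory (ms).
#' @slot tauMemDiMs,thrDi,refDiMs dis-inhibitory neuron constants.
#' @slot tauMemGiMs,thrGi,refGiMs global-inhibitory neuron constants.
#' @slot dt integration step (seconds).
#' @slot validateRanges when `TRUE` (default) the validity method rejects
#'   synapse parameters outside the canonical published ranges.
#'
#' @seealso [defaultNetworkConfig()], [buildNetwork()], [simulateNetwork()]
#' @exportClass NetworkConfig
setClass("NetworkConfig",
  representation(
    nSecondLayer = "integer",
    wUp = "numeric", tauUpMs = "numeric",
    wDn = "numeric", tauDnMs = "numeric",
    wUpDi = "numeric", wDnDi = "numeric", tauDiMs = "numeric",
    wDiGi = "numeric", tauDiGiMs = "numeric",
    wPoissGi = "numeric", tauPoissMs = "numeric",
    wGiSl = "numeric", tauGiSlMs = "numeric",
    poissonRate = "numeric",
    tauMemSlMs = "numeric", thrSl = "numeric", refSlMs = "numeric",
    tauMemDiMs = "numeric", thrDi = "numeric", refDiMs = "numeric",
    tauMemGiMs = "numeric", thrGi = "numeric", refGiMs = "numeric",
    dt = "numeric",
    validateRanges = "logical"
  )
)

setValidity("NetworkConfig", function(object) {
  msg <- character()
  n <- object@nSecondLayer
  if (n < 1L) msg <- c(msg, "need at least one second-layer neuron")
  for (s in c("wUp", "tauUpMs", "wDn", "tauDnMs")) {
    if (length(slot(object, s)) != n)
      msg <- c(msg, sprintf("%s must have one entry per second-layer neuron", s))
  }
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (object@poissonRate < 0) msg <- c(msg, "poissonRate must be >= 0")
  if (isTRUE(object@validateRanges) && length(object@wUp) == n &&
      length(object@tauUpMs) == n && length(object@tauDnMs) == n) {
    inr <- function(x, lo, hi) all(x >= lo - 1e-9 & x <= hi + 1e-9)
    if (!inr(object@wUp, 7, 14))
      msg <- c(msg, "wUp outside the published range [7, 14] fA")
    if (!inr(object@wDn, 7, 14))
      msg <- c(msg, "wDn outside the published range [7, 14] fA")
    if (!inr(object@tauUpMs, 3, 6))
      msg <- c(msg, "tauUpMs outside the published range [3, 6] ms")
    d <- object@tauUpMs - object@tauDnMs
    if (!inr(d, 0.1, 1))
      msg <- c(msg, "tauUpMs - tauDnMs outside the published range [0.1, 1] ms")
    if (object@wUpDi != 21 || object@wDnDi != 21 || object@tauDiMs != 5)
      msg <- c(msg, "dis-inhibitory input synapses must be 21 fA with tau 5 ms")
    if (object@wDiGi != 17.5 || object@tauDiGiMs != 20)
      msg <- c(msg, "DI-to-GI synapse must be 17.5 fA with tau 20 ms")
    if (object@wGiSl != 24.5 || object@tauGiSlMs != 5)
      msg <- c(msg, "GI-to-second-layer synapse must be 24.5 fA with tau 5 ms")
    if (object@tauPoissMs != 5)
      msg <- c(msg, "Poisson-to-GI synapse tau must be 5 ms")
  }
  if (length(msg)) msg else TRUE
})

#' Spiking network ready for simulation
#'
#' A validated network: its configuration plus the explicit connection table
#' (one row per synapse class, expanded over second-layer neurons).
#'
#' @slot config a [NetworkConfig-class].
#' @slot connections data.frame with columns `from`, `to`, `strength_fA`,
#'   `polarity`, `tau_ms`.
#' @seealso [buildNetwork()]
#' @exportClass Network
setClass("Network",
  representation(config = "NetworkConfig", connections = "data.frame")
)
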