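#' Accessors for Recording and SpikeTrain objects
#'
#' Accessor generics for the core containers: `samples()` returns the
#' channels x time matrix in microvolts, `samplingRate()` the rate in Hz,
#' `channelLabels()` the labels, `montage()` the montage tag, `duration()`
#' the length in seconds, `nChannels()`/`nSamples()` the matrix dimensions,
#' and `upTimes()`/`dnTimes()` the spike streams of a [SpikeTrain-class].
#'
#' @param x a [Recording-class] or [SpikeTrain-class] object.
#' @return The slot contents described above.
#' @name accessors
#' @examples
#' rec <- Recording(matrix(0, 2, 100), fs = 2000)
#' nChannels(rec); duration(rec)
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("montage", function(x) standardGeneric("montage"))
#' @rdname accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("upTimes", function(x) standardGeneric("upTimes"))
#' @rdname accessors
#' @export
setGeneric("dnTimes", function(x) standardGeneric("dnTimes"))

#' @rdname accessors
setMethod("samples", "Recording", function(x) x@samples)
#' @rdname accessors
setMethod("samplingRate", "Recording", function(x) x@fs)
#' @rdname accessors
setMethod("channelLabels", "Recording", function(x) x@channelLabels)
#' @rdname accessors
setMethod("montage", "Recording", function(x) x@montage)
#' @rdname accessors
setMethod("duration", "Recording", function(x) ncol(x@samples) / x@fs)
#' @rdname accessors
setMethod("nChannels", "Recording", function(x) nrow(x@samples))
#' @rdname accessors
setMethod("nSamples", "Recording", function(x) ncol(x@samples))

#' @rdname accessors
setMethod("duration", "SpikeTrain", function(x) x@duration)
#' @rdname accessors
setMethod("upTimes", "SpikeTrain", function(x) x@up)
#' @rdname accessors
setMethod("dnTimes", "SpikeTrain", function(x) x@dn)

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channel(s) x %d samples @ %g Hz (%.3f s, %s montage)\n",
              nChannels(object), nSamples(object), samplingRate(object),
              duration(object), montage(object)))
  lbl <- channelLabels(object)
  if (length(lbl) > 6) lbl <- c(lbl[1:6], "...")
  cat("  channels:", paste(lbl, collapse = ", "), "\n")
})

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain: %d UP / %d DN spikes over %.3f s (threshold %.3g uV, refractory %g us)\n",
              length(object@up), length(object@dn), object@duration,
              object@threshold, object@refractory * 1e6))
})

setMethod("show", "Network", function(object) {
  cfg <- object@config
  cat(sprintf("Spiking HFO-detector network: %d second-layer neuron(s), %d connections\n",
              cfg@nSecondLayer, nrow(object@connections)))
  cat(sprintf("  Poisson drive: %g Hz x %g fA onto the global-inhibitory neuron\n",
              cfg@poissonRate, cfg@wPoissGi))
})
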