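#' @include AllGenerics.R
NULL

#' Sampling rate accessor
#'
#' @param x an object holding sampled signals.
#' @return Sampling rate in Hz.
#' @export
setGeneric("sfreq", function(x) standardGeneric("sfreq"))

#' Channel label accessor
#' @param x an object with a channel axis.
#' @return Character vector of channel labels, in axis order.
#' @export
setGeneric("chNames", function(x) standardGeneric("chNames"))

#' Channel position accessor
#' @param x an object with montage information.
#' @return Numeric matrix (channels x 3) of head-frame positions in meters,
#'   or a 0-row matrix for position-free containers.
#' @export
setGeneric("chPositions", function(x) standardGeneric("chPositions"))

#' Bad-channel accessor
#' @param x an object with channel metadata.
#' @return Character vector of channel labels marked bad.
#' @export
setGeneric("badChannels", function(x) standardGeneric("badChannels"))

#' @rdname badChannels
#' @param value replacement character vector (subset of \code{chNames(x)}).
#' @export
setGeneric("badChannels<-", function(x, value) standardGeneric("badChannels<-"))

#' Participant label accessor
#' @param x an epoch container.
#' @return Participant identifier string.
#' @export
setGeneric("participantId", function(x) standardGeneric("participantId"))

#' Epoch / channel / sample counts
#' @param x an object with an epochs axis.
#' @return Integer count.
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname nEpochs
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname nEpochs
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Raw epoched data accessor
#' @param x an epoch container.
#' @return Numeric array epochs x channels x samples (volts).
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' Whether a container carries no sensor positions
#' @param x an epoch container.
#' @return Logical flag; position-free containers are refused by adjacency
#'   and visualization code.
#' @export
setGeneric("positionFree", function(x) standardGeneric("positionFree"))

#' Envelope (modulus) of an analytic signal
#' @param x an \linkS4class{AnalyticSignal}.
#' @param ... unused.
#' @return Real array of the same shape as the complex values; non-negative.
#' @export
setGeneric("envelope", function(x, ...) standardGeneric("envelope"))

#' Instantaneous phase (argument) of an analytic signal
#' @param x an \linkS4class{AnalyticSignal}.
#' @param ... unused.
#' @return Real array of phases in (-pi, pi].
#' @export
setGeneric("phaseAngle", function(x, ...) standardGeneric("phaseAngle"))

#' Frequency-bin accessor
#' @param x an object with a frequency axis.
#' @return Numeric vector of bin centers in Hz.
#' @export
setGeneric("freqs", function(x) standardGeneric("freqs"))

#' Band-to-bin index map
#' @param x an \linkS4class{AnalyticSignal}.
#' @return Named list mapping band name to integer bin indices.
#' @export
setGeneric("bandIndex", function(x) standardGeneric("bandIndex"))

#' Band names of a connectivity matrix
#' @param x a \linkS4class{ConnectivityMatrix}.
#' @return Character vector of band names.
#' @export
setGeneric("bandNames", function(x) standardGeneric("bandNames"))

#' Connectivity values accessor
#' @param x a \linkS4class{ConnectivityMatrix}.
#' @return Array (bands x 2N x 2N), or (epochs x bands x 2N x 2N) when
#'   per-epoch values were preserved.
#' @export
setGeneric("connValues", function(x) standardGeneric("connValues"))

#' Directionality flag of a metric
#' @param x a \linkS4class{ConnectivityMatrix}.
#' @return TRUE for directed metrics (pdc, transfer_entropy).
#' @export
setGeneric("isDirectional", function(x) standardGeneric("isDirectional"))

#' Slice a joint two-participant matrix into its four blocks
#'
#' @param x a \linkS4class{ConnectivityMatrix} or a plain 2N x 2N matrix.
#' @param ... band/epoch selectors, see methods.
#' @return List with elements \code{intra1}, \code{intra2}, \code{inter12},
#'   \code{inter21}, each N x N; blocks tile the parent exactly.
#' @export
setGeneric("sliceBlocks", function(x, ...) standardGeneric("sliceBlocks"))
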