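#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## EpochArray
## ---------------------------------------------------------------------------

#' Epoched multichannel signal for one participant
#'
#' The unit container of the pipeline: a real array of epochs x channels x
#' samples (volts) with its sampling rate, ordered channel labels, optional
#' 3-D sensor positions (head-centered RAS, meters), bad-channel labels and a
#' per-original-epoch drop log.
#'
#' @slot data numeric array, epochs x channels x samples, in volts.
#' @slot sfreq sampling rate in Hz (> 0).
#' @slot chNames unique channel labels, one per channel axis entry.
#' @slot chPos channels x 3 position matrix (meters); a 0-row matrix marks the
#'   container position-free, in which case adjacency construction and
#'   topographic plotting refuse it.
#' @slot bads subset of \code{chNames} marked bad.
#' @slot dropLog logical over the original epochs; TRUE = dropped. The number
#'   of FALSE entries equals the retained epoch count.
#' @slot participantId participant label.
#'
#' @seealso [EpochArray()] constructor, [mergeDyad()], [readEpochs()]
#' @export
setClass("EpochArray",
  representation(
    data = "array",
    sfreq = "numeric",
    chNames = "character",
    chPos = "matrix",
    bads = "character",
    dropLog = "logical",
    participantId = "character"
  )
)

setValidity("EpochArray", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L)
    return("data must be a 3-axis array (epochs x channels x samples)")
  if (d[2L] != length(object@chNames))
    return(sprintf("channel axis length (%d) != number of channel names (%d)",
                   d[2L], length(object@chNames)))
  if (length(object@sfreq) != 1L || !is.finite(object@sfreq) ||
      object@sfreq <= 0)
    return("sfreq must be a single positive number")
  if (anyDuplicated(object@chNames))
    return("channel names must be unique")
  if (!all(object@bads %in% object@chNames))
    return("bads must be a subset of chNames")
  np <- nrow(object@chPos)
  if (np != 0L) {
    if (np != d[2L] || ncol(object@chPos) != 3L)
      return("chPos must be channels x 3 (or 0-row for position-free)")
    if (!all(is.finite(object@chPos)))
      return("chPos must be finite")
  }
  if (sum(!object@dropLog) != d[1L])
    return("dropLog kept count does not match epoch count")
  if (length(object@participantId) != 1L)
    return("participantId must be a single label")
  TRUE
})

#' Construct an EpochArray
#'
#' @param data numeric array epochs x channels x samples (volts).
#' @param sfreq sampling rate (Hz).
#' @param chNames channel labels; default \code{"Ch1"..}.
#' @param chPos channels x 3 matrix of sensor positions (m) or NULL for a
#'   position-free container.
#' @param bads character vector of bad channel labels.
#' @param participantId participant label.
#' @param dropLog logical drop log over original epochs; defaults to all-kept.
#' @return A validated \linkS4class{EpochArray}.
#' @examples
#' e <- EpochArray(array(rnorm(2 * 3 * 100), c(2, 3, 100)), sfreq = 100)
#' nEpochs(e); chNames(e)
#' @export
EpochArray <- function(data, sfreq, chNames = NULL, chPos = NULL,
                       bads = character(), participantId = "P1",
                       dropLog = NULL) {
  data <- as.array(data)
  if (is.null(chNames))
    chNames <- paste0("Ch", seq_len(dim(data)[2L]))
  if (is.null(chPos))
    chPos <- matrix(numeric(0), nrow = 0L, ncol = 3L)
  if (is.null(dropLog))
    dropLog <- rep(FALSE, dim(data)[1L])
  new("EpochArray", data = data, sfreq = as.numeric(sfreq),
      chNames = as.character(chNames), chPos = chPos,
      bads = as.character(bads), dropLog = dropLog,
      participantId = as.character(participantId))
}

#' @describeIn EpochArray sampling rate in Hz
#' @param x,object an \code{EpochArray}
#' @export
setMethod("sfreq", "EpochArray", function(x) x@sfreq)

#' @describeIn EpochArray channel labels
#' @export
setMethod("chNames", "EpochArray", function(x) x@chNames)

#' @describeIn EpochArray sensor positions (0-row when position-free)
#' @export
setMethod("chPositions", "EpochArray", function(x) x@chPos)

#' @describeIn EpochArray bad channel labels
#' @export
setMethod("badChannels", "EpochArray", function(x) x@bads)

#' @describeIn EpochArray replace bad channel labels
#' @param value character vector, subset of \code{chNames(x)}
#' @export
setMethod("badChannels<-", "EpochArray", function(x, value) {
  x@bads <- as.character(value)
  validObject(x)
  x
})

#' @describeIn EpochArray participant label
#' @export
setMethod("participantId", "EpochArray", function(x) x@participantId)

#' @describeIn EpochArray retained epoch count
#' @export
setMethod("nEpochs", "EpochArray", function(x) dim(x@data)[1L])

#' @describeIn EpochArray channel count
#' @export
setMethod("nChannels", "EpochArray", function(x) dim(x@data)[2L])

#' @describeIn EpochArray samples per epoch
#' @export
setMethod("nSamples", "EpochArray", function(x) dim(x@data)[3L])

#' @describeIn EpochArray the raw data array
#' @export
setMethod("epochData", "EpochArray", function(x) x@data)

#' @describeIn EpochArray TRUE when no sensor positions are attached
#' @export
setMethod("positionFree", "EpochArray", function(x) nrow(x@chPos) == 0L)

setMethod("show", "EpochArray", function(object) {
  cat(sprintf("%s '%s': %d epochs x %d channels x %d samples @ %g Hz\n",
              class(object), object@participantId,
              nEpochs(object), nChannels(object), nSamples(object),
              object@sfreq))
  if (length(object@bads))
    cat("  bads:", paste(object@bads, collapse = ", "), "\n")
  if (positionFree(object))
    cat("  (position-free)\n")
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## HyperEpochArray
## ---------------------------------------------------------------------------

#' Merged two-participant ("hyper") epoch container
#'
#' An \linkS4class{EpochArray} whose channel axis concatenates two
#' participants' channels; labels carry participant suffixes (default "_1",
#' "_2"). Exactly half the labels end in the first suffix and half in the
#' second, and the de-suffixed label sequences of the two halves are
#' identical and in the same order.
#'
#' @slot sourceIds the two participant labels, in channel-block order.
#' @slot suffixes the two channel-name suffixes.
#' @seealso [mergeDyad()], [splitDyad()]
#' @export
setClass("HyperEpochArray",
  contains = "EpochArray",
  representation(sourceIds = "character", suffixes = "character")
)

setValidity("HyperEpochArray", function(object) {
  nc <- length(object@chNames)
  if (nc %% 2L != 0L) return("channel count must be even")
  if (length(object@sourceIds) != 2L) return("sourceIds must have length 2")
  if (length(object@suffixes) != 2L) return("suffixes must have length 2")
  n <- nc %/% 2L
  s1 <- object@suffixes[1L]; s2 <- object@suffixes[2L]
  first <- object@chNames[seq_len(n)]
  second <- object@chNames[n + seq_len(n)]
  if (!all(endsWith(first, s1)) || !all(endsWith(second, s2)))
    return("first half of channels must carry suffix 1, second half suffix 2")
  if (!identical(stripSuffix(first, s1), stripSuffix(second, s2)))
    return("de-suffixed channel sequences of the two halves differ")
  TRUE
})

setMethod("show", "HyperEpochArray", function(object) {
  cat(sprintf(
    "%s [%s + %s]: %d epochs x %d channels (2 x %d) x %d samples @ %g Hz\n",
    class(object), object@sourceIds[1L], object@sourceIds[2L],
    nEpochs(object), nChannels(object), nChannels(object) %/% 2L,
    nSamples(object), object@sfreq))
  if (length(object@bads))
    cat("  bads:", paste(object@bads, collapse = ", "), "\n")
  invisible(NULL)
})

## strip a trailing suffix only (no-op on labels that do not end with it)
stripSuffix <- function(x, suffix) {
  hit <- endsWith(x, suffix)
  x[hit] <- substr(x[hit], 1L, nchar(x[hit]) - nchar(suffix))
  x
}

## ---------------------------------------------------------------------------
## PsdResult
## ---------------------------------------------------------------------------

#' Welch power spectral density result
#'
#' @slot psd non-negative power values in V^2/Hz: channels x bins, or
#'   epochs x channels x bins when per-epoch spectra are preserved.
#' @slot freqList exact frequency bins (Hz) at which power was estimated.
#' @slot params list with fmin, fmax, nFft, nPerSeg, epochsAverage.
#' @seealso [welchPsd()]
#' @export
setClass("PsdResult",
  representation(psd = "array", freqList = "numeric", params = "list"))

setValidity("PsdResult", function(object) {
  nd <- length(dim(object@psd))
  if (!nd %in% c(2L, 3L)) return("psd must have 2 or 3 axes")
  if (dim(object@psd)[nd] != length(object@freqList))
    return("trailing psd axis must match freqList")
  if (any(object@psd < 0)) return("psd values must be >= 0")
  fmin <- object@params$fmin; fmax <- object@params$fmax
  if (!is.null(fmin) && length(object@freqList) &&
      (min(object@freqList) < fmin - 1e-9 ||
       max(object@freqList) > fmax + 1e-9))
    return("freqList values must lie in [fmin, fmax]")
  TRUE
})

setMethod("freqs", "PsdResult", function(x) x@freqList)

setMethod("show", "PsdResult", function(object) {
  d <- dim(object@psd)
  cat(sprintf("PsdResult: %s over %d bins [%g, %g] Hz\n",
              paste(d, collapse = " x "), length(object@freqList),
              min(object@freqList), max(object@freqList)))
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## AnalyticSignal
## ---------------------------------------------------------------------------

#' Band-limited analytic-signal decomposition
#'
#' Complex values per epoch, channel, integer-Hz frequency bin and sample.
#' The modulus is the instantaneous envelope, the argument the instantaneous
#' phase. Within every named band, consecutive bins differ by exactly 1 Hz.
#'
#' @slot values complex array, epochs x channels x bins x samples.
#' @slot freqs integer bin centers (Hz), one per bin axis entry.
#' @slot bandIndex named list: band name -> integer indices into the bin axis.
#' @slot sfreq sampling rate (Hz).
#' @slot chNames channel labels.
#' @seealso [computeFreqBands()], [envelope()], [phaseAngle()]
#' @export
setClass("AnalyticSignal",
  representation(values = "array", freqs = "numeric", bandIndex = "list",
                 sfreq = "numeric", chNames = "character"))

setValidity("AnalyticSignal", function(object) {
  d <- dim(object@values)
  if (length(d) != 4L)
    return("values must be epochs x channels x bins x samples")
  if (!is.complex(object@values)) return("values must be complex")
  if (d[2L] != length(object@chNames)) return("channel axis mismatch")
  if (d[3L] != length(object@freqs)) return("bin axis mismatch")
  if (length(object@bandIndex)) {
    idx <- sort(unique(unlist(object@bandIndex)))
    if (!identical(idx, seq_len(d[3L])))
      return("bandIndex must cover every bin exactly")
    for (b in names(object@bandIndex)) {
      f <- object@freqs[object@bandIndex[[b]]]
      if (length(f) > 1L && any(abs(diff(f) - 1) > 1e-9))
        return(sprintf("bins within band '%s' must be spaced exactly 1 Hz", b))
    }
  }
  TRUE
})

#' @describeIn AnalyticSignal complex values array
#' @param x,object an \code{AnalyticSignal}
#' @export
setMethod("epochData", "AnalyticSignal", function(x) x@values)

#' @describeIn AnalyticSignal instantaneous envelope (modulus)
#' @param ... unused
#' @export
setMethod("envelope", "AnalyticSignal", function(x, ...) Mod(x@values))

#' @describeIn AnalyticSignal instantaneous phase in (-pi, pi]
#' @export
setMethod("phaseAngle", "AnalyticSignal", function(x, ...) Arg(x@values))

#' @describeIn AnalyticSignal integer frequency bins (Hz)
#' @export
setMethod("freqs", "AnalyticSignal", function(x) x@freqs)

#' @describeIn AnalyticSignal band name -> bin index map
#' @export
setMethod("bandIndex", "AnalyticSignal", function(x) x@bandIndex)

#' @describeIn AnalyticSignal sampling rate
#' @export
setMethod("sfreq", "AnalyticSignal", function(x) x@sfreq)

#' @describeIn AnalyticSignal channel labels
#' @export
setMethod("chNames", "AnalyticSignal", function(x) x@chNames)

#' @describeIn AnalyticSignal epoch count
#' @export
setMethod("nEpochs", "AnalyticSignal", function(x) dim(x@values)[1L])

#' @describeIn AnalyticSignal channel count
#' @export
setMethod("nChannels", "AnalyticSignal", function(x) dim(x@values)[2L])

#' @describeIn AnalyticSignal samples per epoch
#' @export
setMethod("nSamples", "AnalyticSignal", function(x) dim(x@values)[4L])

setMethod("show", "AnalyticSignal", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "AnalyticSignal: %d epochs x %d channels x %d bins x %d samples\n",
    d[1L], d[2L], d[3L], d[4L]))
  cat(sprintf("  bins: %s Hz; bands: %s\n",
              paste(range(object@freqs), collapse = "-"),
              paste(names(object@bandIndex), collapse = ", ")))
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## ConnectivityMatrix
## ---------------------------------------------------------------------------

#' Joint two-participant connectivity matrix
#'
#' Per-frequency-band values over the stacked 2N channels of a dyad. The four
#' N x N blocks are the two intra-brain and the two inter-brain sub-matrices
#' (see [sliceBlocks()]). Non-directional metrics yield an exactly symmetric
#' matrix; for directed metrics (pdc, transfer_entropy) cell (i, j) carries
#' the influence of channel j on channel i (column = source).
#'
#' @slot values array bands x 2N x 2N, or epochs x bands x 2N x 2N when
#'   per-epoch values are preserved.
#' @slot metric metric name (one of the computeSync modes).
#' @slot directional TRUE for pdc / transfer_entropy.
#' @slot nCh per-participant channel count N.
#' @slot bandNames names of the band axis.
#' @slot chNames the 2N stacked channel labels.
#' @seealso [computeSync()], [sliceBlocks()], [standardize()]
#' @export
setClass("ConnectivityMatrix",
  representation(values = "array", metric = "character",
                 directional = "logical", nCh = "integer",
                 bandNames = "character", chNames = "character"))

setValidity("ConnectivityMatrix", function(object) {
  d <- dim(object@values)
  nd <- length(d)
  if (!nd %in% c(3L, 4L))
    return("values must be (bands x 2N x 2N) or (epochs x bands x 2N x 2N)")
  side <- 2L * object@nCh
  if (d[nd] != side || d[nd - 1L] != side)
    return("trailing axes must be square of side 2 * nCh")
  if (d[nd - 2L] != length(object@bandNames))
    return("band axis must match bandNames")
  if (length(object@chNames) != side)
    return("chNames must have length 2 * nCh")
  if (!object@directional) {
    v <- object@values
    m <- matrix(aperm(v, c(nd - 1L, nd, seq_len(nd - 2L))), nrow = side)
    tm <- matrix(aperm(v, c(nd, nd - 1L, seq_len(nd - 2L))), nrow = side)
    worst <- max(abs(m - tm), 0)
    if (is.finite(worst) && worst > 1e-8)
      return("non-directional metric must yield a symmetric matrix")
  }
  TRUE
})

#' @describeIn ConnectivityMatrix values array
#' @param x,object a \code{ConnectivityMatrix}
#' @export
setMethod("connValues", "ConnectivityMatrix", function(x) x@values)

#' @describeIn ConnectivityMatrix directionality flag
#' @export
setMethod("isDirectional", "ConnectivityMatrix", function(x) x@directional)

#' @describeIn ConnectivityMatrix band names
#' @export
setMethod("bandNames", "ConnectivityMatrix", function(x) x@bandNames)

#' @describeIn ConnectivityMatrix per-participant channel count N
#' @export
setMethod("nChannels", "ConnectivityMatrix", function(x) x@nCh)

#' @describeIn ConnectivityMatrix stacked channel labels (length 2N)
#' @export
setMethod("chNames", "ConnectivityMatrix", function(x) x@chNames)

setMethod("show", "ConnectivityMatrix", function(object) {
  d <- dim(object@values)
  cat(sprintf("ConnectivityMatrix '%s'%s: %s (N = %d per participant)\n",
              object@metric,
              if (object@directional) " (directional)" else "",
              paste(d, collapse = " x "), object@nCh))
  cat("  bands:", paste(object@bandNames, collapse = ", "), "\n")
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## MvarModel
## ---------------------------------------------------------------------------

#' Multivariate autoregressive model
#'
#' Least-squares MVAR fit used by partial directed coherence.
#'
#' @slot order model order p (>= 1).
#' @slot coefs coefficient array C x C x p; \code{coefs[i, j, m]} is the
#'   weight of channel j at lag m in the prediction of channel i.
#' @slot residCov residual covariance (C x C, positive semi-definite).
#' @slot stable TRUE when the companion-matrix spectral radius is < 1.
#' @slot chNames channel labels.
#' @seealso [fitMvar()], [pdc()]
#' @export
setClass("MvarModel",
  representation(order = "integer", coefs = "array", residCov = "matrix",
                 stable = "logical", chNames = "character"))

setValidity("MvarModel", function(object) {
  if (object@order < 1L) return("order must be >= 1")
  d <- dim(object@coefs)
  if (length(d) != 3L || d[1L] != d[2L] || d[3L] != object@order)
    return("coefs must be C x C x order")
  if (!all(dim(object@residCov) == d[1L]))
    return("residCov must be C x C")
  TRUE
})

setMethod("show", "MvarModel", function(object) {
  cat(sprintf("MvarModel: %d channels, order %d, %s\n",
              dim(object@coefs)[1L], object@order,
              if (object@stable) "stable" else "UNSTABLE"))
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## AdjacencyStructure
## ---------------------------------------------------------------------------

#' Sensor neighborhood graph, optionally expanded across frequency bins
#'
#' @slot chCon N x N logical channel neighborhood (symmetric, FALSE diagonal).
#' @slot chConFreq (N*F) x (N*F) logical expansion across F frequency bins:
#'   node (channel c, bin f) indexes row/column c + (f - 1) * N. Two nodes are
#'   linked iff they share the bin and the channels neighbor each other, or
#'   they share the channel and the bins are adjacent.
#' @slot freqs the frequency bins used for the expansion.
#' @slot params neighborhood rule parameters (rule name, threshold, ...).
#' @seealso [conMatrix()]
#' @export
setClass("AdjacencyStructure",
  representation(chCon = "matrix", chConFreq = "matrix", freqs = "numeric",
                 params = "list"))

setValidity("AdjacencyStructure", function(object) {
  a <- object@chCon
  if (!is.logical(a) || nrow(a) != ncol(a)) return("chCon must be square logical")
  if (any(diag(a))) return("chCon diagonal must be FALSE")
  if (!identical(a, t(a))) return("chCon must be symmetric")
  nf <- max(length(object@freqs), 1L)
  if (nrow(object@chConFreq) != nrow(a) * nf)
    return("chConFreq must have N * F nodes")
  TRUE
})

setMethod("show", "AdjacencyStructure", function(object) {
  cat(sprintf("AdjacencyStructure: %d channels, %d bins, rule '%s'\n",
              nrow(object@chCon), max(length(object@freqs), 1L),
              object@params$rule %||% "?"))
  invisible(NULL)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## Statistics results
## ---------------------------------------------------------------------------

#' Cluster-based permutation test result
#'
#' @slot tObs observed statistic per cell.
#' @slot clusters list of integer cell-index sets (disjoint; every member
#'   exceeds the cluster-forming threshold).
#' @slot clusterMasses signed sum of the statistic over each cluster.
#' @slot clusterP permutation p-value per cluster (includes the observed
#'   labeling: (1 + exceedances) / (1 + n permutations)).
#' @slot significantMask logical per cell; union of clusters with p <= alpha.
#' @slot nPermutations,test,tail,alpha,threshold test configuration; threshold
#'   is the cluster-forming statistic value actually used.
#' @seealso [statsCluster()]
#' @export
setClass("ClusterStatsResult",
  representation(tObs = "numeric", clusters = "list",
                 clusterMasses = "numeric", clusterP = "numeric",
                 significantMask = "logical", nPermutations = "integer",
                 test = "character", tail = "integer", alpha = "numeric",
                 threshold = "numeric"))

setValidity("ClusterStatsResult", function(object) {
  if (length(object@clusters) != length(object@clusterP))
    return("one p-value per cluster required")
  if (length(object@clusterP) &&
      (any(object@clusterP < 0) || any(object@clusterP > 1)))
    return("cluster p-values must lie in [0, 1]")
  idx <- unlist(object@clusters)
  if (length(idx) && anyDuplicated(idx))
    return("clusters must be disjoint")
  if (length(object@significantMask) != length(object@tObs))
    return("significantMask must match tObs")
  sig <- which(object@significantMask)
  ok <- unlist(object@clusters[object@clusterP <= object@alpha + 1e-12])
  if (length(sig) && !all(sig %in% ok))
    return("significantMask must be a union of significant clusters")
  TRUE
})

setMethod("show", "ClusterStatsResult", function(object) {
  cat(sprintf(
    "ClusterStatsResult (%s, tail %d): %d cells, %d cluster(s), min p = %s\n",
    object@test, object@tail, length(object@tObs), length(object@clusters),
    if (length(object@clusterP)) format(min(object@clusterP), digits = 4)
    else "NA (no clusters)"))
  invisible(NULL)
})

#' Permutation t-test with FDR correction, result container
#'
#' @slot tObs observed one-sample t per cell (NA where undefined).
#' @slot pValues sign-flip permutation p-values per cell.
#' @slot mask logical significance mask after Benjamini-Hochberg at alpha.
#' @slot tObsPlot tObs where significant, else 0 (for topographic display).
#' @slot excluded cells with zero variance, excluded from the FDR family.
#' @slot alpha,nPermutations,tail test configuration.
#' @seealso [permTtestFdr()]
#' @export
setClass("FdrTestResult",
  representation(tObs = "numeric", pValues = "numeric", mask = "logical",
                 tObsPlot = "numeric", excluded = "logical", alpha = "numeric",
                 nPermutations = "integer", tail = "integer"))

setMethod("show", "FdrTestResult", function(object) {
  cat(sprintf("FdrTestResult: %d cells, %d significant at FDR %g\n",
              length(object@tObs), sum(object@mask), object@alpha))
  invisible(NULL)
})

#' Cross-participant rejection report
#'
#' Records what was rejected per participant and the common (intersected)
#' epochs and channels finally kept: the final kept epochs are the
#' intersection of per-participant kept epochs and the final dropped channels
#' the union of per-participant bad channels, applied to every participant.
#'
#' @slot badEpochs per-participant list of rejected epoch indices.
#' @slot badChannels per-participant list of bad channel labels.
#' @slot keptEpochs final common kept-epoch indices (into original epochs).
#' @slot droppedChannels final common dropped channel labels (de-suffixed).
#' @slot threshold peak-to-peak threshold used, in volts.
#' @seealso [intersectGood()], [markBadEpochsPtp()]
#' @export
setClass("RejectionReport",
  representation(badEpochs = "list", badChannels = "list",
                 keptEpochs = "integer", droppedChannels = "character",
                 threshold = "numeric"))

setMethod("show", "RejectionReport", function(object) {
  cat(sprintf(
    "RejectionReport: kept %d epochs; dropped channels: %s (ptp %.4g V)\n",
    length(object@keptEpochs),
    if (length(object@droppedChannels))
      paste(object@droppedChannels, collapse = ", ") else "none",
    object@threshold))
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## Visualization containers
## ---------------------------------------------------------------------------

#' Suprathreshold inter-brain links
#'
#' @slot links data.frame with columns i, j (channel indices into the two
#'   participants), value, rendered; row-major (i-then-j) ordering.
#' @slot threshold the user threshold applied.
#' @slot mode "signed" (value > threshold) or "abs" (|value| > threshold).
#' @seealso [extractLinks()], [render2dInter()]
#' @export
setClass("LinkSet",
  representation(links = "data.frame", threshold = "numeric",
                 mode = "character"))

setMethod("show", "LinkSet", function(object) {
  cat(sprintf("LinkSet: %d link(s) over threshold %g (%s)\n",
              nrow(object@links), object@threshold, object@mode))
  invisible(NULL)
})

#' Number of links in a LinkSet or rendered figure
#' @param x a \linkS4class{LinkSet} or \linkS4class{InterBrainFigure}.
#' @return Integer link count.
#' @export
setGeneric("linkCount", function(x) standardGeneric("linkCount"))

#' @rdname linkCount
#' @export
setMethod("linkCount", "LinkSet", function(x) nrow(x@links))

#' Deterministic two-head topographic figure description
#'
#' A renderable, testable description of the inter-brain link plot: sensor
#' positions projected to 2-D on two side-by-side head outlines, crosses for
#' bad channels, and one Bezier polyline per suprathreshold link (red family
#' for positive, blue for negative values; width increasing with |value|).
#' Use \code{plot()} to draw it with ggplot2.
#'
#' @slot sensors data.frame: x, y, label, head (1/2), bad.
#' @slot links data.frame: i, j, value, color, width.
#' @slot paths list of polyline matrices, one per link row.
#' @slot outlines list of head-outline polylines.
#' @slot params rendering parameters (threshold, steps, ...).
#' @export
setClass("InterBrainFigure",
  representation(sensors = "data.frame", links = "data.frame",
                 paths = "list", outlines = "list", params = "list"))

#' @rdname linkCount
#' @export
setMethod("linkCount", "InterBrainFigure", function(x) length(x@paths))

setMethod("show", "InterBrainFigure", function(object) {
  cat(sprintf("InterBrainFigure: %d sensors, %d link path(s)\n",
              nrow(object@sensors), length(object@paths)))
  invisible(NULL)
})

#' Single-head statistic topography description
#'
#' @slot sensors data.frame: x, y, label, value, highlighted.
#' @slot params rendering parameters.
#' @seealso [plotSignificantSensors()]
#' @export
setClass("SensorMapFigure",
  representation(sensors = "data.frame", params = "list"))

setMethod("show", "SensorMapFigure", function(object) {
  cat(sprintf("SensorMapFigure: %d sensors, %d highlighted\n",
              nrow(object@sensors), sum(object@sensors$highlighted)))
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## DyadSimConfig
## ---------------------------------------------------------------------------

#' Configuration for the synthetic dyad generator
#'
#' See [dyadSimConfig()] for field semantics and defaults.
#'
#' @slot nEpochs,nChannels,sfreq,duration,carrier see constructor.
#' @slot kappa phase-coupling strength in [0, 1].
#' @slot lag imposed phase lag (radians) at the coupled pairs.
#' @slot coupledPairs k x 2 integer matrix of (participant-1 channel,
#'   participant-2 channel) coupled pairs.
#' @slot rhoEnv envelope correlation in [-1, 1] at the coupled pairs.
#' @slot noiseSd additive white sensor noise, relative to signal RMS.
#' @slot phaseJitter phase random-walk increment SD (radians per sample).
#' @slot seed master seed; per-participant, per-epoch substreams derive
#'   from it.
#' @export
setClass("DyadSimConfig",
  representation(nEpochs = "integer", nChannels = "integer",
                 sfreq = "numeric", duration = "numeric", carrier = "numeric",
                 kappa = "numeric", lag = "numeric", coupledPairs = "matrix",
                 rhoEnv = "numeric", noiseSd = "numeric",
                 phaseJitter = "numeric", seed = "integer"))

setValidity("DyadSimConfig", function(object) {
  if (object@nEpochs < 1L || object@nChannels < 1L)
    return("nEpochs and nChannels must be >= 1")
  if (object@carrier >= object@sfreq / 2)
    return("carrier must be below the Nyquist frequency")
  if (object@kappa < 0 || object@kappa > 1)
    return("kappa must lie in [0, 1]")
  if (abs(object@rhoEnv) > 1) return("rhoEnv must lie in [-1, 1]")
  cp <- object@coupledPairs
  if (nrow(cp) && (ncol(cp) != 2L || any(cp < 1L) ||
                   any(cp > object@nChannels)))
    return("coupledPairs must reference valid channels (k x 2)")
  TRUE
})

setMethod("show", "DyadSimConfig", function(object) {
  cat(sprintf(
    "DyadSimConfig: %d epochs x %d ch, %g Hz, %g s, carrier %g Hz, kappa %g\n",
    object@nEpochs, object@nChannels, object@sfreq, object@duration,
    object@carrier, object@kappa))
  invisible(NULL)
})
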