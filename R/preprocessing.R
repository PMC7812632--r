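#' @include epochs-io.R
NULL

#' Mark epochs exceeding a peak-to-peak amplitude threshold
#'
#' A single global peak-to-peak criterion: an epoch is marked bad when any
#' non-bad channel's max - min amplitude within the epoch exceeds the
#' threshold. This simple documented rule is the package's artifact marker;
#' channels already listed in \code{badChannels(e)} are ignored.
#'
#' @param e an \linkS4class{EpochArray}.
#' @param threshold peak-to-peak threshold in volts (default 150e-6, i.e.
#'   150 microvolts).
#' @return Integer vector of bad epoch indices (possibly empty).
#' @examples
#' e <- EpochArray(array(0, c(3, 2, 50)), 100)
#' markBadEpochsPtp(e, 100e-6)  # integer(0)
#' @export
markBadEpochsPtp <- function(e, threshold = 150e-6) {
  stopifnot(is(e, "EpochArray"))
  if (length(threshold) != 1L || !is.finite(threshold) || threshold <= 0)
    stop("threshold must be a single positive voltage")
  good <- !(chNames(e) %in% badChannels(e))
  if (!any(good)) return(integer(0))
  dat <- e@data[, good, , drop = FALSE]
  ptp <- apply(dat, c(1L, 2L), function(v) max(v) - min(v))
  which(apply(ptp, 1L, max) > threshold)
}

#' Keep only epochs and channels good for every participant
#'
#' The cross-participant intersection rule: the kept epochs are the
#' intersection of each participant's kept epochs, and the dropped channels
#' are the union of each participant's bad channels (matched on de-suffixed
#' labels), removed from every participant. Applying the function twice
#' changes nothing.
#'
#' @param es list of \linkS4class{EpochArray} with equal epoch counts.
#' @param reports optional list (one per participant) of
#'   \code{list(badEpochs = <integer>, badChannels = <character>)}. When
#'   omitted, bad epochs are taken from [markBadEpochsPtp()] at
#'   \code{threshold} and bad channels from each container's
#'   \code{badChannels()}.
#' @param threshold peak-to-peak threshold (volts) used when deriving
#'   default reports; recorded in the returned report either way.
#' @return List with elements \code{epochs} (the cleaned containers, all with
#'   identical kept-epoch indices and identical de-suffixed channel lists)
#'   and \code{report} (a \linkS4class{RejectionReport}).
#' @export
intersectGood <- function(es, reports = NULL, threshold = 150e-6) {
  stopifnot(is.list(es), length(es) >= 1L,
            all(vapply(es, is, logical(1L), "EpochArray")))
  nE <- unique(vapply(es, nEpochs, integer(1L)))
  if (length(nE) != 1L)
    stop("all containers must have equal epoch counts before rejection (got ",
         paste(vapply(es, nEpochs, integer(1L)), collapse = ", "), ")")
  if (is.null(reports)) {
    reports <- lapply(es, function(e)
      list(badEpochs = markBadEpochsPtp(e, threshold),
           badChannels = badChannels(e)))
  }
  stopifnot(length(reports) == length(es))
  badEpochs <- lapply(reports, function(r) as.integer(r$badEpochs %||%
                                                        integer(0)))
  badCh <- lapply(reports, function(r) as.character(r$badChannels %||%
                                                      character(0)))
  keptEpochs <- setdiff(seq_len(nE), sort(unique(unlist(badEpochs))))
  if (!length(keptEpochs))
    stop("all epochs were rejected across participants; ",
         "refusing to return an empty container")
  deSuffix <- function(x) sub("_[12]$", "", x)
  dropped <- sort(unique(deSuffix(unlist(badCh))))
  out <- lapply(es, function(e) {
    keepCh <- which(!(deSuffix(chNames(e)) %in% dropped))
    if (!length(keepCh))
      stop("all channels were rejected across participants")
    subsetEpochs(e, epochs = keptEpochs, channels = keepCh)
  })
  report <- new("RejectionReport", badEpochs = badEpochs,
                badChannels = badCh, keptEpochs = as.integer(keptEpochs),
                droppedChannels = dropped, threshold = threshold)
  list(epochs = out, report = report)
}

#' Zero-phase high-pass filter for drift removal
#'
#' 4th-order Butterworth high-pass applied forward and backward
#' (zero phase) along the sample axis, channel by channel and epoch by
#' epoch. Intended for slow-drift removal ahead of artifact marking; the
#' synthetic-dyad fixtures use it in their generation path.
#'
#' @param e an \linkS4class{EpochArray}.
#' @param cutoff high-pass cutoff in Hz (default 1).
#' @return A filtered \linkS4class{EpochArray}.
#' @export
highpassFilter <- function(e, cutoff = 1) {
  stopifnot(is(e, "EpochArray"), cutoff > 0, cutoff < sfreq(e) / 2)
  bf <- signal::butter(4, cutoff / (sfreq(e) / 2), type = "high")
  dat <- e@data
  nS <- nSamples(e)
  ## odd-reflection padding keeps the filter's startup transient out of the
  ## epoch (the transient of a 1 Hz filter spans a sizable part of a short
  ## epoch otherwise)
  p <- min(nS - 1L, as.integer(3 * ceiling(sfreq(e) / cutoff)))
  for (ep in seq_len(nEpochs(e)))
    for (k in seq_len(nChannels(e))) {
      x <- dat[ep, k, ]
      xp <- c(2 * x[1L] - x[(p + 1L):2L], x,
              2 * x[nS] - x[(nS - 1L):(nS - p)])
      dat[ep, k, ] <- signal::filtfilt(bf, xp)[p + seq_len(nS)]
    }
  out <- e
  out@data <- dat
  out
}

#' Serialize a rejection report to JSON
#'
#' @param report a \linkS4class{RejectionReport}.
#' @param path optional output file; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
rejectionReportJson <- function(report, path = NULL) {
  stopifnot(is(report, "RejectionReport"))
  x <- list(
    bad_epochs = report@badEpochs,
    bad_channels = report@badChannels,
    kept_epochs = report@keptEpochs,
    dropped_channels = report@droppedChannels,
    threshold_volts = report@threshold
  )
  js <- jsonlite::toJSON(x, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
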