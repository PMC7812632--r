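#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Columnar text dialect
##
## Header lines:
##   # columnar-epochs v1
##   # participant=<id>
##   # sfreq=<Hz>
##   # units=volts
##   # ch=<name>:<x>,<y>,<z>      (":x,y,z" omitted when position-free)
##   # bads=<comma list>          (optional)
##   # droplog=<0/1 comma list>   (optional; 1 = dropped original epoch)
## then one line per (epoch, sample): leading epoch index (1-based),
## tab-separated channel values. Values are written with 17 significant
## digits, so the round-trip is bit-exact at double (a fortiori float32)
## precision.
## ---------------------------------------------------------------------------

#' Read an epoch container from disk
#'
#' Supported formats: the package's columnar text dialect (full fidelity) and
#' EDF (16-bit; positions, bads and the drop log are not representable in EDF
#' and come back empty). FIF requires an external backend that this package
#' does not bundle and is refused with a configuration error.
#'
#' @param path file path.
#' @param format one of "columnar", "edf", "fif"; default guesses from the
#'   file extension.
#' @return An \linkS4class{EpochArray}.
#' @examples
#' e <- EpochArray(array(rnorm(600), c(2, 3, 100)), sfreq = 100)
#' f <- tempfile(fileext = ".txt")
#' writeEpochs(e, f)
#' identical(epochData(readEpochs(f)), epochData(e))
#' @seealso [writeEpochs()]
#' @export
readEpochs <- function(path, format = c("auto", "columnar", "edf", "fif")) {
  format <- match.arg(format)
  if (format == "auto") format <- guessFormat(path)
  if (!file.exists(path))
    stop("cannot read epochs: no such file: ", path)
  switch(format,
    columnar = readColumnar(path),
    edf = readEdf(path),
    fif = stop("FIF support requires an external backend that is not ",
               "bundled with this package; convert to the columnar dialect ",
               "or EDF instead")
  )
}

#' Write an epoch container to disk
#'
#' @param e an \linkS4class{EpochArray}.
#' @param path output file path.
#' @param format "columnar" (default, full fidelity) or "edf".
#' @return The output path, invisibly.
#' @seealso [readEpochs()]
#' @export
writeEpochs <- function(e, path, format = c("auto", "columnar", "edf", "fif")) {
  stopifnot(is(e, "EpochArray"))
  format <- match.arg(format)
  if (format == "auto") format <- guessFormat(path)
  switch(format,
    columnar = writeColumnar(e, path),
    edf = writeEdf(e, path),
    fif = stop("FIF writing is not supported (no backend); ",
               "use format = \"columnar\"")
  )
  invisible(path)
}

guessFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, edf = "edf", fif = "fif", "columnar")
}

writeColumnar <- function(e, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# columnar-epochs v1", con)
  writeLines(sprintf("# participant=%s", e@participantId), con)
  writeLines(sprintf("# sfreq=%.17g", e@sfreq), con)
  writeLines("# units=volts", con)
  pos <- chPositions(e)
  for (k in seq_len(nChannels(e))) {
    if (positionFree(e)) {
      writeLines(sprintf("# ch=%s", e@chNames[k]), con)
    } else {
      writeLines(sprintf("# ch=%s:%.17g,%.17g,%.17g", e@chNames[k],
                         pos[k, 1L], pos[k, 2L], pos[k, 3L]), con)
    }
  }
  if (length(e@bads))
    writeLines(sprintf("# bads=%s", paste(e@bads, collapse = ",")), con)
  if (any(e@dropLog))
    writeLines(sprintf("# droplog=%s",
                       paste(as.integer(e@dropLog), collapse = ",")), con)
  nE <- nEpochs(e); nS <- nSamples(e)
  ## body: samples x (epoch index + channels), epoch blocks in order
  for (ep in seq_len(nE)) {
    block <- t(e@data[ep, , , drop = TRUE])
    if (nChannels(e) == 1L) block <- matrix(e@data[ep, 1L, ], ncol = 1L)
    lines <- apply(block, 1L, function(row)
      paste(c(ep, sprintf("%.17g", row)), collapse = "\t"))
    writeLines(lines, con)
  }
  path
}

readColumnar <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  getHdr <- function(key) {
    hit <- hdr[startsWith(hdr, paste0("# ", key, "="))]
    sub(paste0("^# ", key, "="), "", hit)
  }
  sf <- as.numeric(getHdr("sfreq"))
  if (length(sf) != 1L || !is.finite(sf))
    stop("columnar format error in ", path, ": missing or bad sfreq header")
  pid <- getHdr("participant")
  if (!length(pid)) pid <- "P1"
  chLines <- getHdr("ch")
  if (!length(chLines))
    stop("columnar format error in ", path, ": no channel headers")
  hasPos <- grepl(":", chLines, fixed = TRUE)
  if (any(hasPos) && !all(hasPos))
    stop("columnar format error in ", path,
         ": positions must be given for all channels or none")
  chNames <- sub(":.*$", "", chLines)
  if (all(hasPos)) {
    pos <- t(vapply(strsplit(sub("^[^:]*:", "", chLines), ","),
                    function(v) as.numeric(v), numeric(3L)))
  } else {
    pos <- NULL
  }
  bads <- getHdr("bads")
  bads <- if (length(bads)) strsplit(bads, ",")[[1L]] else character()
  dl <- getHdr("droplog")
  dropLog <- if (length(dl)) as.integer(strsplit(dl, ",")[[1L]]) == 1L else NULL
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L || nf[1L] != length(chNames) + 1L)
    stop("columnar format error in ", path,
         ": inconsistent channel count across rows")
  m <- matrix(as.numeric(unlist(fields)), ncol = nf[1L], byrow = TRUE)
  epIdx <- as.integer(m[, 1L])
  eps <- unique(epIdx)
  nPer <- tabulate(epIdx)[eps]
  if (length(unique(nPer)) != 1L)
    stop("columnar format error in ", path,
         ": inconsistent sample count across epochs")
  nS <- nPer[1L]; nE <- length(eps); nC <- length(chNames)
  dat <- array(0, c(nE, nC, nS))
  for (i in seq_len(nE)) {
    rows <- m[epIdx == eps[i], -1L, drop = FALSE]  # samples x channels
    dat[i, , ] <- t(rows)
  }
  EpochArray(dat, sfreq = sf, chNames = chNames, chPos = pos, bads = bads,
             participantId = pid, dropLog = dropLog)
}

## ---------------------------------------------------------------------------
## Minimal EDF backend: fixed-width ASCII header, int16 little-endian data,
## one EDF data record per epoch. Physical units are microvolts, as is usual
## for EEG EDFs; data are converted from/to volts at the boundary.
## ---------------------------------------------------------------------------

edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)  # left-justified, space padded
}

writeEdf <- function(e, path) {
  nC <- nChannels(e); nE <- nEpochs(e); nS <- nSamples(e)
  dur <- nS / e@sfreq
  uv <- e@data * 1e6
  physMax <- max(abs(range(uv)), 1)
  scale <- 32767 / physMax        # symmetric digital range, 1 LSB = 1/scale
  con <- file(path, open = "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edfPad(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8L)
  wr(paste0("X X X ", e@participantId), 80L)
  wr("Startdate 01-JAN-2000 X X X", 80L)
  wr("01.01.00", 8L)
  wr("00.00.00", 8L)
  wr(256L + 256L * nC, 8L)
  wr("", 44L)
  wr(nE, 8L)
  wr(sprintf("%.6g", dur), 8L)
  wr(nC, 4L)
  for (nm in e@chNames) wr(nm, 16L)
  for (k in seq_len(nC)) wr("", 80L)
  for (k in seq_len(nC)) wr("uV", 8L)
  for (k in seq_len(nC)) wr(sprintf("%.6g", -physMax), 8L)
  for (k in seq_len(nC)) wr(sprintf("%.6g", physMax), 8L)
  for (k in seq_len(nC)) wr(-32767L, 8L)
  for (k in seq_len(nC)) wr(32767L, 8L)
  for (k in seq_len(nC)) wr("", 80L)
  for (k in seq_len(nC)) wr(nS, 8L)
  for (k in seq_len(nC)) wr("", 32L)
  for (ep in seq_len(nE)) {
    for (k in seq_len(nC)) {
      dig <- as.integer(round(uv[ep, k, ] * scale))
      dig <- pmin(pmax(dig, -32767L), 32767L)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  path
}

readEdf <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8L)
  patient <- rd(80L)
  rd(80L); rd(8L); rd(8L)
  nHeader <- as.integer(rd(8L))
  rd(44L)
  nRec <- as.integer(rd(8L))
  dur <- as.numeric(rd(8L))
  nC <- as.integer(rd(4L))
  if (!is.finite(nRec) || !is.finite(dur) || !is.finite(nC) || nC < 1L)
    stop("EDF format error in ", path, ": unparsable header")
  labels <- vapply(seq_len(nC), function(k) rd(16L), character(1L))
  for (k in seq_len(nC)) rd(80L)               # transducer
  units <- vapply(seq_len(nC), function(k) rd(8L), character(1L))
  physMin <- as.numeric(vapply(seq_len(nC), function(k) rd(8L), character(1L)))
  physMax <- as.numeric(vapply(seq_len(nC), function(k) rd(8L), character(1L)))
  digMin <- as.numeric(vapply(seq_len(nC), function(k) rd(8L), character(1L)))
  digMax <- as.numeric(vapply(seq_len(nC), function(k) rd(8L), character(1L)))
  for (k in seq_len(nC)) rd(80L)               # prefilter
  nsPerRec <- as.integer(vapply(seq_len(nC), function(k) rd(8L),
                                character(1L)))
  for (k in seq_len(nC)) rd(32L)
  if (length(unique(nsPerRec)) != 1L)
    stop("EDF format error in ", path,
         ": inconsistent samples-per-record across channels")
  nS <- nsPerRec[1L]
  sf <- nS / dur
  gain <- (physMax - physMin) / (digMax - digMin)
  off <- physMin - gain * digMin
  toVolts <- ifelse(tolower(units) %in% c("uv", "µv"), 1e-6, 1)
  dat <- array(0, c(nRec, nC, nS))
  for (ep in seq_len(nRec)) {
    for (k in seq_len(nC)) {
      dig <- readBin(con, "integer", n = nS, size = 2L, endian = "little",
                     signed = TRUE)
      if (length(dig) != nS)
        stop("EDF format error in ", path, ": truncated data records")
      dat[ep, k, ] <- (dig * gain[k] + off[k]) * toVolts[k]
    }
  }
  pid <- sub("^.* ", "", patient)
  if (!nzchar(pid)) pid <- "P1"
  EpochArray(dat, sfreq = sf, chNames = labels, participantId = pid)
}

## ---------------------------------------------------------------------------
## merge / split
## ---------------------------------------------------------------------------

#' Merge two participants' epochs into one hyper-epoch container
#'
#' Concatenates the channel axes of two index-aligned epoch containers into a
#' single \linkS4class{HyperEpochArray}; channel names get participant
#' suffixes (default "_1" / "_2") and bad-channel labels are carried over with
#' their suffix. Alignment is strictly index-wise: unequal epoch counts are an
#' error, not a truncation.
#'
#' @param e1,e2 \linkS4class{EpochArray} objects with equal sfreq, epoch count
#'   and samples per epoch.
#' @param suffixes length-2 character vector of channel-name suffixes.
#' @return A \linkS4class{HyperEpochArray} with 2N channels; the first N
#'   channels are participant 1's.
#' @examples
#' a <- EpochArray(array(rnorm(600), c(2, 3, 100)), 100, participantId = "A")
#' b <- EpochArray(array(rnorm(600), c(2, 3, 100)), 100, participantId = "B")
#' h <- mergeDyad(a, b)
#' chNames(h)
#' @seealso [splitDyad()]
#' @export
mergeDyad <- function(e1, e2, suffixes = c("_1", "_2")) {
  stopifnot(is(e1, "EpochArray"), is(e2, "EpochArray"),
            length(suffixes) == 2L)
  if (e1@sfreq != e2@sfreq)
    stop("incompatible containers: sfreq differs (", e1@sfreq, " vs ",
         e2@sfreq, " Hz)")
  if (nSamples(e1) != nSamples(e2))
    stop("incompatible containers: samples per epoch differ (",
         nSamples(e1), " vs ", nSamples(e2), ")")
  if (nEpochs(e1) != nEpochs(e2))
    stop("epoch alignment error: participant 1 has ", nEpochs(e1),
         " epochs, participant 2 has ", nEpochs(e2))
  if (!setequal(chNames(e1), chNames(e2)))
    warning("channel sets differ between participants; merging as-is")
  n1 <- nChannels(e1); n2 <- nChannels(e2)
  if (n1 != n2)
    stop("hyper-epoch requires equal channel counts (", n1, " vs ", n2, ")")
  nE <- nEpochs(e1); nS <- nSamples(e1)
  dat <- array(0, c(nE, n1 + n2, nS))
  dat[, seq_len(n1), ] <- e1@data
  dat[, n1 + seq_len(n2), ] <- e2@data
  names1 <- paste0(chNames(e1), suffixes[1L])
  names2 <- paste0(chNames(e2), suffixes[2L])
  posFree <- positionFree(e1) || positionFree(e2)
  pos <- if (posFree) matrix(numeric(0), 0L, 3L) else
    rbind(chPositions(e1), chPositions(e2))
  suffixed <- function(x, sfx) if (length(x)) paste0(x, sfx) else character(0)
  bads <- c(suffixed(badChannels(e1), suffixes[1L]),
            suffixed(badChannels(e2), suffixes[2L]))
  new("HyperEpochArray",
      data = dat, sfreq = e1@sfreq, chNames = c(names1, names2),
      chPos = pos, bads = bads, dropLog = e1@dropLog | e2@dropLog,
      participantId = paste0(participantId(e1), "+", participantId(e2)),
      sourceIds = c(participantId(e1), participantId(e2)),
      suffixes = suffixes)
}

#' Split a hyper-epoch container back into two participants
#'
#' The inverse of [mergeDyad()]: suffixes are stripped (trailing match only)
#' and each participant recovers their channels, positions and bad-channel
#' labels. \code{splitDyad(mergeDyad(a, b))} reproduces \code{a} and \code{b}
#' exactly on data values.
#'
#' @param h a \linkS4class{HyperEpochArray}.
#' @return List of two \linkS4class{EpochArray} objects.
#' @export
splitDyad <- function(h) {
  stopifnot(is(h, "HyperEpochArray"))
  validObject(h)
  n <- nChannels(h) %/% 2L
  idx1 <- seq_len(n); idx2 <- n + seq_len(n)
  out <- vector("list", 2L)
  for (p in 1:2) {
    idx <- if (p == 1L) idx1 else idx2
    sfx <- h@suffixes[p]
    nm <- stripSuffix(h@chNames[idx], sfx)
    bads <- h@bads[endsWith(h@bads, sfx)]
    bads <- stripSuffix(bads, sfx)
    bads <- bads[bads %in% nm]
    pos <- if (positionFree(h)) NULL else h@chPos[idx, , drop = FALSE]
    out[[p]] <- EpochArray(h@data[, idx, , drop = FALSE], h@sfreq,
                           chNames = nm, chPos = pos, bads = bads,
                           participantId = h@sourceIds[p],
                           dropLog = h@dropLog)
  }
  out
}

## internal: subset epochs/channels, keeping metadata consistent.
## epochs indexes retained epochs; channels indexes the channel axis.
subsetEpochs <- function(e, epochs = seq_len(nEpochs(e)),
                         channels = seq_len(nChannels(e))) {
  keptOrig <- which(!e@dropLog)
  dropLog <- rep(TRUE, length(e@dropLog))
  dropLog[keptOrig[epochs]] <- FALSE
  nm <- e@chNames[channels]
  pos <- if (positionFree(e)) NULL else e@chPos[channels, , drop = FALSE]
  EpochArray(e@data[epochs, channels, , drop = FALSE], e@sfreq,
             chNames = nm, chPos = pos, bads = intersect(e@bads, nm),
             participantId = e@participantId, dropLog = dropLog)
}
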