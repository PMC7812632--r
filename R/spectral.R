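#' @include AllClasses.R
NULL

#' Minimum Welch segment length for a lowest frequency of interest
#'
#' The segment must span at least four periods of the lowest frequency to be
#' estimated: \code{ceil(4 * sfreq / fmin)} samples. For example, estimating
#' down to 4 Hz at a 1000 Hz sampling rate requires segments of at least
#' 1000 samples (one second).
#'
#' @param fmin lowest frequency of interest (Hz, > 0).
#' @param sfreq sampling rate (Hz, > 0).
#' @return Minimum segment length in samples.
#' @examples
#' minSegmentLength(4, 1000)   # 1000
#' minSegmentLength(7.5, 500)  # 267
#' @export
minSegmentLength <- function(fmin, sfreq) {
  if (!is.finite(fmin) || fmin <= 0 || !is.finite(sfreq) || sfreq <= 0)
    stop("fmin and sfreq must be positive")
  as.integer(ceiling(4 * sfreq / fmin))
}

#' Welch power spectral density of epoched data
#'
#' Per epoch and channel, the signal is cut into segments of \code{nPerSeg}
#' samples with 50\% overlap, each segment is mean-detrended, Hann-windowed
#' and Fourier-transformed (zero-padded to \code{nFft} when given), and the
#' one-sided periodograms are averaged. The frequency-bin spacing is
#' \code{sfreq / nFft} (or \code{sfreq / nPerSeg} when \code{nFft} is NULL);
#' the exact bins used are returned in the result's \code{freqList}.
#'
#' @param e an \linkS4class{EpochArray}.
#' @param fmin,fmax frequency range of interest (Hz).
#' @param nPerSeg Welch segment length in samples (<= samples per epoch).
#' @param nFft FFT length, NULL (default) or >= nPerSeg for zero padding.
#' @param epochsAverage average the per-epoch spectra (default TRUE); when
#'   FALSE the result keeps a leading epoch axis.
#' @return A \linkS4class{PsdResult} with power in V^2/Hz.
#' @examples
#' x <- array(sin(2 * pi * 10 * (0:255) / 256), c(1, 1, 256))
#' p <- welchPsd(EpochArray(x, 256), fmin = 2, fmax = 40, nPerSeg = 256)
#' freqs(p)[which.max(p@psd)]  # 10
#' @export
welchPsd <- function(e, fmin, fmax, nPerSeg, nFft = NULL,
                     epochsAverage = TRUE) {
  stopifnot(is(e, "EpochArray"))
  nS <- nSamples(e); sf <- sfreq(e)
  nPerSeg <- as.integer(nPerSeg)
  if (nPerSeg > nS)
    stop("nPerSeg (", nPerSeg, ") must not exceed samples per epoch (",
         nS, ")")
  if (!is.null(nFft)) {
    nFft <- as.integer(nFft)
    if (nFft < nPerSeg)
      stop("parameter error: n_fft has to be bigger or equal to n_per_seg (",
           nFft, " < ", nPerSeg, ")")
  } else {
    nFft <- nPerSeg
  }
  if (fmin > 0 && nPerSeg < minSegmentLength(fmin, sf))
    warning("nPerSeg = ", nPerSeg, " is below the recommended minimum of ",
            minSegmentLength(fmin, sf),
            " samples (four periods of fmin); low-frequency power ",
            "estimates will be unreliable")
  win <- hannWindow(nPerSeg)
  u <- sum(win^2)                       # window power normalization
  step <- max(1L, nPerSeg %/% 2L)       # 50% overlap
  starts <- seq(1L, nS - nPerSeg + 1L, by = step)
  freqAll <- (seq_len(nFft %/% 2L + 1L) - 1L) * sf / nFft
  sel <- which(freqAll >= fmin - 1e-9 & freqAll <= fmax + 1e-9)
  if (!length(sel))
    stop("no frequency bins inside [", fmin, ", ", fmax, "] Hz")
  nE <- nEpochs(e); nC <- nChannels(e)
  out <- array(0, c(nE, nC, length(sel)))
  for (ep in seq_len(nE)) {
    for (k in seq_len(nC)) {
      x <- e@data[ep, k, ]
      acc <- numeric(length(sel))
      for (s0 in starts) {
        seg <- x[s0:(s0 + nPerSeg - 1L)]
        seg <- (seg - mean(seg)) * win
        X <- stats::fft(c(seg, numeric(nFft - nPerSeg)))
        pxx <- (Mod(X)^2) / (sf * u)
        pxx <- pxx[seq_len(nFft %/% 2L + 1L)]
        ## one-sided scaling: double everything except DC (and Nyquist when
        ## nFft is even)
        dbl <- rep(2, length(pxx)); dbl[1L] <- 1
        if (nFft %% 2L == 0L) dbl[length(pxx)] <- 1
        acc <- acc + (pxx * dbl)[sel]
      }
      out[ep, k, ] <- acc / length(starts)
    }
  }
  params <- list(fmin = fmin, fmax = fmax, nFft = nFft, nPerSeg = nPerSeg,
                 epochsAverage = epochsAverage)
  psd <- if (epochsAverage) {
    m <- apply(out, c(2L, 3L), mean)
    array(m, dim(m))
  } else out
  new("PsdResult", psd = psd, freqList = freqAll[sel], params = params)
}

hannWindow <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0L, n - 1L) / (n - 1L))
}

#' Default frequency band table
#'
#' Named list of c(fmin, fmax) band edges: Theta 4-7, Alpha_Low 7.5-11,
#' Alpha_High 11.5-13, Beta 13.5-29.5, Gamma 30-48 Hz. Integer bins inside
#' each closed interval are the analysis bins, so e.g. Alpha_Low covers the
#' 8, 9, 10 and 11 Hz bins.
#'
#' @return Named list of length-2 numeric vectors.
#' @export
defaultFreqBands <- function() {
  list(Theta = c(4, 7), Alpha_Low = c(7.5, 11), Alpha_High = c(11.5, 13),
       Beta = c(13.5, 29.5), Gamma = c(30, 48))
}

#' Analytic-signal decomposition into integer-Hz bins per band
#'
#' For every integer frequency f inside each band's closed interval
#' \code{[fmin, fmax]}, the signal is band-passed around f (1 Hz passband,
#' 0.5 Hz raised-cosine transitions, zero phase) and the analytic signal is
#' taken, yielding complex values per epoch, channel, bin and sample. The
#' filter and Hilbert transform are applied jointly in the frequency domain
#' on reflection-padded epochs (the negative-frequency half is zeroed, which
#' is exactly the analytic-signal construction); each epoch is processed on
#' its own, with no cross-epoch concatenation. Both participants are
#' decomposed with identical bins, which makes the outputs element-wise
#' comparable.
#'
#' @param pair list of two \linkS4class{EpochArray} sharing sfreq, epoch
#'   count and samples per epoch (a single container is also accepted).
#' @param bands named list of c(fmin, fmax) band edges; default
#'   [defaultFreqBands()].
#' @return List of two \linkS4class{AnalyticSignal} objects (or one, if one
#'   container was given) sharing their \code{freqs}.
#' @examples
#' t <- (0:511) / 128
#' x <- array(rep(sin(2 * pi * 10 * t), each = 2)[1:1024], c(2, 1, 512))
#' e <- EpochArray(aperm(array(sin(2 * pi * 10 * (0:511) / 128),
#'                             c(512, 1, 2)), c(3, 2, 1)), 128)
#' a <- computeFreqBands(list(e, e), list(Alpha_Low = c(7.5, 11)))
#' freqs(a[[1]])  # 8 9 10 11
#' @export
computeFreqBands <- function(pair, bands = defaultFreqBands()) {
  single <- is(pair, "EpochArray")
  if (single) pair <- list(pair)
  stopifnot(all(vapply(pair, is, logical(1L), "EpochArray")))
  sf <- unique(vapply(pair, sfreq, numeric(1L)))
  nE <- unique(vapply(pair, nEpochs, integer(1L)))
  nS <- unique(vapply(pair, nSamples, integer(1L)))
  if (length(sf) != 1L || length(nE) != 1L || length(nS) != 1L)
    stop("participants must share sfreq, epoch count and samples per epoch")
  binList <- lapply(names(bands), function(b) {
    lim <- bands[[b]]
    f <- seq(ceiling(lim[1L] - 1e-9), floor(lim[2L] + 1e-9))
    f <- f[f >= lim[1L] - 1e-9 & f <= lim[2L] + 1e-9 & f > 0]
    if (!length(f))
      stop("band '", b, "' [", lim[1L], ", ", lim[2L],
           "] contains no integer frequency")
    if (max(f) >= sf / 2)
      stop("band '", b, "' exceeds the Nyquist frequency")
    f
  })
  names(binList) <- names(bands)
  allFreqs <- unlist(binList, use.names = FALSE)
  bandIdx <- list()
  off <- 0L
  for (b in names(bands)) {
    bandIdx[[b]] <- off + seq_along(binList[[b]])
    off <- off + length(binList[[b]])
  }
  out <- lapply(pair, function(e)
    analyticDecompose(e, allFreqs, bandIdx, sf))
  if (single) out[[1L]] else out
}

## frequency-domain band-pass + analytic signal on reflect-padded epochs
analyticDecompose <- function(e, freqsHz, bandIdx, sf) {
  nE <- nEpochs(e); nC <- nChannels(e); nS <- nSamples(e)
  pad <- min(nS, max(64L, nS %/% 2L))
  nT <- nS + 2L * pad
  fAxis <- (seq_len(nT) - 1L) * sf / nT
  fAxis[fAxis > sf / 2] <- fAxis[fAxis > sf / 2] - sf   # signed frequencies
  vals <- array(complex(real = 0), c(nE, nC, length(freqsHz), nS))
  masks <- lapply(freqsHz, function(f0) {
    h <- numeric(nT)
    pos <- fAxis > 0
    d <- abs(fAxis - f0)
    h[pos & d <= 0.5] <- 1
    tr <- pos & d > 0.5 & d <= 1
    h[tr] <- 0.5 * (1 + cos(pi * (d[tr] - 0.5) / 0.5))
    2 * h    # doubling the positive half yields the analytic signal
  })
  keep <- pad + seq_len(nS)
  for (ep in seq_len(nE)) {
    x <- matrix(e@data[ep, , ], nrow = nC)        # channels x samples
    xp <- cbind(x[, pad:1, drop = FALSE], x, x[, nS:(nS - pad + 1L),
                                               drop = FALSE])
    X <- stats::mvfft(t(xp))                      # samples x channels
    for (q in seq_along(freqsHz)) {
      a <- stats::mvfft(X * masks[[q]], inverse = TRUE) / nT
      vals[ep, , q, ] <- t(a[keep, , drop = FALSE])
    }
  }
  new("AnalyticSignal", values = vals, freqs = as.numeric(freqsHz),
      bandIndex = bandIdx, sfreq = sf, chNames = chNames(e))
}
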