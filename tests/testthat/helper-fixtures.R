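# shared fixture builders; everything is generated in code at test time

# epochs of a pure sinusoid, identical across epochs
sineEpochs <- function(freq = 10, sfreq = 128, nEpochs = 2, nChannels = 1,
                       duration = 2, phase = 0, amp = 1) {
  nS <- as.integer(sfreq * duration)
  t <- (seq_len(nS) - 1) / sfreq
  x <- amp * sin(2 * pi * freq * t + phase)
  dat <- array(rep(x, each = nEpochs * nChannels), c(nEpochs, nChannels, nS))
  EpochArray(dat, sfreq)
}

# random epochs with optional positions
noiseEpochs <- function(nEpochs = 3, nChannels = 4, nSamples = 128,
                        sfreq = 128, seed = 1, positions = TRUE,
                        amp = 1e-5) {
  set.seed(seed)
  dat <- array(rnorm(nEpochs * nChannels * nSamples),
               c(nEpochs, nChannels, nSamples)) * amp
  pos <- if (positions) capPositions(nChannels) else NULL
  EpochArray(dat, sfreq, chPos = pos)
}

# sensors on an upper spherical cap (generic montage stand-in)
capPositions <- function(n, radius = 0.09) {
  k <- seq_len(n)
  polar <- 0.3 + 0.9 * (k - 1) / max(n - 1, 1)
  azim <- (k - 1) * 2.399963
  cbind(radius * sin(polar) * cos(azim),
        radius * sin(polar) * sin(azim),
        radius * cos(polar))
}

# wrap a complex array into an AnalyticSignal with single-bin bands
makeAnalytic <- function(vals, freqsHz, sfreq = 128,
                         bands = NULL) {
  if (is.null(bands)) {
    bands <- as.list(seq_along(freqsHz))
    names(bands) <- paste0("b", freqsHz)
    bands <- lapply(bands, function(i) i)
  }
  new("AnalyticSignal", values = vals, freqs = as.numeric(freqsHz),
      bandIndex = bands, sfreq = sfreq,
      chNames = paste0("Ch", seq_len(dim(vals)[2L])))
}

# complex white analytic noise: epochs x channels x bins x samples
randAnalytic <- function(nE = 2, nC = 3, freqsHz = 10, nS = 64, seed = 1) {
  set.seed(seed)
  n <- nE * nC * length(freqsHz) * nS
  vals <- array(complex(real = rnorm(n), imaginary = rnorm(n)),
                c(nE, nC, length(freqsHz), nS))
  makeAnalytic(vals, freqsHz)
}

# 2-D grid cell adjacency (nr x nc cells, column-major indexing)
gridAdjacency <- function(nr, nc) {
  n <- nr * nc
  A <- matrix(FALSE, n, n)
  idx <- function(r, c) (c - 1L) * nr + r
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (r < nr) A[idx(r, c), idx(r + 1L, c)] <- TRUE
    if (c < nc) A[idx(r, c), idx(r, c + 1L)] <- TRUE
  }
  A | t(A)
}

# inter-brain PLV at the (1, 1) channel pair of a dyad, at the carrier bin
dyadPairMetric <- function(dyad, mode, band = list(a = c(9.5, 10.5)), ...) {
  as <- computeFreqBands(dyad, band)
  sliceBlocks(computeSync(as, mode, ...))$inter12[1L, 1L]
}
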