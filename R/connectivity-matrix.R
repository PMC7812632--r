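#' @include connectivity-metrics.R mvar.R
NULL

syncModes <- c("coh", "imaginary_coh", "plv", "pli", "ccorr",
               "envelope_corr", "pow_corr", "proj_pow_corr", "pdc",
               "transfer_entropy")
directionalModes <- c("pdc", "transfer_entropy")

#' Joint two-participant connectivity from analytic signals
#'
#' Computes the requested metric channel-pair-wise on the stacked 2N channels
#' of a dyad and assembles the (bands x 2N x 2N) joint matrix: intra-brain
#' blocks on the diagonal, inter-brain blocks off it (see [sliceBlocks()]).
#' Per-bin metrics (phase, envelope and coherency families) are evaluated at
#' every integer-Hz bin and averaged (unweighted) over each band's bins;
#' phase metrics are computed over time within each epoch and then averaged
#' across epochs, while coherency-family expectations run jointly over
#' samples and epochs. Directed metrics work on the band-limited real signal:
#' pdc fits one MVAR across epochs (coefficients averaged) and evaluates at
#' the band's bin frequencies; transfer_entropy is estimated per epoch and
#' averaged. For directed metrics cell (i, j) carries the influence of
#' channel j on channel i.
#'
#' @param pair list of two \linkS4class{AnalyticSignal} objects sharing
#'   shape and bins (as returned by [computeFreqBands()]).
#' @param mode metric name, one of coh, imaginary_coh, plv, pli, ccorr,
#'   envelope_corr, pow_corr, proj_pow_corr, pdc, transfer_entropy.
#' @param epochsAverage average over epochs (default TRUE); when FALSE the
#'   result keeps a leading epoch axis (per-epoch MVAR fits for pdc).
#' @param mvarOrder MVAR order for pdc (default 5).
#' @param teLag transfer-entropy lag order (default 1).
#' @param ccorrMethod "circular" (default) or "pearson" (compatibility
#'   switch, see [ccorr()]).
#' @return A \linkS4class{ConnectivityMatrix}.
#' @seealso [computeFreqBands()], [sliceBlocks()], [standardize()]
#' @export
computeSync <- function(pair, mode, epochsAverage = TRUE, mvarOrder = 5L,
                        teLag = 1L, ccorrMethod = c("circular", "pearson")) {
  if (!mode %in% syncModes)
    stop("unknown mode '", mode, "'; choose one of: ",
         paste(syncModes, collapse = ", "))
  ccorrMethod <- match.arg(ccorrMethod)
  stopifnot(is.list(pair), length(pair) == 2L,
            all(vapply(pair, is, logical(1L), "AnalyticSignal")))
  a1 <- pair[[1L]]; a2 <- pair[[2L]]
  if (!identical(dim(a1@values), dim(a2@values)))
    stop("the two analytic signals must share their shape")
  if (!isTRUE(all.equal(a1@freqs, a2@freqs)))
    stop("the two analytic signals must share their frequency bins")
  nE <- nEpochs(a1); n1 <- nChannels(a1); nS <- nSamples(a1)
  nCh <- 2L * n1
  bands <- names(bandIndex(a1))
  nBand <- length(bands)
  X <- array(complex(real = 0), c(nE, nCh, length(a1@freqs), nS))
  X[, seq_len(n1), , ] <- a1@values
  X[, n1 + seq_len(n1), , ] <- a2@values
  chLabels <- c(paste0(chNames(a1), "_1"), paste0(chNames(a2), "_2"))
  directional <- mode %in% directionalModes

  if (!directional) {
    perEpoch <- array(0, c(nE, nBand, nCh, nCh))
    if (mode %in% c("coh", "imaginary_coh") && epochsAverage) {
      vals <- array(0, c(nBand, nCh, nCh))
      for (b in seq_len(nBand)) {
        binIdx <- bandIndex(a1)[[b]]
        acc <- matrix(0, nCh, nCh)
        for (q in binIdx) {
          cross <- matrix(0i, nCh, nCh)
          for (ep in seq_len(nE)) {
            Xm <- matrix(X[ep, , q, ], nrow = nCh)
            cross <- cross + Xm %*% t(Conj(Xm))
          }
          acc <- acc + cohFromCross(cross, mode)
        }
        vals[b, , ] <- symmetrizeExact(acc / length(binIdx))
      }
      return(newConnMatrix(vals, mode, FALSE, n1, bands, chLabels))
    }
    for (ep in seq_len(nE)) {
      for (b in seq_len(nBand)) {
        binIdx <- bandIndex(a1)[[b]]
        acc <- matrix(0, nCh, nCh)
        for (q in binIdx) {
          Xm <- matrix(X[ep, , q, ], nrow = nCh)
          acc <- acc + binMetricMatrix(Xm, mode, ccorrMethod)
        }
        perEpoch[ep, b, , ] <- symmetrizeExact(acc / length(binIdx))
      }
    }
    vals <- if (epochsAverage) {
      v <- apply(perEpoch, c(2L, 3L, 4L), mean)
      ## exact symmetry survives averaging, but enforce against float drift
      for (b in seq_len(nBand)) v[b, , ] <- symmetrizeExact(v[b, , ])
      v
    } else perEpoch
    return(newConnMatrix(vals, mode, FALSE, n1, bands, chLabels))
  }

  ## --- directed metrics on the band-limited real signal -------------------
  bandSignal <- function(b) {
    binIdx <- bandIndex(a1)[[b]]
    sig <- array(0, c(nE, nCh, nS))
    for (ep in seq_len(nE)) {
      acc <- matrix(0, nCh, nS)
      for (q in binIdx) acc <- acc + Re(matrix(X[ep, , q, ], nrow = nCh))
      sig[ep, , ] <- acc
    }
    sig
  }
  if (epochsAverage) {
    vals <- array(0, c(nBand, nCh, nCh))
    for (b in seq_len(nBand)) {
      sig <- bandSignal(b)
      if (mode == "pdc") {
        model <- fitMvar(sig, order = mvarOrder, chNames = chLabels)
        P <- pdc(model, a1@freqs[bandIndex(a1)[[b]]], sfreq(a1))
        vals[b, , ] <- apply(P, c(1L, 2L), mean)
      } else {
        vals[b, , ] <- teMatrix(sig, teLag, average = TRUE)
      }
    }
    return(newConnMatrix(vals, mode, TRUE, n1, bands, chLabels))
  }
  vals <- array(0, c(nE, nBand, nCh, nCh))
  for (b in seq_len(nBand)) {
    sig <- bandSignal(b)
    for (ep in seq_len(nE)) {
      one <- matrix(sig[ep, , ], nrow = nCh)
      if (mode == "pdc") {
        model <- fitMvar(one, order = mvarOrder, chNames = chLabels)
        P <- pdc(model, a1@freqs[bandIndex(a1)[[b]]], sfreq(a1))
        vals[ep, b, , ] <- apply(P, c(1L, 2L), mean)
      } else {
        vals[ep, b, , ] <- teMatrix(array(one, c(1L, dim(one))), teLag,
                                    average = TRUE)
      }
    }
  }
  newConnMatrix(vals, mode, TRUE, n1, bands, chLabels)
}

newConnMatrix <- function(vals, mode, directional, nCh, bands, chLabels) {
  new("ConnectivityMatrix", values = vals, metric = mode,
      directional = directional, nCh = as.integer(nCh),
      bandNames = bands, chNames = chLabels)
}

symmetrizeExact <- function(m) (m + t(m)) / 2

## per-(epoch, bin) metric matrices on a channels x samples complex slab
binMetricMatrix <- function(Xm, mode, ccorrMethod = "circular") {
  nS <- ncol(Xm)
  switch(mode,
    plv = {
      U <- exp(1i * Arg(Xm))
      pmin(Mod(U %*% t(Conj(U))) / nS, 1)
    },
    pli = {
      phi <- Arg(Xm)
      S <- sin(phi); C <- cos(phi)
      out <- matrix(0, nrow(Xm), nrow(Xm))
      for (j in seq_len(nrow(Xm))) {
        sd_ <- sweep(C, 2L, S[j, ], "*") - sweep(S, 2L, C[j, ], "*")
        ## row k of sd_ is sin(phi_j - phi_k) over samples
        out[j, ] <- abs(rowMeans(sign(sd_)))
      }
      diag(out) <- 0
      out
    },
    ccorr = {
      phi <- Arg(Xm)
      if (ccorrMethod == "pearson") {
        r <- suppressWarnings(stats::cor(t(phi)))
        r[!is.finite(r)] <- 0
        diag(r) <- 1
        return(r)
      }
      mu <- Arg(rowMeans(exp(1i * phi)))
      Sn <- sin(sweep(phi, 1L, mu, "-"))
      num <- Sn %*% t(Sn)
      rs <- rowSums(Sn^2)
      den <- sqrt(outer(rs, rs))
      r <- num / pmax(den, .EPS)
      r[den < .EPS] <- 0
      pmin(pmax(r, -1), 1)
    },
    envelope_corr = corrOrZero(t(Mod(Xm))),
    pow_corr = corrOrZero(t(Mod(Xm)^2)),
    proj_pow_corr = {
      nC <- nrow(Xm)
      R <- matrix(0, nC, nC)
      env <- Mod(Xm)
      for (j in seq_len(nC)) {
        u <- Conj(Xm[j, ]) / pmax(env[j, ], .EPS)
        orth <- abs(Im(t(t(Xm) * u)))       # channels x samples
        R[j, ] <- suppressWarnings(stats::cor(env[j, ], t(orth)))
      }
      R[!is.finite(R)] <- 0
      symmetrizeExact(R)
    },
    coh = ,
    imaginary_coh = {
      cross <- Xm %*% t(Conj(Xm))
      cohFromCross(cross, mode)
    },
    stop("unhandled mode ", mode)
  )
}

corrOrZero <- function(m) {
  r <- suppressWarnings(stats::cor(m))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  r
}

cohFromCross <- function(cross, mode) {
  ## ratios are Cauchy-Schwarz bounded; the floor only guards 0/0, so it
  ## must sit far below any physical signal power (volts^2 scale)
  p <- Re(diag(cross))
  if (mode == "coh") {
    den <- outer(p, p)
    pmin(Mod(cross)^2 / pmax(den, 1e-300), 1)
  } else {
    den <- sqrt(outer(p, p))
    pmin(abs(Im(cross / pmax(den, 1e-300))), 1)
  }
}

teMatrix <- function(sig, k, average = TRUE) {
  nE <- dim(sig)[1L]; nC <- dim(sig)[2L]
  acc <- matrix(0, nC, nC)
  for (ep in seq_len(nE)) {
    one <- matrix(sig[ep, , ], nrow = nC)
    for (i in seq_len(nC)) for (j in seq_len(nC)) {
      if (i == j) next
      te <- tryCatch(transferEntropy(one[j, ], one[i, ], k = k),
                     error = function(e) 0)
      acc[i, j] <- acc[i, j] + te
    }
  }
  acc / nE
}

#' @describeIn sliceBlocks slice one band (and epoch, for per-epoch results)
#'   of a \linkS4class{ConnectivityMatrix}
#' @param band band index or name (default first band).
#' @param epoch epoch index for per-epoch matrices (default first).
#' @export
setMethod("sliceBlocks", "ConnectivityMatrix", function(x, band = 1L,
                                                        epoch = 1L) {
  if (is.character(band)) band <- match(band, x@bandNames)
  v <- x@values
  m <- if (length(dim(v)) == 3L) v[band, , ] else v[epoch, band, , ]
  out <- sliceBlocks(m)
  out
})

#' @describeIn sliceBlocks slice a plain 2N x 2N matrix
#' @export
setMethod("sliceBlocks", "matrix", function(x, ...) {
  side <- nrow(x)
  if (side != ncol(x) || side %% 2L != 0L)
    stop("expected a square matrix with even side")
  n <- side %/% 2L
  i1 <- seq_len(n); i2 <- n + seq_len(n)
  list(intra1 = x[i1, i1, drop = FALSE],
       intra2 = x[i2, i2, drop = FALSE],
       inter12 = x[i1, i2, drop = FALSE],
       inter21 = x[i2, i1, drop = FALSE])
})

#' Grand z-score standardization of a connectivity block
#'
#' Zeroes the diagonal, then subtracts the grand mean and divides by the
#' grand (population) standard deviation, both computed over all N^2 cells
#' including the zeroed diagonal. The output therefore has grand mean 0 and
#' grand standard deviation 1 by construction. Positive rescaling of the
#' input leaves the output unchanged.
#'
#' @param block square numeric matrix (a connectivity block).
#' @return Standardized matrix of the same shape.
#' @examples
#' m <- matrix(runif(16), 4)
#' z <- standardize(m)
#' c(mean(z), sqrt(mean((z - mean(z))^2)))  # 0, 1
#' @export
standardize <- function(block) {
  stopifnot(is.matrix(block), nrow(block) == ncol(block))
  v <- block
  diag(v) <- 0
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s < .EPS)
    stop("undefined standardization: zero variance after diagonal zeroing")
  (v - m) / s
}
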