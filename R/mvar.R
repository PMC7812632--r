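#' @include AllClasses.R
NULL

#' Least-squares multivariate autoregression
#'
#' Fits \deqn{x_t = \sum_{m=1}^p A_m x_{t-m} + \epsilon_t} by ordinary least
#' squares per epoch (channels demeaned within epoch), with coefficient
#' matrices averaged across epochs. The residual covariance is pooled over
#' epochs using the averaged coefficients. Stability is assessed from the
#' companion-matrix spectral radius and recorded as a flag.
#'
#' @param data channels x samples matrix, or epochs x channels x samples
#'   array.
#' @param order model order p (>= 1).
#' @param chNames optional channel labels.
#' @return An \linkS4class{MvarModel}.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(2 * 2000), 2)
#' for (t in 3:2000) x[1, t] <- 0.5 * x[1, t - 1] + x[1, t]
#' m <- fitMvar(x, order = 1)
#' @seealso [pdc()]
#' @export
fitMvar <- function(data, order = 5L, chNames = NULL) {
  p <- as.integer(order)
  if (p < 1L) stop("parameter error: MVAR order must be >= 1")
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  stopifnot(length(dim(data)) == 3L)
  nE <- dim(data)[1L]; nC <- dim(data)[2L]; nS <- dim(data)[3L]
  if (nS - p <= p * nC)
    stop("not identifiable: need samples per epoch > order * channels + ",
         "order (", nS, " samples, ", nC, " channels, order ", p,
         "); try a lower order")
  if (is.null(chNames)) chNames <- paste0("Ch", seq_len(nC))
  Bsum <- matrix(0, nC, nC * p)
  for (ep in seq_len(nE)) {
    x <- matrix(data[ep, , ], nrow = nC)
    x <- x - rowMeans(x)
    Y <- x[, (p + 1L):nS, drop = FALSE]                   # C x T
    Z <- do.call(rbind, lapply(seq_len(p), function(m)
      x[, (p + 1L - m):(nS - m), drop = FALSE]))          # (C p) x T
    qrz <- qr(t(Z))
    if (qrz$rank < nrow(Z))
      stop("MVAR estimation error: rank-deficient regressors; ",
           "try a lower order")
    Bsum <- Bsum + t(qr.coef(qrz, t(Y)))                  # C x (C p)
  }
  B <- Bsum / nE
  ## pooled residual covariance under the averaged coefficients
  Rsum <- matrix(0, nC, nC)
  nT <- 0L
  for (ep in seq_len(nE)) {
    x <- matrix(data[ep, , ], nrow = nC)
    x <- x - rowMeans(x)
    Y <- x[, (p + 1L):nS, drop = FALSE]
    Z <- do.call(rbind, lapply(seq_len(p), function(m)
      x[, (p + 1L - m):(nS - m), drop = FALSE]))
    Rres <- Y - B %*% Z
    Rsum <- Rsum + tcrossprod(Rres)
    nT <- nT + ncol(Y)
  }
  residCov <- Rsum / nT
  coefs <- array(0, c(nC, nC, p))
  for (m in seq_len(p))
    coefs[, , m] <- B[, ((m - 1L) * nC + 1L):(m * nC), drop = FALSE]
  ## companion matrix stability
  comp <- matrix(0, nC * p, nC * p)
  comp[seq_len(nC), ] <- B
  if (p > 1L)
    comp[(nC + 1L):(nC * p), seq_len(nC * (p - 1L))] <-
      diag(nC * (p - 1L))
  rad <- max(Mod(eigen(comp, only.values = TRUE)$values))
  new("MvarModel", order = p, coefs = coefs, residCov = residCov,
      stable = rad < 1, chNames = as.character(chNames))
}

#' Partial directed coherence from an MVAR model
#'
#' Classic (Baccala-Sameshima) PDC:
#' \deqn{PDC_{ij}(f) = \frac{|\bar A_{ij}(f)|}{\sqrt{\sum_k |\bar
#'   A_{kj}(f)|^2}}, \quad \bar A(f) = I - \sum_m A_m e^{-i 2\pi f m / f_s}}
#' Cell (i, j) measures the directed influence of channel j on channel i;
#' each column's squared entries sum to 1 at every frequency. An unstable
#' model triggers a warning but values are still returned.
#'
#' @param model an \linkS4class{MvarModel}.
#' @param freqsHz frequencies (Hz) at which to evaluate.
#' @param sfreq sampling rate (Hz).
#' @return Array C x C x length(freqsHz) of PDC values in [0, 1].
#' @export
pdc <- function(model, freqsHz, sfreq) {
  stopifnot(is(model, "MvarModel"))
  if (!model@stable)
    warning("MVAR model is unstable (companion spectral radius >= 1); ",
            "PDC values may be unreliable")
  nC <- dim(model@coefs)[1L]
  out <- array(0, c(nC, nC, length(freqsHz)),
               dimnames = list(model@chNames, model@chNames, freqsHz))
  for (q in seq_along(freqsHz)) {
    Abar <- diag(nC) + 0i
    for (m in seq_len(model@order))
      Abar <- Abar - model@coefs[, , m] *
        exp(-2i * pi * freqsHz[q] * m / sfreq)
    mag <- Mod(Abar)
    den <- sqrt(colSums(mag^2))
    out[, , q] <- sweep(mag, 2L, pmax(den, .EPS), "/")
  }
  out
}
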