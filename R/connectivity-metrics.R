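#' @include AllClasses.R
NULL

.EPS <- 1e-12

checkPhases <- function(x, y, minLen = 2L) {
  if (length(x) != length(y))
    stop("phase series must have equal lengths")
  if (length(x) < minLen)
    stop("degenerate input: need at least ", minLen, " samples")
  invisible(NULL)
}

#' Phase-locking value
#'
#' Modulus of the time-averaged unit phasor of the phase difference:
#' \code{|mean(exp(1i * (x - y)))|}. 1 means a perfectly constant phase
#' relation (at any constant offset); for independent uniform phases the
#' expected value decays as \code{sqrt(pi/4)/sqrt(n)}.
#'
#' @param phaseX,phaseY instantaneous phases (radians) over one epoch,
#'   equal lengths >= 2.
#' @return Value in [0, 1].
#' @examples
#' plv(1:100 * 0.1, 1:100 * 0.1 + pi / 2)  # 1: offset-invariant
#' @export
plv <- function(phaseX, phaseY) {
  checkPhases(phaseX, phaseY)
  Mod(mean(exp(1i * (phaseX - phaseY))))
}

#' Phase lag index
#'
#' Modulus of the time-averaged sign of the sine of the phase difference;
#' sin(0) contributes 0. Insensitive to zero-lag coupling: identical phases
#' give 0, a constant nonzero lag inside (0, pi) gives 1.
#'
#' @inheritParams plv
#' @return Value in [0, 1].
#' @export
pli <- function(phaseX, phaseY) {
  checkPhases(phaseX, phaseY)
  abs(mean(sign(sin(phaseX - phaseY))))
}

circularMean <- function(x) Arg(mean(exp(1i * x)))

#' Circular correlation coefficient of two phase series
#'
#' The circular-statistics (sine-deviation) form:
#' \deqn{\rho = \frac{\sum \sin(x-\bar x)\sin(y-\bar y)}
#'   {\sqrt{\sum \sin^2(x-\bar x)\,\sum \sin^2(y-\bar y)}}}
#' with circular means \eqn{\bar x,\bar y}. A literal Pearson correlation on
#' the wrapped angle values is available as a compatibility switch
#' (\code{method = "pearson"}), but it is discontinuous at +/-pi and not the
#' default.
#'
#' @inheritParams plv
#' @param method "circular" (default) or "pearson".
#' @return Value in [-1, 1].
#' @export
ccorr <- function(phaseX, phaseY, method = c("circular", "pearson")) {
  method <- match.arg(method)
  checkPhases(phaseX, phaseY, minLen = 3L)
  if (method == "pearson")
    return(stats::cor(phaseX, phaseY))
  sx <- sin(phaseX - circularMean(phaseX))
  sy <- sin(phaseY - circularMean(phaseY))
  den <- sqrt(sum(sx^2) * sum(sy^2))
  if (den < .EPS)
    stop("undefined circular correlation: zero angular variance")
  sum(sx * sy) / den
}

asComplexMatrix <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
}

#' Magnitude-squared coherence of two analytic series
#'
#' \code{|<x conj(y)>|^2 / (<|x|^2> <|y|^2>)}, the expectation running over
#' all supplied values (epochs x samples). A single value pair has no
#' averaging support and is identically 1, so it is refused.
#'
#' @param x,y complex analytic values at one frequency bin: vectors or
#'   epochs x samples matrices of equal shape.
#' @return Value in [0, 1].
#' @export
coherence <- function(x, y) {
  x <- asComplexMatrix(x); y <- asComplexMatrix(y)
  stopifnot(all(dim(x) == dim(y)))
  if (length(x) < 2L)
    stop("degenerate coherence estimate: a single unaveraged segment is ",
         "identically 1; provide at least 2 values")
  sxy <- mean(x * Conj(y))
  den <- mean(Mod(x)^2) * mean(Mod(y)^2)
  ## the ratio is Cauchy-Schwarz bounded; the floor only guards 0/0
  min(Mod(sxy)^2 / max(den, 1e-300), 1)
}

#' Absolute imaginary part of the coherency
#'
#' \code{|Im(<x conj(y)> / sqrt(<|x|^2> <|y|^2>))|}; discards zero-lag
#' (instantaneous) dependence, so y = x gives 0.
#'
#' @inheritParams coherence
#' @return Value in [0, 1].
#' @export
imaginaryCoherence <- function(x, y) {
  x <- asComplexMatrix(x); y <- asComplexMatrix(y)
  stopifnot(all(dim(x) == dim(y)))
  if (length(x) < 2L)
    stop("degenerate coherency estimate: provide at least 2 values")
  sxy <- mean(x * Conj(y))
  den <- sqrt(mean(Mod(x)^2) * mean(Mod(y)^2))
  min(abs(Im(sxy / max(den, 1e-300))), 1)
}

envCor <- function(a, b) {
  if (stats::sd(a) < .EPS || stats::sd(b) < .EPS)
    stop("undefined correlation: zero envelope variance")
  stats::cor(a, b)
}

#' Envelope correlation
#'
#' Pearson correlation of the instantaneous envelopes |x| and |y| over time.
#'
#' @inheritParams coherence
#' @return Value in [-1, 1].
#' @export
envelopeCorr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  envCor(Mod(x), Mod(y))
}

#' Power correlation
#'
#' Pearson correlation of the instantaneous powers |x|^2 and |y|^2 over time.
#'
#' @inheritParams coherence
#' @return Value in [-1, 1].
#' @export
powCorr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  envCor(Mod(x)^2, Mod(y)^2)
}

#' Projected (orthogonalized) power correlation
#'
#' Removes the per-sample component of y parallel to x in the complex plane
#' (\code{y_orth = Im(y * conj(x) / |x|)}) before correlating |x| with
#' |y_orth|, discounting spuriously shared zero-lag signal. The one-sided
#' value is direction-dependent, so the reported value averages both
#' orthogonalization directions. If the orthogonalized residual has zero
#' variance (y is a complex multiple of x), the correlation is undefined and
#' 0 is returned with attribute \code{degenerate = TRUE}.
#'
#' @inheritParams coherence
#' @param symmetrize average both orthogonalization directions
#'   (default TRUE).
#' @return Value in [-1, 1], possibly carrying a \code{degenerate} attribute.
#' @export
projPowCorr <- function(x, y, symmetrize = TRUE) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  one <- function(a, b) {
    bOrth <- Im(b * Conj(a) / pmax(Mod(a), .EPS))
    if (stats::sd(abs(bOrth)) < .EPS || stats::sd(Mod(a)) < .EPS)
      return(NA_real_)
    stats::cor(Mod(a), abs(bOrth))
  }
  r1 <- one(x, y)
  r2 <- if (symmetrize) one(y, x) else r1
  if (is.na(r1) && is.na(r2)) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  mean(c(r1, r2), na.rm = TRUE)
}

#' Gaussian-estimator transfer entropy
#'
#' TE(x -> y) with lag order k under the linear-Gaussian model: half the log
#' ratio of the residual variance of y_t given its own k past values to the
#' residual variance given additionally x's k past values. By construction
#' this equals half the linear Granger-causality log statistic, and it is
#' non-negative (nested least squares).
#'
#' @param x,y real-valued series of equal length (> 10 * k).
#' @param k lag order (default 1).
#' @return Transfer entropy in nats (>= 0).
#' @examples
#' set.seed(1); x <- rnorm(5000); y <- c(0, 0.8 * x[-5000]) + rnorm(5000)
#' transferEntropy(x, y)           # about 0.5 * log(1.64)
#' @export
transferEntropy <- function(x, y, k = 1L) {
  k <- as.integer(k)
  stopifnot(length(x) == length(y), k >= 1L)
  n <- length(x)
  if (n <= 10L * k)
    stop("series too short for lag ", k, ": need length > ", 10L * k)
  idx <- (k + 1L):n
  lagMat <- function(v) {
    m <- vapply(seq_len(k), function(m) v[idx - m], numeric(length(idx)))
    matrix(m, ncol = k)
  }
  yt <- y[idx] - mean(y[idx])
  Zr <- scale(lagMat(y), scale = FALSE)
  Zf <- cbind(Zr, scale(lagMat(x), scale = FALSE))
  rssOf <- function(Z) {
    qrz <- qr(Z)
    if (qrz$rank < ncol(Z))
      stop("undefined transfer entropy: singular conditioning covariance")
    sum(qr.resid(qrz, yt)^2)
  }
  te <- 0.5 * log(rssOf(Zr) / rssOf(Zf))
  max(te, 0)
}
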