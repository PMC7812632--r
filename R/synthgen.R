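#' @include epochs-io.R
NULL

#' Configure the synthetic dyad generator
#'
#' Defaults describe a small but realistic resting-style dyad: 20 epochs of
#' 2 s at 128 Hz, 4 channels per participant, a 10 Hz (alpha) carrier, phase
#' random-walk jitter of 0.3 rad/sample (a Lorentzian linewidth of about
#' 1 Hz, typical of resting alpha) and 10\% relative sensor noise. Signal
#' amplitude is on the order of 10 microvolts.
#'
#' @param nEpochs epochs per participant.
#' @param nChannels channels per participant.
#' @param sfreq sampling rate (Hz).
#' @param duration epoch duration (s).
#' @param carrier oscillation carrier frequency (Hz, below Nyquist).
#' @param kappa phase-coupling strength in [0, 1] at the coupled pairs.
#' @param lag imposed phase lag (radians) at the coupled pairs.
#' @param coupledPairs k x 2 matrix of (participant-1 channel,
#'   participant-2 channel) indices; default couples channel 1 to channel 1.
#' @param rhoEnv envelope correlation in [-1, 1] at the coupled pairs.
#' @param noiseSd additive white noise SD relative to the clean signal RMS.
#' @param phaseJitter phase random-walk increment SD (radians per sample).
#' @param seed master seed; per-participant, per-epoch substreams are
#'   derived from it, so changing the epoch count does not reshuffle
#'   earlier epochs.
#' @return A validated \linkS4class{DyadSimConfig}.
#' @seealso [simulateCoupledDyad()], [simulateDirectedDyad()]
#' @export
dyadSimConfig <- function(nEpochs = 20L, nChannels = 4L, sfreq = 128,
                          duration = 2, carrier = 10, kappa = 0, lag = 0,
                          coupledPairs = matrix(c(1L, 1L), 1L, 2L),
                          rhoEnv = 0, noiseSd = 0.1, phaseJitter = 0.3,
                          seed = 1L) {
  new("DyadSimConfig", nEpochs = as.integer(nEpochs),
      nChannels = as.integer(nChannels), sfreq = as.numeric(sfreq),
      duration = as.numeric(duration), carrier = as.numeric(carrier),
      kappa = as.numeric(kappa), lag = as.numeric(lag),
      coupledPairs = matrix(as.integer(coupledPairs), ncol = 2L),
      rhoEnv = as.numeric(rhoEnv), noiseSd = as.numeric(noiseSd),
      phaseJitter = as.numeric(phaseJitter), seed = as.integer(seed))
}

## deterministic substream seed per (participant, epoch); stays below 2^31
substreamSeed <- function(master, participant, epoch) {
  as.integer((as.numeric(master) * 7919 + participant * 104729 +
                epoch * 1299709) %% 2147483647)
}

## golden-angle spiral on a spherical cap (head radius 0.09 m), z up
standardPositions <- function(n, radius = 0.09) {
  k <- seq_len(n)
  polar <- 0.25 + 1.05 * (k - 1) / max(n - 1, 1)     # rad from vertex
  azim <- (k - 1) * pi * (3 - sqrt(5))
  cbind(radius * sin(polar) * cos(azim),
        radius * sin(polar) * sin(azim),
        radius * cos(polar))
}

## smooth unit-variance modulation series from the current RNG stream
smoothModulation <- function(nS) {
  z <- as.numeric(stats::filter(stats::rnorm(nS + 64L), 0.97,
                                method = "recursive"))[-seq_len(64L)]
  s <- stats::sd(z)
  if (s < 1e-12) z * 0 else (z - mean(z)) / s
}

phaseWalk <- function(nS, carrier, sfreq, jitter) {
  2 * pi * carrier * seq_len(nS) / sfreq + cumsum(stats::rnorm(nS, 0, jitter))
}

#' Simulate a phase- and envelope-coupled dyad
#'
#' Generates two participants' epoched narrow-band oscillations with known
#' ground truth. Participant 1's coupled channels carry a wrapped-Gaussian
#' random-walk phase around the carrier; participant 2's coupled channels
#' blend, with weight \code{kappa}, participant 1's phase plus the imposed
#' lag against an independent phase walk (phasor interpolation:
#' \code{Arg(kappa * exp(1i (phi1 + lag)) + (1 - kappa) * exp(1i phi_ind))}),
#' so \code{kappa = 1} reproduces the lagged phase exactly and
#' \code{kappa = 0} is fully independent. Envelopes at the coupled pairs are
#' exponentiated correlated Gaussian modulations with correlation
#' \code{rhoEnv}; all other channels are independent. White Gaussian sensor
#' noise is added at \code{noiseSd} times the clean RMS. The generated
#' montage is a standard spiral layout on the upper head surface. Fully
#' reproducible from the master seed via per-participant, per-epoch
#' substreams.
#'
#' @param cfg a \linkS4class{DyadSimConfig}.
#' @return List of two \linkS4class{EpochArray} objects ("S1", "S2").
#' @examples
#' d <- simulateCoupledDyad(dyadSimConfig(nEpochs = 2, kappa = 1))
#' nEpochs(d[[1]])
#' @export
simulateCoupledDyad <- function(cfg) {
  stopifnot(is(cfg, "DyadSimConfig"))
  validObject(cfg)
  nS <- as.integer(round(cfg@duration * cfg@sfreq))
  nE <- cfg@nEpochs; nC <- cfg@nChannels
  amp <- 1e-5                               # 10 microvolt scale
  dat1 <- array(0, c(nE, nC, nS))
  dat2 <- array(0, c(nE, nC, nS))
  coupled2 <- cfg@coupledPairs[, 2L]
  partnerOf <- integer(nC)
  partnerOf[coupled2] <- cfg@coupledPairs[, 1L]
  for (ep in seq_len(nE)) {
    ## participant 1 first: coupled channels' phases are reused below
    set.seed(substreamSeed(cfg@seed, 1L, ep))
    phi1 <- matrix(0, nC, nS)
    env1 <- matrix(0, nC, nS)
    mod1 <- matrix(0, nC, nS)
    for (k in seq_len(nC)) {
      phi1[k, ] <- phaseWalk(nS, cfg@carrier, cfg@sfreq, cfg@phaseJitter)
      mod1[k, ] <- smoothModulation(nS)
      env1[k, ] <- exp(0.2 * mod1[k, ])
      x <- env1[k, ] * cos(phi1[k, ])
      noise <- stats::rnorm(nS, 0, cfg@noiseSd * sqrt(mean(x^2)))
      dat1[ep, k, ] <- amp * (x + noise)
    }
    set.seed(substreamSeed(cfg@seed, 2L, ep))
    for (k in seq_len(nC)) {
      phiInd <- phaseWalk(nS, cfg@carrier, cfg@sfreq, cfg@phaseJitter)
      modInd <- smoothModulation(nS)
      if (k %in% coupled2) {
        src <- partnerOf[k]
        ph <- Arg(cfg@kappa * exp(1i * (phi1[src, ] + cfg@lag)) +
                    (1 - cfg@kappa) * exp(1i * phiInd))
        md <- cfg@rhoEnv * mod1[src, ] +
          sqrt(max(1 - cfg@rhoEnv^2, 0)) * modInd
      } else {
        ph <- phiInd
        md <- modInd
      }
      env <- exp(0.2 * md)
      x <- env * cos(ph)
      noise <- stats::rnorm(nS, 0, cfg@noiseSd * sqrt(mean(x^2)))
      dat2[ep, k, ] <- amp * (x + noise)
    }
  }
  pos <- standardPositions(nC)
  list(
    EpochArray(dat1, cfg@sfreq, chPos = pos, participantId = "S1"),
    EpochArray(dat2, cfg@sfreq, chPos = pos, participantId = "S2")
  )
}

#' Simulate a directionally coupled dyad
#'
#' Participant 1's source channel is a resonant AR(2) oscillation at the
#' carrier frequency; participant 2's target channel is \code{arCoeff} times
#' the source delayed by \code{lagSamples}, plus independent unit-variance
#' noise (for \code{direction = "2to1"} the roles swap). All other channels
#' are independent AR(2) oscillations. The ground truth is attached as
#' attribute \code{groundTruth}.
#'
#' @param cfg a \linkS4class{DyadSimConfig}; \code{kappa}/\code{lag}/
#'   \code{rhoEnv} are ignored here.
#' @param direction "1to2" (default) or "2to1".
#' @param arCoeff directed coupling coefficient, |arCoeff| < 1.
#' @param sourceChannel,targetChannel channel indices (default 1 and 1).
#' @param lagSamples coupling delay in samples (default 1).
#' @return List of two \linkS4class{EpochArray} objects with a
#'   \code{groundTruth} attribute.
#' @export
simulateDirectedDyad <- function(cfg, direction = c("1to2", "2to1"),
                                 arCoeff = 0.5, sourceChannel = 1L,
                                 targetChannel = 1L, lagSamples = 1L) {
  stopifnot(is(cfg, "DyadSimConfig"))
  direction <- match.arg(direction)
  if (abs(arCoeff) >= 1)
    stop("config error: |arCoeff| must be < 1")
  nS <- as.integer(round(cfg@duration * cfg@sfreq))
  nE <- cfg@nEpochs; nC <- cfg@nChannels
  if (sourceChannel > nC || targetChannel > nC)
    stop("config error: source/target channel out of range")
  r <- 0.9
  a1 <- 2 * r * cos(2 * pi * cfg@carrier / cfg@sfreq)
  a2 <- -r^2
  ar2 <- function(n) {
    x <- as.numeric(stats::filter(stats::rnorm(n + 128L), c(a1, a2),
                                  method = "recursive"))[-seq_len(128L)]
    x / stats::sd(x)
  }
  amp <- 1e-5
  srcP <- if (direction == "1to2") 1L else 2L
  tgtP <- if (direction == "1to2") 2L else 1L
  dat <- list(array(0, c(nE, nC, nS)), array(0, c(nE, nC, nS)))
  for (ep in seq_len(nE)) {
    set.seed(substreamSeed(cfg@seed, srcP, ep))
    srcSig <- matrix(0, nC, nS)
    for (k in seq_len(nC)) srcSig[k, ] <- ar2(nS)
    dat[[srcP]][ep, , ] <- amp * srcSig
    set.seed(substreamSeed(cfg@seed, tgtP, ep))
    for (k in seq_len(nC)) {
      if (k == targetChannel) {
        lagged <- c(numeric(lagSamples),
                    srcSig[sourceChannel, seq_len(nS - lagSamples)])
        dat[[tgtP]][ep, k, ] <- amp * (arCoeff * lagged + stats::rnorm(nS))
      } else {
        dat[[tgtP]][ep, k, ] <- amp * ar2(nS)
      }
    }
  }
  pos <- standardPositions(nC)
  out <- list(
    EpochArray(dat[[1L]], cfg@sfreq, chPos = pos, participantId = "S1"),
    EpochArray(dat[[2L]], cfg@sfreq, chPos = pos, participantId = "S2")
  )
  attr(out, "groundTruth") <- list(direction = direction,
                                   sourceChannel = sourceChannel,
                                   targetChannel = targetChannel,
                                   arCoeff = arCoeff,
                                   lagSamples = lagSamples)
  out
}
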