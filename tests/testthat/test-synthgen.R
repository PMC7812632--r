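test_that("the generator is deterministic and extends without reshuffling", {
  cfg <- dyadSimConfig(nEpochs = 4, nChannels = 3, seed = 81)
  d1 <- simulateCoupledDyad(cfg)
  d2 <- simulateCoupledDyad(cfg)
  expect_identical(epochData(d1[[1]]), epochData(d2[[1]]))
  expect_identical(epochData(d1[[2]]), epochData(d2[[2]]))
  ## per-epoch substreams: adding epochs preserves the earlier ones
  more <- simulateCoupledDyad(dyadSimConfig(nEpochs = 6, nChannels = 3,
                                            seed = 81))
  expect_identical(epochData(more[[1]])[1:4, , ], epochData(d1[[1]]))
})

test_that("generator output satisfies the container invariants end to end", {
  cfg <- dyadSimConfig(nEpochs = 3, nChannels = 4, kappa = 0.5, seed = 82)
  d <- simulateCoupledDyad(cfg)
  for (e in d) {
    expect_s4_class(e, "EpochArray")
    expect_true(validObject(e))
    expect_false(positionFree(e))
    expect_identical(dim(epochData(e)), c(3L, 4L, 256L))
  }
  ## the whole metric pipeline runs without errors on simulated dyads
  as <- computeFreqBands(d, list(Alpha_Low = c(7.5, 11)))
  for (m in c("plv", "ccorr", "coh", "envelope_corr"))
    expect_s4_class(computeSync(as, m), "ConnectivityMatrix")
  expect_error(dyadSimConfig(nChannels = 2,
                             coupledPairs = matrix(c(1L, 3L), 1)),
               "valid channels")
})

test_that("full phase coupling with a quarter-cycle lag is recovered", {
  ## long epochs keep the filter's edge response a small fraction of the
  ## epoch; low jitter keeps the oscillation inside the 1 Hz analysis bin
  cfg <- dyadSimConfig(nEpochs = 6, nChannels = 2, kappa = 1, lag = pi / 2,
                       noiseSd = 0, phaseJitter = 0.05, rhoEnv = 1,
                       duration = 16, seed = 83)
  d <- simulateCoupledDyad(cfg)
  expect_gte(dyadPairMetric(d, "plv"), 0.98)
  expect_gte(dyadPairMetric(d, "pli"), 0.98)
})

test_that("uncoupled dyads sit at the Monte-Carlo null level", {
  ## Monte-Carlo null: independent replicate dyads under identical
  ## conditions define the null distribution of the coupled-pair PLV
  nullPlv <- vapply(1:20, function(s)
    dyadPairMetric(simulateCoupledDyad(
      dyadSimConfig(nEpochs = 10, nChannels = 2, kappa = 0,
                    seed = 900 + s)), "plv"),
    numeric(1))
  probe <- dyadPairMetric(simulateCoupledDyad(
    dyadSimConfig(nEpochs = 10, nChannels = 2, kappa = 0, seed = 990)),
    "plv")
  expect_lte(probe, quantile(nullPlv, 0.95) + 0.05)
  ## and far below a strongly coupled dyad
  strong <- dyadPairMetric(simulateCoupledDyad(
    dyadSimConfig(nEpochs = 10, nChannels = 2, kappa = 0.9, seed = 990)),
    "plv")
  expect_gt(strong, max(nullPlv))
})

test_that("phase metrics increase with the coupling strength", {
  kap <- c(0, 0.3, 0.6, 0.9)
  means <- sapply(kap, function(k) {
    vals <- sapply(1:8, function(rep) {
      d <- simulateCoupledDyad(dyadSimConfig(nEpochs = 10, nChannels = 2,
                                             kappa = k, seed = 300 + rep))
      as <- computeFreqBands(d, list(a = c(9.5, 10.5)))
      c(plv = sliceBlocks(computeSync(as, "plv"))$inter12[1, 1],
        ccorr = sliceBlocks(computeSync(as, "ccorr"))$inter12[1, 1])
    })
    rowMeans(vals)
  })
  expect_true(all(diff(means["plv", ]) > 0))
  expect_true(all(diff(means["ccorr", ]) > 0))
})

test_that("directed dyads drive transfer entropy the right way", {
  ## forward beats backward on nearly every seeded replicate
  wins <- vapply(1:50, function(s) {
    d <- simulateDirectedDyad(dyadSimConfig(nEpochs = 1, nChannels = 1,
                                            duration = 40, seed = 1000 + s),
                              arCoeff = 0.6)
    x <- epochData(d[[1]])[1, 1, ]
    y <- epochData(d[[2]])[1, 1, ]
    transferEntropy(x, y, 2) > transferEntropy(y, x, 2)
  }, logical(1))
  expect_gte(mean(wins), 0.95)

  ## no coupling, no forward transfer
  nulls <- vapply(1:20, function(s) {
    d <- simulateDirectedDyad(dyadSimConfig(nEpochs = 1, nChannels = 1,
                                            duration = 40, seed = 2000 + s),
                              arCoeff = 0)
    transferEntropy(epochData(d[[1]])[1, 1, ],
                    epochData(d[[2]])[1, 1, ], 2)
  }, numeric(1))
  expect_lt(mean(nulls), 0.005)

  ## pdc sees the asymmetry in the stated direction through the pipeline
  d <- simulateDirectedDyad(dyadSimConfig(nEpochs = 6, nChannels = 2,
                                          duration = 4, seed = 84),
                            arCoeff = 0.6)
  gt <- attr(d, "groundTruth")
  expect_identical(gt$direction, "1to2")
  as <- computeFreqBands(d, list(broad = c(2, 40)))
  bl <- sliceBlocks(computeSync(as, "pdc", mvarOrder = 6))
  expect_gt(bl$inter21[1, 1], bl$inter12[1, 1])
})

test_that("envelope coupling shows up in the envelope correlation", {
  mk <- function(rho, s) dyadPairMetric(simulateCoupledDyad(
    dyadSimConfig(nEpochs = 8, nChannels = 2, kappa = 1, rhoEnv = rho,
                  noiseSd = 0.02, phaseJitter = 0.05, duration = 8,
                  seed = s)), "envelope_corr")
  high <- mean(vapply(1:5, function(s) mk(0.9, 400 + s), numeric(1)))
  zero <- mean(vapply(1:5, function(s) mk(0, 400 + s), numeric(1)))
  expect_gt(high, zero + 0.2)
})
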