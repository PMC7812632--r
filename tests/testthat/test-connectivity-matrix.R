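nonDirectional <- setdiff(c("coh", "imaginary_coh", "plv", "pli", "ccorr",
                            "envelope_corr", "pow_corr", "proj_pow_corr"),
                          character(0))

test_that("identical participants give unit self-synchrony on the inter diagonal", {
  a <- randAnalytic(nE = 2, nC = 3, freqsHz = 10, nS = 200, seed = 31)
  C <- computeSync(list(a, a), "plv")
  bl <- sliceBlocks(C)
  expect_equal(diag(bl$inter12), rep(1, 3))
  expect_equal(diag(bl$intra1), rep(1, 3))
})

test_that("every non-directional mode yields an exactly symmetric matrix", {
  a1 <- randAnalytic(nE = 3, nC = 3, freqsHz = c(9, 10), nS = 150, seed = 32)
  a2 <- randAnalytic(nE = 3, nC = 3, freqsHz = c(9, 10), nS = 150, seed = 33)
  a1@bandIndex <- list(alpha = 1:2); a2@bandIndex <- list(alpha = 1:2)
  for (m in nonDirectional) {
    C <- computeSync(list(a1, a2), m)
    v <- connValues(C)[1, , ]
    expect_lt(max(abs(v - t(v))), 1e-10)
    expect_false(isDirectional(C))
    bl <- sliceBlocks(C)
    expect_equal(bl$inter12, t(bl$inter21))
  }
})

test_that("matrix cells agree with the pairwise metric primitives", {
  a1 <- randAnalytic(nE = 2, nC = 2, freqsHz = 10, nS = 300, seed = 34)
  a2 <- randAnalytic(nE = 2, nC = 2, freqsHz = 10, nS = 300, seed = 35)
  stack <- function(ep, ch) {
    v <- if (ch <= 2) a1@values[ep, ch, 1, ] else a2@values[ep, ch - 2, 1, ]
    v
  }
  C <- computeSync(list(a1, a2), "plv")
  v <- connValues(C)[1, , ]
  for (i in 1:4) for (j in 1:4) {
    byHand <- mean(vapply(1:2, function(ep)
      plv(Arg(stack(ep, i)), Arg(stack(ep, j))), numeric(1)))
    expect_equal(v[i, j], byHand, tolerance = 1e-10)
  }
  Ce <- computeSync(list(a1, a2), "envelope_corr")
  ve <- connValues(Ce)[1, , ]
  byHand <- mean(vapply(1:2, function(ep)
    envelopeCorr(stack(ep, 1), stack(ep, 4)), numeric(1)))
  expect_equal(ve[1, 4], byHand, tolerance = 1e-10)
  Cc <- computeSync(list(a1, a2), "ccorr")
  vc <- connValues(Cc)[1, , ]
  byHand <- mean(vapply(1:2, function(ep)
    ccorr(Arg(stack(ep, 2)), Arg(stack(ep, 3))), numeric(1)))
  expect_equal(vc[2, 3], byHand, tolerance = 1e-10)
})

test_that("the assembled matrix has the documented layout", {
  a1 <- randAnalytic(nE = 2, nC = 31, freqsHz = c(4, 8, 12, 20, 35),
                     nS = 64, seed = 36)
  a2 <- randAnalytic(nE = 2, nC = 31, freqsHz = c(4, 8, 12, 20, 35),
                     nS = 64, seed = 37)
  bands <- list(Theta = 1L, Alpha_Low = 2L, Alpha_High = 3L, Beta = 4L,
                Gamma = 5L)
  a1@bandIndex <- bands; a2@bandIndex <- bands
  C <- computeSync(list(a1, a2), "plv")
  expect_identical(dim(connValues(C)), c(5L, 62L, 62L))
  expect_identical(bandNames(C), names(bands))
  bl <- sliceBlocks(C, band = "Beta")
  expect_identical(dim(bl$intra1), c(31L, 31L))
  ## the four blocks tile the parent exactly
  v <- connValues(C)[4, , ]
  expect_identical(rbind(cbind(bl$intra1, bl$inter12),
                         cbind(bl$inter21, bl$intra2)), v)
  ## per-epoch variant keeps the epoch axis
  Cp <- computeSync(list(a1, a2), "plv", epochsAverage = FALSE)
  expect_identical(dim(connValues(Cp)), c(2L, 5L, 62L, 62L))
})

test_that("band values are unweighted means of per-bin values", {
  a1 <- randAnalytic(nE = 2, nC = 2, freqsHz = c(9, 10), nS = 120, seed = 38)
  a2 <- randAnalytic(nE = 2, nC = 2, freqsHz = c(9, 10), nS = 120, seed = 39)
  twoBin <- list(alpha = 1:2)
  oneA <- list(b9 = 1L, b10 = 2L)
  a1@bandIndex <- twoBin; a2@bandIndex <- twoBin
  Cband <- connValues(computeSync(list(a1, a2), "plv"))[1, , ]
  a1@bandIndex <- oneA; a2@bandIndex <- oneA
  Cbins <- connValues(computeSync(list(a1, a2), "plv"))
  expect_equal(Cband, (Cbins[1, , ] + Cbins[2, , ]) / 2, tolerance = 1e-12)
})

test_that("metric range invariants hold on random fixtures", {
  a1 <- randAnalytic(nE = 2, nC = 3, freqsHz = 10, nS = 150, seed = 40)
  a2 <- randAnalytic(nE = 2, nC = 3, freqsHz = 10, nS = 150, seed = 41)
  ranges <- list(plv = c(0, 1), pli = c(0, 1), coh = c(0, 1),
                 imaginary_coh = c(0, 1), ccorr = c(-1, 1),
                 envelope_corr = c(-1, 1), pow_corr = c(-1, 1),
                 proj_pow_corr = c(-1, 1))
  for (m in names(ranges)) {
    v <- connValues(computeSync(list(a1, a2), m))
    expect_true(all(v >= ranges[[m]][1] - 1e-12 &
                      v <= ranges[[m]][2] + 1e-12), label = m)
  }
})

test_that("directed metrics break inter-block symmetry in the true direction", {
  cfg <- dyadSimConfig(nEpochs = 6, nChannels = 2, sfreq = 128,
                       duration = 4, seed = 42)
  dyad <- simulateDirectedDyad(cfg, arCoeff = 0.6)
  as <- computeFreqBands(dyad, list(broad = c(2, 40)))
  for (m in c("pdc", "transfer_entropy")) {
    C <- computeSync(as, m, mvarOrder = 6, teLag = 4)
    expect_true(isDirectional(C))
    bl <- sliceBlocks(C)
    expect_gt(max(abs(bl$inter12 - t(bl$inter21))), 0.05)
    ## cell (i, j) carries j -> i: the 1 -> 2 drive lands in inter21
    expect_gt(bl$inter21[1, 1], 3 * bl$inter12[1, 1])
  }
  ## pdc respects its range and transfer entropy is non-negative
  vp <- connValues(computeSync(as, "pdc", mvarOrder = 6))
  expect_true(all(vp >= -1e-12 & vp <= 1 + 1e-12))
  vt <- connValues(computeSync(as, "transfer_entropy", teLag = 2))
  expect_true(all(vt >= 0))
})

test_that("unknown modes are rejected with the list of choices", {
  a <- randAnalytic()
  expect_error(computeSync(list(a, a), "wavelet_coh"), "unknown mode")
})

test_that("standardization gives grand mean 0 and sd 1 with a zeroed diagonal", {
  set.seed(43)
  m <- matrix(runif(36, 1, 5), 6)
  z <- standardize(m)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-12)
  ## positive rescaling leaves the output unchanged
  expect_equal(standardize(3.7 * m), z, tolerance = 1e-12)
  ## constant off-diagonal input is degenerate
  k <- matrix(2, 4, 4)
  expect_error(standardize(k * 0), "zero variance")
})
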