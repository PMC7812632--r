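test_that("PLV identities hold exactly", {
  ph <- runif(500, -pi, pi)
  expect_equal(plv(ph, ph), 1)
  expect_equal(plv(ph, ph - pi / 2), 1)        # offset-invariant
  expect_error(plv(1, 1), "degenerate")
  expect_error(plv(1:3, 1:4), "equal lengths")
})

test_that("null PLV matches the small-sample Monte-Carlo law", {
  set.seed(101)
  ## at n = 100 the expected null PLV is sqrt(pi/4)/sqrt(n) ~= 0.089
  m100 <- mean(replicate(200, plv(runif(100, -pi, pi),
                                  runif(100, -pi, pi))))
  expect_gt(m100, 0.06)
  expect_lt(m100, 0.12)
  ## and it decays as 1/sqrt(n)
  m1e4 <- mean(replicate(50, plv(runif(1e4, -pi, pi),
                                 runif(1e4, -pi, pi))))
  expect_lt(m1e4, 0.02)
  expect_equal(m100 / m1e4, 10, tolerance = 0.35)
})

test_that("PLI is zero-lag insensitive and sign-balanced", {
  ph <- runif(1000, -pi, pi)
  expect_equal(pli(ph, ph), 0)
  expect_equal(pli(ph + pi / 2, ph), 1)
  off <- rep(c(pi / 4, -pi / 4), 500)           # signs cancel by design
  expect_equal(pli(ph + off, ph), 0)
})

test_that("circular correlation hits +/-1 on identical and reflected phases", {
  set.seed(5)
  ph <- rnorm(1000, 0, 0.8)
  expect_equal(ccorr(ph, ph), 1)
  expect_equal(ccorr(ph, -ph), -1)
  expect_error(ccorr(rep(0.3, 10), ph[1:10]), "zero angular variance")
  ## compatibility switch: literal Pearson on the wrapped angles
  expect_equal(ccorr(ph, ph, method = "pearson"), 1)
})

test_that("circular correlation is at null level for independent phases", {
  set.seed(6)
  r <- replicate(200, ccorr(runif(1e4, -pi, pi), runif(1e4, -pi, pi)))
  expect_gte(mean(abs(r) < 0.05), 0.95)
})

test_that("coherence identities and null level", {
  set.seed(7)
  x <- matrix(complex(real = rnorm(500), imaginary = rnorm(500)), 10)
  expect_equal(coherence(x, x), 1)
  expect_equal(coherence(x, 3 * x), 1)          # amplitude invariance
  expect_error(coherence(1 + 2i, 1 - 1i), "single unaveraged segment")
  nullCoh <- replicate(100, {
    a <- matrix(complex(real = rnorm(1000), imaginary = rnorm(1000)), 50)
    b <- matrix(complex(real = rnorm(1000), imaginary = rnorm(1000)), 50)
    coherence(a, b)
  })
  expect_lt(mean(nullCoh), 0.1)
})

test_that("imaginary coherence kills zero-lag and keeps lagged coherency", {
  set.seed(8)
  x <- matrix(complex(real = rnorm(400), imaginary = rnorm(400)), 8)
  expect_equal(imaginaryCoherence(x, x), 0)
  ## algebraic identity: rotating y by a pi/2 phasor moves the real part of
  ## the coherency into the imaginary part; for y = x the coherency is real,
  ## so the rotated pair recovers the full (unit) coherency magnitude
  expect_equal(imaginaryCoherence(x, x * exp(1i * pi / 2)), 1,
               tolerance = 1e-12)
  w <- matrix(complex(real = rnorm(400), imaginary = rnorm(400)), 8)
  y <- 0.7 * x + 0.5 * w
  expectRot <- abs(Re(mean(x * Conj(y)))) /
    sqrt(mean(Mod(x)^2) * mean(Mod(y)^2))
  expect_equal(imaginaryCoherence(x, y * exp(1i * pi / 2)), expectRot,
               tolerance = 1e-12)
  b <- matrix(complex(real = rnorm(400), imaginary = rnorm(400)), 8)
  expect_lt(imaginaryCoherence(x, b), 0.25)
})

test_that("envelope and power correlations behave as Pearson on moduli", {
  set.seed(9)
  a <- exp(0.3 * rnorm(500))
  th <- runif(500, -pi, pi)
  x <- a * exp(1i * th)
  expect_equal(envelopeCorr(x, x), 1)
  expect_equal(powCorr(x, 2 * x), 1)
  ## perfectly anticorrelated envelopes
  y <- (3 - a) * exp(1i * runif(500, -pi, pi))
  expect_equal(envelopeCorr(x, y), -1)
  ## independent amplitude-modulated noise stays near zero
  r <- replicate(50, {
    u <- exp(0.3 * rnorm(1e4)) * exp(1i * runif(1e4, -pi, pi))
    v <- exp(0.3 * rnorm(1e4)) * exp(1i * runif(1e4, -pi, pi))
    envelopeCorr(u, v)
  })
  expect_lt(max(abs(r)), 0.1)
  expect_error(envelopeCorr(rep(1 + 0i, 10), x[1:10]), "zero envelope")
})

test_that("projected power correlation recovers planted envelope coupling", {
  set.seed(10)
  n <- 4000
  za <- rnorm(n)
  zb <- 0.8 * za + sqrt(1 - 0.8^2) * rnorm(n)
  a <- exp(0.2 * za); b <- exp(0.2 * zb)
  phi <- cumsum(rnorm(n, 0.5, 0.3))
  x <- a * exp(1i * phi)
  y <- b * exp(1i * (phi + pi / 2))
  ## construction oracle: orthogonalization leaves exactly the b-envelope,
  ## so the metric must match cor(a, b)
  expect_equal(projPowCorr(x, y), stats::cor(a, b), tolerance = 1e-10)
  expect_lt(abs(projPowCorr(x, y) - 0.8), 0.1)

  ## fully shared signal is degenerate and flagged
  d <- projPowCorr(x, (2 + 0i) * x)
  expect_equal(as.numeric(d), 0)
  expect_true(isTRUE(attr(d, "degenerate")))

  ## independent signals stay near zero
  r <- replicate(30, {
    u <- exp(0.2 * rnorm(1e4)) * exp(1i * cumsum(rnorm(1e4, 0.5, 0.3)))
    v <- exp(0.2 * rnorm(1e4)) * exp(1i * cumsum(rnorm(1e4, 0.5, 0.3)))
    projPowCorr(u, v)
  })
  expect_lt(max(abs(r)), 0.1)
})

test_that("Gaussian transfer entropy matches its closed form", {
  set.seed(12)
  n <- 1e4
  x <- rnorm(n)
  y <- c(0, 0.8 * x[-n]) + rnorm(n)
  te <- transferEntropy(x, y)
  expect_equal(te, 0.5 * log(1 + 0.64), tolerance = 0.1)
  ## directionality
  expect_gt(te, 10 * transferEntropy(y, x))
  expect_error(transferEntropy(x[1:8], y[1:8]), "too short")
})

test_that("transfer entropy is unbiased-null and non-negative", {
  set.seed(13)
  nulls <- replicate(100, transferEntropy(rnorm(1e4), rnorm(1e4)))
  expect_true(all(nulls >= 0))
  expect_lt(mean(nulls), 0.005)
})

test_that("transfer entropy equals half the Granger log-ratio (lm oracle)", {
  set.seed(14)
  n <- 1e4
  x <- rnorm(n); y <- c(0, 0, 0.6 * x[-c(n - 1, n)]) + rnorm(n)
  k <- 2
  idx <- (k + 1):n
  d <- data.frame(yt = y[idx], y1 = y[idx - 1], y2 = y[idx - 2],
                  x1 = x[idx - 1], x2 = x[idx - 2])
  rssR <- sum(resid(lm(yt ~ y1 + y2, d))^2)
  rssF <- sum(resid(lm(yt ~ y1 + y2 + x1 + x2, d))^2)
  gc <- log(rssR / rssF)
  expect_equal(transferEntropy(x, y, k = 2), gc / 2, tolerance = 0.05)
})
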