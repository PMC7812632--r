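test_that("Delaunay adjacency on a square of sensors is sane", {
  ## four sensors at the corners of a square on the upper head surface
  pos <- rbind(c(1, 1, 2), c(-1, 1, 2), c(-1, -1, 2), c(1, -1, 2))
  adj <- conMatrix(pos)
  ## Delaunay oracle on the square: all co-circular, both diagonal
  ## triangulations are valid, so every sensor has at least its two
  ## side-neighbors
  expect_true(all(rowSums(adj@chCon) >= 2))
  expect_false(any(diag(adj@chCon)))
  expect_identical(adj@chCon, t(adj@chCon))
})

test_that("degenerate sensor geometries are refused", {
  line <- cbind(1:4 / 10, 1:4 / 10, 2)
  expect_error(conMatrix(line), "geometry error")
  expect_error(conMatrix(rbind(c(1, 1, 2), c(-1, 1, 2))), "at least 3")
  e <- noiseEpochs(positions = FALSE)
  expect_error(conMatrix(e), "position-free")
})

test_that("frequency expansion matches the hand-enumerated rule", {
  pos <- rbind(c(1, 1, 2), c(-1, 1, 2), c(-1, -1, 2), c(1, -1, 2))
  a1 <- conMatrix(pos, freqsHz = 10)
  expect_identical(a1@chConFreq, a1@chCon)      # F = 1: identical

  ## N = 2 fully connected channels, F = 3 bins -> 6 nodes, hand enumerated:
  ## node (c, f) = c + (f - 1) * 2; links: channel partner at same bin, own
  ## channel at adjacent bins
  full2 <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2)
  a3 <- conMatrix(rbind(c(1, 0, 2), c(0, 1, 2), c(-1, -1, 2)),
                  freqsHz = c(8, 9, 10))
  expected <- matrix(FALSE, 6, 6)
  for (f in 1:3) {
    expected[1 + (f - 1) * 2, 2 + (f - 1) * 2] <- TRUE  # partner, same bin
    expected[2 + (f - 1) * 2, 1 + (f - 1) * 2] <- TRUE
  }
  for (c0 in 1:2) for (f in 1:2) {
    expected[c0 + (f - 1) * 2, c0 + f * 2] <- TRUE      # own, adjacent bin
    expected[c0 + f * 2, c0 + (f - 1) * 2] <- TRUE
  }
  twoCh <- new("AdjacencyStructure", chCon = full2,
               chConFreq = expected, freqs = c(8, 9, 10), params = list())
  ## rebuild through the exported constructor on any 2-channel montage is
  ## impossible (needs >= 3 sensors), so expand manually via the same rule
  built <- kronecker(diag(3) > 0, full2) |
    kronecker(abs(outer(1:3, 1:3, "-")) == 1, diag(2) > 0)
  expect_identical(built, expected)
  ## and the >= 3-channel path agrees with the kron construction
  expect_identical(
    a3@chConFreq,
    kronecker(diag(3) > 0, a3@chCon) |
      kronecker(abs(outer(1:3, 1:3, "-")) == 1, diag(3) > 0))
})

test_that("inter-brain cell adjacency follows the two-ends rule", {
  ch <- matrix(FALSE, 3, 3); ch[1, 2] <- ch[2, 1] <- TRUE
  A <- interCellAdjacency(ch)
  cell <- function(i, j) i + (j - 1) * 3
  ## (1,1) and (2,2): both ends move along an edge -> adjacent
  expect_true(A[cell(1, 1), cell(2, 2)])
  ## (1,1) and (1,2): same row end, column ends adjacent -> adjacent
  expect_true(A[cell(1, 1), cell(1, 2)])
  ## (1,1) and (3,1): ends 1 and 3 are not neighbors -> not adjacent
  expect_false(A[cell(1, 1), cell(3, 1)])
  expect_false(any(diag(A)))
})

test_that("all-zero differences yield no significant cells", {
  r <- permTtestFdr(matrix(0, 10, 6), 200)
  expect_true(all(r@excluded))
  expect_false(any(r@mask))
  expect_true(all(r@tObsPlot == 0))
})

test_that("a single strongly shifted cell is detected exactly", {
  hits <- 0; exact <- 0
  for (s in 1:40) {
    set.seed(400 + s)
    X <- matrix(rnorm(20 * 10), 20, 10)
    X[, 4] <- X[, 4] + 5                 # 5 sigma shift
    r <- permTtestFdr(X, 1000, seed = s)
    hits <- hits + (4L %in% which(r@mask))
    exact <- exact + identical(which(r@mask), 4L)
  }
  expect_gte(hits / 40, 0.95)
  expect_gte(exact / 40, 0.9)
})

test_that("FDR flags at most the nominal fraction of null cells on average", {
  set.seed(55)
  flagged <- replicate(200, {
    r <- permTtestFdr(matrix(rnorm(12 * 20), 12, 20), 256)
    mean(r@mask)
  })
  expect_lte(mean(flagged), 0.05)
})

test_that("significance masks are monotone in alpha", {
  set.seed(56)
  X <- matrix(rnorm(15 * 12), 15, 12)
  X[, 2] <- X[, 2] + 2
  X[, 7] <- X[, 7] + 1
  r10 <- permTtestFdr(X, 1000, alpha = 0.10, seed = 1)
  r01 <- permTtestFdr(X, 1000, alpha = 0.01, seed = 1)
  expect_true(all(which(r01@mask) %in% which(r10@mask)))
})

test_that("identical groups produce no significant clusters", {
  set.seed(57)
  X <- matrix(rnorm(8 * 12), 8, 12)
  r <- statsCluster(list(X, X), "ind_ttest", gridAdjacency(3, 4),
                    nPermutations = 200)
  expect_length(r@clusters, 0)
  expect_false(any(r@significantMask))
})

test_that("an adjacent shifted patch is found as one significant cluster", {
  A <- gridAdjacency(4, 5)
  found <- 0
  for (s in 1:30) {
    set.seed(500 + s)
    g1 <- matrix(rnorm(16 * 20), 16, 20)
    g2 <- matrix(rnorm(16 * 20), 16, 20)
    g2[, c(1, 2, 5)] <- g2[, c(1, 2, 5)] + 3   # adjacent cells on the grid
    r <- statsCluster(list(g1, g2), "ind_ttest", A, nPermutations = 500,
                      seed = s)
    sig <- r@clusters[r@clusterP <= 0.05]
    found <- found + any(vapply(sig, function(cl)
      all(c(1L, 2L, 5L) %in% cl), logical(1)))
  }
  expect_gte(found / 30, 0.9)
})

test_that("clusters never merge across disconnected adjacency components", {
  ## two 2-cell components, all four cells forced suprathreshold
  A <- matrix(FALSE, 4, 4)
  A[1, 2] <- A[2, 1] <- TRUE
  A[3, 4] <- A[4, 3] <- TRUE
  set.seed(58)
  g1 <- matrix(rnorm(12 * 4), 12, 4)
  g2 <- matrix(rnorm(12 * 4), 12, 4) + 4
  r <- statsCluster(list(g1, g2), "ind_ttest", A, nPermutations = 200,
                    seed = 2)
  expect_length(r@clusters, 2)
  expect_true(all(vapply(r@clusters, length, integer(1)) == 2))
  ## without adjacency every cell is its own cluster
  r0 <- statsCluster(list(g1, g2), "ind_ttest", NULL, nPermutations = 200,
                     seed = 2)
  expect_length(r0@clusters, 4)
})

test_that("paired and F tests run and reject invalid designs", {
  set.seed(59)
  g1 <- matrix(rnorm(10 * 6), 10, 6)
  g2 <- g1 + matrix(rnorm(10 * 6, 1), 10, 6)
  r <- statsCluster(list(g1, g2), "rel_ttest", NULL, nPermutations = 300,
                    seed = 3)
  expect_s4_class(r, "ClusterStatsResult")
  g3 <- matrix(rnorm(10 * 6), 10, 6)
  rf <- statsCluster(list(g1, g2, g3), "f_oneway", NULL,
                     nPermutations = 300, seed = 4)
  expect_identical(rf@tail, 1L)
  expect_true(all(rf@tObs >= 0))
  expect_error(statsCluster(list(g1, g2, g3), "ind_ttest"), "exactly 2")
  expect_error(statsCluster(list(g1[1:5, ], g2), "rel_ttest"),
               "equal group sizes")
  expect_error(statsCluster(list(g1, g2), "ind_ttest", factorLevel = c(2, 3)),
               "not implemented")
})

test_that("permutation p-values are valid under the exchangeable null", {
  set.seed(60)
  reject <- replicate(200, {
    g1 <- matrix(rnorm(10 * 8), 10, 8)
    g2 <- matrix(rnorm(10 * 8), 10, 8)
    r <- statsCluster(list(g1, g2), "ind_ttest", gridAdjacency(2, 4),
                      nPermutations = 200)
    if (length(r@clusterP)) min(r@clusterP) <= 0.05 else FALSE
  })
  expect_lte(mean(reject), 0.05 + 0.04)
})

test_that("dyad permutation schemes are reproducible and avoid true pairs", {
  parts <- data.frame(id = paste0("p", 1:8), dyad = rep(1:4, each = 2),
                      group = rep(c("A", "B"), each = 4),
                      role = rep(1:2, 4))
  s1 <- permuteDyads(parts, "shuffle_time", seed = 7, nEpochs = 12)
  s2 <- permuteDyads(parts, "shuffle_time", seed = 7, nEpochs = 12)
  expect_identical(s1, s2)
  expect_named(s1, parts$id)
  expect_true(all(vapply(s1, function(p) setequal(p, 1:12), logical(1))))

  truePairs <- c("p1p2", "p3p4", "p5p6", "p7p8")
  for (seed in 0:99) {
    fp <- permuteDyads(parts, "fake_pairs_within", seed = seed)
    expect_identical(nrow(fp), 4L)
    expect_false(any(paste0(fp$id1, fp$id2) %in% truePairs))
    expect_true(all(fp$group1 == fp$group2))
  }
  single <- parts[parts$dyad == 1, ]
  expect_error(permuteDyads(single, "fake_pairs_within", seed = 1),
               "single")
  fb <- permuteDyads(parts, "fake_pairs_between", seed = 3)
  expect_true(all(fb$group1 == "A" & fb$group2 == "B"))
})

test_that("time shuffling destroys genuine inter-brain coupling", {
  wins <- 0
  for (s in 1:15) {
    cfg <- dyadSimConfig(nEpochs = 12, nChannels = 1, kappa = 0.9,
                         seed = 700 + s)
    d <- simulateCoupledDyad(cfg)
    as <- computeFreqBands(d, list(a = c(9.5, 10.5)))
    true <- sliceBlocks(computeSync(as, "plv"))$inter12[1, 1]
    parts <- data.frame(id = c("a", "b"), dyad = 1, group = "g", role = 1:2)
    perm <- permuteDyads(parts, "shuffle_time", seed = s, nEpochs = 12)
    shuf <- d
    shuf[[2]]@data <- d[[2]]@data[perm$b, , , drop = FALSE]
    asS <- computeFreqBands(shuf, list(a = c(9.5, 10.5)))
    surro <- sliceBlocks(computeSync(asS, "plv"))$inter12[1, 1]
    wins <- wins + (surro < true)
  }
  expect_gte(wins / 15, 0.95)
})
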