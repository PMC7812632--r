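test_that("columnar dialect round-trips data, metadata and channel order", {
  e <- noiseEpochs(nEpochs = 2, nChannels = 3, nSamples = 100, seed = 4)
  badChannels(e) <- "Ch2"
  f <- withr::local_tempfile(fileext = ".txt")
  writeEpochs(e, f)
  e2 <- readEpochs(f)
  expect_identical(dim(epochData(e2)), c(2L, 3L, 100L))
  expect_identical(epochData(e2), epochData(e))
  expect_identical(chNames(e2), chNames(e))
  expect_identical(badChannels(e2), "Ch2")
  expect_equal(chPositions(e2), chPositions(e), ignore_attr = TRUE)
  expect_identical(sfreq(e2), sfreq(e))
})

test_that("position-free flag and drop log survive the columnar round-trip", {
  e <- noiseEpochs(nChannels = 2, positions = FALSE)
  expect_true(positionFree(e))
  f <- withr::local_tempfile()
  writeEpochs(e, f)
  expect_true(positionFree(readEpochs(f)))

  d <- e
  d@dropLog <- c(TRUE, FALSE, FALSE, TRUE)
  d@data <- e@data[1:2, , , drop = FALSE]
  validObject(d)
  writeEpochs(d, f)
  expect_identical(readEpochs(f)@dropLog, d@dropLog)
})

test_that("unreadable or malformed columnar files raise informative errors", {
  expect_error(readEpochs(file.path(tempdir(), "nope.txt")), "no such file")
  f <- withr::local_tempfile()
  writeLines(c("# columnar-epochs v1", "# sfreq=100", "# ch=A", "# ch=B",
               "1\t0.1\t0.2", "1\t0.3"), f)
  expect_error(readEpochs(f), "inconsistent channel count")
})

test_that("EDF files round-trip amplitudes and encode the sampling rate", {
  e <- noiseEpochs(nEpochs = 2, nChannels = 3, nSamples = 128, sfreq = 256,
                   seed = 9)
  f <- withr::local_tempfile(fileext = ".edf")
  writeEpochs(e, f)
  ## independent oracle: the published fixed-offset header layout.
  ## record duration lives at byte 244 (8 ASCII chars); samples-per-record
  ## for the first signal at byte 256 + nSignals * 216.
  con <- file(f, "rb")
  seek(con, 244L)
  dur <- as.numeric(trimws(readChar(con, 8L)))
  seek(con, 256L + 3L * 216L)
  spr <- as.integer(trimws(readChar(con, 8L)))
  close(con)
  expect_equal(spr / dur, 256)
  e2 <- readEpochs(f)
  expect_equal(sfreq(e2), 256)
  expect_identical(chNames(e2), chNames(e))
  ## 16-bit quantization bound (1 LSB of the symmetric digital range)
  tol <- max(abs(epochData(e))) / 32767 * 1.01
  expect_lt(max(abs(epochData(e2) - epochData(e))), tol)
})

test_that("FIF is refused with a configuration error", {
  e <- noiseEpochs()
  expect_error(writeEpochs(e, tempfile(fileext = ".fif")), "not supported")
  f <- withr::local_tempfile(fileext = ".fif")
  writeLines("x", f)
  expect_error(readEpochs(f), "backend")
})

test_that("merge concatenates channels with suffixes and carries bads", {
  a <- noiseEpochs(nEpochs = 2, nChannels = 31, nSamples = 64, seed = 1)
  b <- noiseEpochs(nEpochs = 2, nChannels = 31, nSamples = 64, seed = 2)
  a@participantId <- "A"; b@participantId <- "B"
  a@chNames[5] <- "Cz"; b@chNames[5] <- "Cz"
  badChannels(a) <- "Cz"
  h <- mergeDyad(a, b)
  expect_s4_class(h, "HyperEpochArray")
  expect_identical(nChannels(h), 62L)
  expect_identical(chNames(h)[1:31], paste0(chNames(a), "_1"))
  expect_identical(chNames(h)[32:62], paste0(chNames(b), "_2"))
  expect_true("Cz_1" %in% badChannels(h))
  expect_identical(h@sourceIds, c("A", "B"))
})

test_that("merge rejects incompatible containers with named counts", {
  a <- noiseEpochs(nEpochs = 3, nChannels = 2)
  b <- noiseEpochs(nEpochs = 2, nChannels = 2)
  expect_error(mergeDyad(a, b), "3 epochs.*2")
  b2 <- noiseEpochs(nEpochs = 3, nChannels = 2, sfreq = 200)
  expect_error(mergeDyad(a, b2), "sfreq differs")
})

test_that("split inverts merge exactly, with suffixes stripped", {
  a <- noiseEpochs(nEpochs = 2, nChannels = 31, nSamples = 32, seed = 5)
  b <- noiseEpochs(nEpochs = 2, nChannels = 31, nSamples = 32, seed = 6)
  a@participantId <- "A"; b@participantId <- "B"
  badChannels(b) <- "Ch3"
  h <- mergeDyad(a, b)
  s <- splitDyad(h)
  expect_identical(nChannels(s[[1]]), 31L)
  expect_identical(nChannels(s[[2]]), 31L)
  expect_identical(epochData(s[[1]]), epochData(a))
  expect_identical(epochData(s[[2]]), epochData(b))
  expect_identical(chNames(s[[1]]), chNames(a))
  expect_identical(badChannels(s[[2]]), "Ch3")
  expect_identical(participantId(s[[1]]), "A")
  ## second-output channels come only from the "_2" half
  expect_identical(s[[2]]@data[1, 1, ], h@data[1, 32, ])
})

test_that("merge then split then merge is stable (identity on data)", {
  a <- noiseEpochs(seed = 7); b <- noiseEpochs(seed = 8)
  h <- mergeDyad(a, b)
  h2 <- do.call(mergeDyad, splitDyad(h))
  expect_identical(epochData(h2), epochData(h))
  expect_identical(chNames(h2), chNames(h))
})
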