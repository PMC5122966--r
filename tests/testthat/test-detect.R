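test_that("blank images yield no candidates, with a warning", {
  img <- matrix(100, 64, 128)
  expect_warning(cand <- detectCandidates(img), "blank")
  expect_equal(nrow(cand), 0L)
})

test_that("noiseless puncta are all recovered as candidates", {
  spec <- imageSpec(nPuncta = 5L, noiseSd = 0, seed = 21)
  sim <- simulateAxonImage(spec)
  cand <- detectCandidates(sim$image)
  expect_gte(nrow(cand), 5L)
  gx <- sim$groundTruth$x_um / spec@pixelSizeUm + 0.5
  gy <- sim$groundTruth$y_um / spec@pixelSizeUm + 0.5
  for (i in seq_along(gx)) {
    d <- sqrt((cand$x_px - gx[i])^2 + (cand$y_px - gy[i])^2)
    expect_lte(min(d), 2)
  }
})

test_that("two puncta separated by 4 PSF sigmas give two distinct candidates", {
  # brute-force local-maxima oracle on a hand-built image
  img <- matrix(0, 40, 120)
  psf <- 2
  for (cx in c(50, 50 + 4 * psf)) {
    for (x in 1:120) for (y in 1:40)
      img[y, x] <- img[y, x] + 200 * exp(-((x - cx)^2 + (y - 20)^2) / (2 * psf^2))
  }
  mx <- bruteForceLocalMaxima(img)
  mx <- mx[img[mx] > 10, , drop = FALSE]
  expect_equal(nrow(mx), 2L)
  cand <- detectCandidates(img, scales = c(1.6, 2.4))
  expect_equal(nrow(cand), 2L)
  expect_equal(sort(cand$x_px), sort(mx[, 2]), tolerance = 1e-8)
})

test_that("detection is equivariant to axial translation", {
  spec <- imageSpec(widthPx = 400L, nPuncta = 4L, noiseSd = 0, seed = 31)
  sim <- simulateAxonImage(spec)
  shift <- 15L
  img2 <- cbind(sim$image[, (ncol(sim$image) - shift + 1):ncol(sim$image)],
                sim$image[, 1:(ncol(sim$image) - shift)])
  a <- detectCandidates(sim$image)
  b <- detectCandidates(img2)
  expect_equal(nrow(a), nrow(b))
  expect_equal(sort(b$x_px), sort(a$x_px + shift))
})

test_that("segmentation recovers analytic Gaussian photometry", {
  # single noiseless Gaussian: integrated intensity ~ 2 pi A s^2
  A <- 300; s <- 2.5
  img <- matrix(0, 48, 96)
  for (x in 1:96) for (y in 1:48)
    img[y, x] <- A * exp(-((x - 48)^2 + (y - 24)^2) / (2 * s^2))
  cand <- detectCandidates(img, scales = c(2, 2.5, 3))
  rec <- segmentPuncta(img, cand, pixelSizeUm = 1)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$integrated_intensity, 2 * pi * A * s^2, tolerance = 0.05)
  expect_equal(rec$peak_intensity, A, tolerance = 0.02)
  # half-max area ~ pi * (s * sqrt(2 log 2))^2
  expect_equal(rec$size_um2, pi * 2 * log(2) * s^2, tolerance = 0.15)
})

test_that("identical puncta segment to identical records, sorted by position", {
  img <- matrix(0, 40, 160)
  for (cx in c(40, 120)) {
    for (x in 1:160) for (y in 1:40)
      img[y, x] <- img[y, x] + 250 * exp(-((x - cx)^2 + (y - 20)^2) / (2 * 2^2))
  }
  cand <- detectCandidates(img, scales = c(1.6, 2.2))
  rec <- segmentPuncta(img, cand[rev(seq_len(nrow(cand))), ], pixelSizeUm = 0.2)
  expect_equal(nrow(rec), 2L)
  expect_false(is.unsorted(rec$axial_position_um))
  expect_equal(rec$size_um2[1], rec$size_um2[2], tolerance = 0.01)
  expect_equal(rec$integrated_intensity[1], rec$integrated_intensity[2],
               tolerance = 0.01)
})

test_that("intensity features ignore a constant background offset", {
  spec <- imageSpec(nPuncta = 4L, noiseSd = 0, background = 0, seed = 41)
  sim <- simulateAxonImage(spec)
  candA <- detectCandidates(sim$image)
  candB <- detectCandidates(sim$image + 500)
  recA <- segmentPuncta(sim$image, candA, 0.16)
  recB <- segmentPuncta(sim$image + 500, candB, 0.16)
  expect_equal(nrow(recA), nrow(recB))
  expect_equal(recB$integrated_intensity, recA$integrated_intensity,
               tolerance = 0.01)
  expect_equal(recB$peak_intensity, recA$peak_intensity, tolerance = 0.01)
})
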