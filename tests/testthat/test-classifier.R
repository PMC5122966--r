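makeToyCandidates <- function(n, center, seed) {
  set.seed(seed)
  d <- matrix(rnorm(n * 6, sd = 0.3), n, 6)
  d <- sweep(d, 2, center, "+")
  colnames(d) <- c("peak_intensity", "local_contrast", "blob_response",
                   "area_halfmax", "eccentricity", "local_background")
  data.frame(x_px = seq_len(n), y_px = 1, scale_px = 2, d)
}

test_that("separable descriptor clusters train to perfect accuracy", {
  pos <- makeToyCandidates(20, rep(3, 6), 1)
  neg <- makeToyCandidates(20, rep(-3, 6), 2)
  cand <- rbind(pos, neg)
  labels <- rep(c(TRUE, FALSE), each = 20)
  model <- trainClassifier(cand, labels, seed = 1)
  acc <- classifyCandidates(model, cand)
  expect_equal(nrow(acc), 20L)
  expect_true(all(acc$x_px %in% pos$x_px))
  # a training positive far from the margin is accepted
  expect_equal(nrow(classifyCandidates(model, pos[1, ])), 1L)
})

test_that("permuted labels give chance-level cross-validated accuracy", {
  pos <- makeToyCandidates(60, rep(1.5, 6), 3)
  neg <- makeToyCandidates(60, rep(-1.5, 6), 4)
  cand <- rbind(pos, neg)
  set.seed(99)
  labels <- sample(rep(c(TRUE, FALSE), each = 60))  # destroys the signal
  folds <- sample(rep_len(1:5, nrow(cand)))
  accs <- vapply(1:5, function(f) {
    m <- trainClassifier(cand[folds != f, ], labels[folds != f], seed = f)
    d <- synProfiler:::classifierDecision(m, cand[folds == f, m$descriptors])
    mean((d > 0) == labels[folds == f])
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("training is reproducible and serialization is bit-exact", {
  pos <- makeToyCandidates(15, rep(2, 6), 5)
  neg <- makeToyCandidates(15, rep(-2, 6), 6)
  cand <- rbind(pos, neg)
  labels <- rep(c(TRUE, FALSE), each = 15)
  m1 <- trainClassifier(cand, labels, seed = 7)
  m2 <- trainClassifier(cand, labels, seed = 7)
  probe <- makeToyCandidates(50, rep(0, 6), 8)
  expect_identical(synProfiler:::classifierDecision(m1, probe[, m1$descriptors]),
                   synProfiler:::classifierDecision(m2, probe[, m2$descriptors]))
  path <- withr::local_tempfile(fileext = ".json")
  writeClassifierJson(m1, path)
  m3 <- readClassifierJson(path)
  expect_identical(synProfiler:::classifierDecision(m1, probe[, m1$descriptors]),
                   synProfiler:::classifierDecision(m3, probe[, m3$descriptors]))
})

test_that("degenerate training inputs are rejected", {
  pos <- makeToyCandidates(20, rep(1, 6), 9)
  expect_error(trainClassifier(pos, rep(TRUE, 20)), "negative")
  expect_error(trainClassifier(pos, rep(FALSE, 20)), "positive")
  neg <- makeToyCandidates(5, rep(-1, 6), 10)
  expect_error(trainClassifier(rbind(pos, neg), c(rep(TRUE, 20), rep(FALSE, 5))),
               "at least 10")
})

test_that("classifying an empty candidate list returns an empty table", {
  pos <- makeToyCandidates(12, rep(2, 6), 11)
  neg <- makeToyCandidates(12, rep(-2, 6), 12)
  m <- trainClassifier(rbind(pos, neg), rep(c(TRUE, FALSE), each = 12))
  out <- classifyCandidates(m, pos[0, ])
  expect_equal(nrow(out), 0L)
  # dimension mismatch errors
  expect_error(classifyCandidates(m, data.frame(x_px = 1, y_px = 1)),
               "descriptor")
})

test_that("classifier prunes noise blobs on the synthetic benchmark", {
  bm <- detectionBenchmark(nImages = 15L, nTrain = 8L, seed = 2)
  expect_gte(bm$recall, 0.9)
  expect_gte(bm$precision, 0.9)
})
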