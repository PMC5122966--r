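test_that("feature registry is the canonical 76-entry table", {
  reg <- featureRegistry()
  expect_equal(nrow(reg), 76L)
  expect_identical(reg$id, 1:76)
  expect_setequal(unique(reg$category),
                  c("count", "size", "intensity", "spatial", "regional",
                    "variability"))
  # the six externally pinned descriptor names
  expect_identical(reg$name[reg$id == 1L], "number of puncta")
  expect_identical(reg$name[reg$id == 21L], "puncta intensity homogeneity")
  expect_identical(reg$name[reg$id == 33L], "intensity of posterior puncta")
  expect_identical(reg$name[reg$id == 52L], "interpunctal intensity")
  expect_identical(reg$name[reg$id == 55L], "10th percentile of integrated intensity")
  expect_identical(reg$name[reg$id == 75L], "number of puncta in the top 75% of size range")
  # stable across calls
  expect_identical(reg, featureRegistry())
})

test_that("definitional features evaluate exactly", {
  pr <- extractProfile(punctaTable(1:10))
  expect_equal(pr[["f001"]], 10)          # number of puncta
  expect_equal(pr[["f002"]], 9)           # synaptic domain length
  expect_equal(pr[["f048"]], 1)
  expect_equal(pr[["f049"]], 10)

  # identical integrated intensities: homogeneity (CV) is zero
  expect_equal(extractProfile(punctaTable(1:6, integrated = 42))[["f021"]], 0)

  # 10th percentile of integrated intensity, linear interpolation between
  # order statistics: hand value for {10,...,100} is 19
  pt <- punctaTable(1:10, integrated = seq(10, 100, by = 10))
  expect_equal(extractProfile(pt)[["f055"]], 19)
})

test_that("profiles are invariant to puncta record order", {
  set.seed(1)
  pt <- simulateAnimalPuncta(populationSpec("wt", 1, seed = 3), 1)
  shuffled <- pt[sample(nrow(pt)), ]
  expect_equal(extractProfile(shuffled), extractProfile(pt))
})

test_that("axial translation moves only absolute-location features", {
  pt <- simulateAnimalPuncta(populationSpec("wt", 1, seed = 8), 1)
  shifted <- pt
  shifted$axial_position_um <- shifted$axial_position_um + 7.5
  a <- extractProfile(pt)
  b <- extractProfile(shifted)
  absIds <- which(featureRegistry()$absolute_position)
  expect_equal(b[absIds], a[absIds] + 7.5, ignore_attr = TRUE)
  expect_equal(b[-absIds], a[-absIds], ignore_attr = TRUE)
})

test_that("intensity rescaling doubles linear features and fixes dimensionless ones", {
  pt <- simulateAnimalPuncta(populationSpec("wt", 1, seed = 13), 1)
  doubled <- pt
  for (cc in c("integrated_intensity", "peak_intensity", "interpunctal_intensity"))
    doubled[[cc]] <- 2 * doubled[[cc]]
  a <- extractProfile(pt)
  b <- extractProfile(doubled)
  lin <- which(featureRegistry()$intensity_scaling == "linear")
  expect_equal(b[lin], 2 * a[lin], ignore_attr = TRUE)
  expect_equal(b[-lin], a[-lin], ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("profiles below the five-puncta rule are flagged and filtered", {
  short <- extractProfile(punctaTable(1:4))
  expect_false(attr(short, "qc_pass"))
  expect_true(all(is.na(short)))

  m <- matrix(rnorm(76 * 3), nrow = 76)
  pp <- PhenotypeProfiles(m, paste0("a", 1:3), "wt", n_puncta = c(4L, 5L, 12L))
  filt <- qcFilter(pp)
  expect_equal(ncol(filt), 2L)                       # exactly 5 is retained
  log <- S4Vectors::metadata(filt)$qc_exclusions
  expect_equal(log$animal_id, "a1")
  expect_match(log$reason, "fewer than 5")

  empty <- qcFilter(pp[, 0])
  expect_equal(ncol(empty), 0L)
  expect_equal(nrow(S4Vectors::metadata(empty)$qc_exclusions), 0L)
})

test_that("multi-animal extraction groups by animal id", {
  p1 <- cbind(animal_id = "w1", simulateAnimalPuncta(populationSpec("wt", 2, seed = 2), 1))
  p2 <- cbind(animal_id = "w2", simulateAnimalPuncta(populationSpec("wt", 2, seed = 2), 2))
  pp <- extractProfiles(rbind(p1, p2), genotype = "wt")
  expect_equal(ncol(pp), 2L)
  expect_equal(featureMatrix(pp)["f001", "w1"], nrow(p1))
})
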