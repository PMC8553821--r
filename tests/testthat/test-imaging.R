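.handImage <- function() {
  # nucleus: 100 px of intensity 2 (total 200); cytoplasm: 300 px of
  # intensity 1 (total 300) -> ratio (200/100)/(300/300) = 2
  int <- matrix(0, 20, 20)
  nuc <- matrix(FALSE, 20, 20)
  nuc[1:10, 1:10] <- TRUE
  cell <- matrix(FALSE, 20, 20)
  cell[1:20, 1:20] <- TRUE
  int[nuc] <- 2
  int[cell & !nuc] <- 1
  LabeledCellImage(intensity = int, nucleusMasks = nuc, cellMask = cell)
}

test_that("sparse n/c ratio matches hand arithmetic and uniform limits", {
  img <- .handImage()
  expect_equal(ncRatioSparse(img), 2)
  # uniform intensity gives exactly 1
  u <- img
  u@intensity[] <- 7
  expect_equal(ncRatioSparse(u), 1)
  # invariance to positive rescaling
  s <- img
  s@intensity <- img@intensity * 37.5
  expect_equal(ncRatioSparse(s), ncRatioSparse(img))
})

test_that("confluent ratio pools nuclei per the area-weighted formula", {
  # two nuclei (totals 100 over 50 px, 300 over 100 px), zone remainder 450
  # over 450 px -> (400/150)/(450/450) = 8/3
  int <- matrix(0, 30, 30)
  n1 <- matrix(FALSE, 30, 30); n1[1:5, 1:10] <- TRUE
  n2 <- matrix(FALSE, 30, 30); n2[10:19, 1:10] <- TRUE
  zone <- matrix(FALSE, 30, 30); zone[1:30, 1:20] <- TRUE
  int[n1] <- 2
  int[n2] <- 3
  int[zone & !n1 & !n2] <- 1
  img <- LabeledCellImage(intensity = int, nucleusMasks = list(n1, n2),
                          cellMask = zone)
  expect_equal(ncRatioConfluent(img), (400 / 150) / 1)
  # single nucleus with zone = cell reduces exactly to the sparse formula
  one <- .handImage()
  expect_identical(ncRatioConfluent(one), ncRatioSparse(one))
  # overlapping nuclei are rejected
  bad <- LabeledCellImage(intensity = int,
                          nucleusMasks = list(n1, n1), cellMask = zone)
  expect_error(ncRatioConfluent(bad), "disjoint")
})

test_that("saturated or degenerate images are rejected with clear errors", {
  img <- .handImage()
  img@intensity[5, 5] <- img@saturationValue
  expect_error(ncRatioSparse(img), "[Ss]aturated")
  expect_error(ncRatioConfluent(img), "[Ss]aturated")
  z <- .handImage()
  z@intensity[z@cellMask & !z@nucleusMasks[[1]]] <- 0
  expect_error(ncRatioSparse(z), "cytoplasmic")
  # nucleus escaping the cell mask fails validity
  nuc <- matrix(FALSE, 20, 20); nuc[1:5, 1:5] <- TRUE
  cell <- matrix(FALSE, 20, 20); cell[10:20, 10:20] <- TRUE
  expect_error(LabeledCellImage(intensity = matrix(1, 20, 20),
                                nucleusMasks = nuc, cellMask = cell),
               "inside")
})

test_that("nuclear flattening recovers ellipsoid geometry from stacks", {
  stk <- makeNucleusZstack(20, 10, 5)
  g <- nuclearFlattening(stk$stack, stk$voxelSize)
  expect_equal(flattening(g), 4, tolerance = 0.05)
  expect_equal(nucleusLength(g), 20, tolerance = 0.05)
  expect_equal(nucleusHeight(g), 5, tolerance = 0.05)
  # sphere has unit flattening
  sph <- makeNucleusZstack(10, 10, 10, voxelSize = c(0.2, 0.2, 0.2))
  expect_equal(flattening(nuclearFlattening(sph$stack, sph$voxelSize)), 1,
               tolerance = 0.05)
  # blur emulating in-plane optics does not move the estimate beyond 5%
  blr <- makeNucleusZstack(20, 10, 5, blurSigma = 0.4)
  expect_equal(flattening(nuclearFlattening(blr$stack, blr$voxelSize)), 4,
               tolerance = 0.05)
  # the largest component wins over specks
  spk <- stk$stack
  spk[1, 1, 1] <- 200
  expect_equal(flattening(nuclearFlattening(spk, stk$voxelSize)),
               flattening(g), tolerance = 1e-6)
  expect_error(nuclearFlattening(array(0, c(4, 4, 4))), "threshold|empty")
})

test_that("a nucleus taller than long warns instead of failing", {
  # upright ellipsoid: 5 um in-plane, 15 um tall
  v <- c(0.25, 0.25, 0.25)
  dims <- c(40, 40, 80)
  ax <- (seq_len(dims[1]) - 0.5) * v[1] - 5
  az <- (seq_len(dims[3]) - 0.5) * v[3] - 10
  inside <- outer(outer((ax / 2.5)^2, (ax / 2.5)^2, `+`), (az / 7.5)^2,
                  `+`) <= 1
  stack <- array(10, dims)
  stack[inside] <- 200
  expect_warning(g <- nuclearFlattening(stack, v), "height exceeds")
  expect_lt(flattening(g), 1)
})

test_that("the internal Otsu threshold agrees with EBImage on full frames", {
  set.seed(77)
  m <- matrix(c(rnorm(4000, 0.3, 0.05), rnorm(4000, 0.7, 0.05)), 80, 100)
  m <- pmin(pmax(m, 0), 1)
  m[1:2, 1] <- c(0, 1)   # pin the data range to [0, 1] so bins align
  ours <- MechanoMemory:::.otsu(as.vector(m))
  ref <- EBImage::otsu(m, range = c(0, 1))
  # the class-assignment convention at the threshold bin differs, so allow
  # a few histogram bins of slack and require near-identical segmentations
  expect_lt(abs(ours - ref), 8 / 256)
  expect_lt(mean((m > ours) != (m > ref)), 0.01)
})

test_that("co-localization fraction behaves as a thresholded area overlap", {
  full <- makeColocMasks(1)
  expect_equal(colocalizationFraction(full$channelA, full$channelB,
                                      full$roi), 100)
  none <- makeColocMasks(0)
  expect_equal(colocalizationFraction(none$channelA, none$channelB,
                                      none$roi), 0)
  half <- makeColocMasks(0.5)
  expect_equal(colocalizationFraction(half$channelA, half$channelB,
                                      half$roi), 50, tolerance = 0.5)
  # asymmetric by definition: B+ is larger than its overlap with A+
  expect_false(isTRUE(all.equal(
    colocalizationFraction(half$channelA, half$channelB, half$roi),
    colocalizationFraction(half$channelB, half$channelA, half$roi))))
  # empty A+ is undefined
  flat <- matrix(5, 64, 64)
  expect_error(colocalizationFraction(flat, half$channelB),
               "positive area|undefined|threshold")
})

test_that("positive-cell fractions are simple guarded percentages", {
  expect_equal(positiveCellFraction(0, 50), 0)
  expect_equal(positiveCellFraction(50, 50), 100)
  expect_equal(positiveCellFraction(21, 60), 35)
  expect_error(positiveCellFraction(5, 0), "nTotal")
  expect_error(positiveCellFraction(-1, 10), "nPositive")
  expect_error(positiveCellFraction(11, 10), "nPositive")
})
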