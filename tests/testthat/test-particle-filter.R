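test_that("region features match expectations on canonical shapes", {
  f <- computeRegionFeatures(mkDisc(20, 64))
  expect_gte(f$convexity, 0.98)
  expect_lte(f$aspect_ratio, 1.05)
  expect_equal(f$hollowness, 0)
  expect_gte(f$circularity, 0.9)
  expect_equal(f$equiv_radius, 20, tolerance = 0.01)
  expect_equal(c(f$cx, f$cy), c(31.5, 31.5), tolerance = 0.05)

  bar <- matrix(FALSE, 50, 50); bar[10:12, 5:44] <- TRUE
  fb <- computeRegionFeatures(bar)
  expect_gte(fb$aspect_ratio, 10)
  expect_equal(fb$area, 3 * 40)
  expect_equal(fb$perimeter, 2 * (39 + 2), tolerance = 1e-9)

  # disc with a punched hole: hollowness = hole_area / area by definition
  m <- mkDisc(20, 64) & !mkDisc(4, 64)
  fh <- computeRegionFeatures(m)
  holeArea <- sum(mkDisc(4, 64))
  expect_equal(fh$hollowness, holeArea / fh$area, tolerance = 1e-9)
})

test_that("labelling matches the igraph oracle partition", {
  skip_if_not_installed("igraph")
  set.seed(11)
  m <- matrix(runif(48 * 48) > 0.6, 48, 48)
  mine <- cfuCounter:::.ccLabel8(m)
  ref <- igraphLabel(m)
  # identical partitions: label ids may differ, co-membership may not
  expect_equal(attr(mine, "nlab"), max(ref))
  expect_true(all(tapply(ref[m], mine[m], function(v) length(unique(v))) == 1))
})

test_that("screening rejects small, elongated and hollow regions", {
  p <- colonyParams(rMin = 2)
  pass <- function(m) screenRegion(computeRegionFeatures(m), p)
  expect_false(pass(mkDisc(1, 15)))                   # below minimal radius
  expect_true(pass(mkDisc(4, 21)))                    # clean disc
  expect_false(pass(mkRing(17, 13, 45)))              # bubble-like ring
  bar <- matrix(FALSE, 30, 60); bar[14:16, 5:55] <- TRUE
  expect_false(pass(bar))                             # crack-like bar
})

test_that("classification routes discs, dumbbells and fragments correctly", {
  p <- colonyParams(rMin = 2)
  cls <- function(m) classifyRegion(computeRegionFeatures(m), p, rMax = 30)
  for (r in c(3, 5, 8, 15, 25)) expect_equal(cls(mkDisc(r, 64)), "SINGLE")
  expect_equal(cls(mkPair(10)), "MULTIPLE")
  expect_equal(cls(mkPair(4)), "MULTIPLE")
  expect_equal(cls(mkChain3(5)), "MULTIPLE")
  expect_equal(cls(mkDisc(35, 80)), "INVALID")        # beyond maximal radius
})

test_that("a region too small for two minimal objects is never MULTIPLE", {
  p <- colonyParams(rMin = 3)
  set.seed(5)
  for (i in 1:25) {
    m <- matrix(FALSE, 30, 30)
    pts <- cbind(sample(8:22, 12, TRUE), sample(8:22, 12, TRUE))
    m[pts] <- TRUE
    m <- EBImage::dilate(m, EBImage::makeBrush(3, "box")) > 0
    f <- computeRegionFeatures(m)
    f <- f[f$area < 2 * pi * p@rMin^2, , drop = FALSE]
    if (nrow(f))
      expect_false(any(classifyRegion(f, p, rMax = 20) == "MULTIPLE"))
  }
})

test_that("clean-disc acceptance is monotone in radius over [rMin, rMax]", {
  p <- colonyParams(rMin = 2)
  accepted <- vapply(2:30, function(r) {
    classifyRegion(computeRegionFeatures(mkDisc(r, 75)), p,
                   rMax = 30) == "SINGLE"
  }, logical(1))
  expect_true(all(accepted))
})

test_that("identical features give identical classes", {
  f <- computeRegionFeatures(mkDisc(6, 25))
  p <- colonyParams()
  expect_identical(classifyRegion(f, p, rMax = 20),
                   classifyRegion(f, p, rMax = 20))
})
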