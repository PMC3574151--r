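test_that("a blank grey image yields no votes anywhere", {
  sm <- buildScoreMap(matrix(0, 40, 40), colonyParams(),
                      thresholds = seq(10, 90, by = 10))
  expect_true(all(votes(sm) == 0))
})

test_that("a clean disc accrues one vote per threshold below its contrast", {
  grey <- mkDisc(8, 64) * 100
  sm <- buildScoreMap(grey, colonyParams(), thresholds = seq(10, 90, by = 10))
  expect_equal(nThresholds(sm), 9)
  inner <- mkDisc(6, 64)
  expect_true(all(votes(sm)[inner] == 9))
  expect_true(all(votes(sm)[grey == 0] == 0))
})

test_that("ring artefacts never vote", {
  grey <- mkRing(17, 13, 45) * 120
  sm <- buildScoreMap(grey, colonyParams(), thresholds = seq(10, 110, by = 10))
  expect_true(all(votes(sm) == 0))
})

test_that("score-map equals the naive per-threshold oracle pixel-for-pixel", {
  skip_if_not_installed("igraph")
  p <- colonyParams(rMin = 2)
  th <- seq(6, 246, by = 8)
  # structured 64x64 fixture: discs of both sizes, a ring, a bar, a gradient
  xs <- seq_len(64) - 1
  grey <- outer(rep(1, 64), xs) * 0.3
  grey <- grey + mkDisc(7, 64, cx = 18, cy = 18) * 150
  grey <- grey + mkDisc(4, 64, cx = 45, cy = 14) * 90
  grey <- grey + (mkRing(10, 7, 64) & xs > 0) * 120
  grey[50:52, 10:50] <- grey[50:52, 10:50] + 110
  expect_identical(votes(buildScoreMap(grey, p, thresholds = th)),
                   naiveScoreMap(grey, th, p))

  # and on a smoothed random texture
  set.seed(19)
  tex <- as.matrix(EBImage::imageData(EBImage::gblur(
    matrix(runif(64 * 64), 64, 64), 1.5))) * 240
  expect_identical(votes(buildScoreMap(tex, p, thresholds = th)),
                   naiveScoreMap(tex, th, p))
})

test_that("thresholding the score map is monotone and honours bounds", {
  grey <- mkDisc(8, 64) * 100 + mkDisc(4, 64, cx = 50, cy = 50) * 40
  sm <- buildScoreMap(grey, colonyParams(), thresholds = seq(5, 95, by = 5))
  masks <- lapply(c(1, 5, 10, 19), function(t) thresholdScoreMap(sm, t))
  for (k in seq_len(length(masks) - 1))
    expect_true(all(masks[[k + 1]] <= masks[[k]]))     # mask(t+1) within mask(t)
  expect_identical(masks[[1]], votes(sm) >= 1)
  expect_identical(thresholdScoreMap(sm, nThresholds(sm)),
                   votes(sm) >= nThresholds(sm))
  expect_error(thresholdScoreMap(sm, nThresholds(sm) + 1), "unsatisfiable")
  expect_error(thresholdScoreMap(sm, 0), "positive")
})

test_that("the automatic score threshold selects a usable cut", {
  grey <- mkDisc(8, 64) * 100
  sm <- buildScoreMap(grey, colonyParams(), thresholds = seq(5, 95, by = 5))
  auto <- thresholdScoreMap(sm, "auto")
  expect_true(any(auto))
  expect_true(all(auto[votes(sm) == 0] == FALSE))
})

test_that("threshold list validation catches bad input", {
  g <- mkDisc(5, 32) * 80
  expect_error(buildScoreMap(g, thresholds = numeric()), "empty")
  expect_error(buildScoreMap(g, thresholds = c(30, 20)), "increasing")
  expect_error(buildScoreMap(g, thresholds = c(0, 10)), "0, 255")
})
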