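test_that("dish detection recovers a synthetic rim within 2 px", {
  sp <- sceneSpec(512, 512, gradientAmplitude = 5, noiseSigma = 2, seed = 2,
                  artefacts = data.frame(kind = "dish_edge", cx = 256,
                                         cy = 256, size = 200))
  sc <- renderScene(sp)
  roi <- detectDish(luminance3(sc$image), margin = 0)
  expect_equal(roiOrigin(roi), "auto_petri")
  expect_lt(max(abs(roi@centre - c(256, 256))), 2)
  expect_lt(abs(roi@radius - 200), 2)

  roi25 <- detectDish(luminance3(sc$image), margin = -25)
  expect_lt(abs(roi25@radius - 175), 2)
  expect_equal(maskSurface(roi25), sum(roi25@mask))
})

test_that("a blank image falls back to the full frame", {
  set.seed(6)
  g <- matrix(150 + rnorm(256^2, 0, 2), 256, 256)
  expect_warning(roi <- detectDish(g), "full frame")
  expect_equal(roiOrigin(roi), "full_frame")
  expect_equal(maskSurface(roi), 256^2)
})

test_that("the detected mask follows a translated dish", {
  sc <- renderScene(randomPlateSpec(30, seed = 71))
  g1 <- luminance3(sc$image)
  g2 <- luminance3(translateImage(sc$image, -25, -25))
  r1 <- detectDish(g1)
  r2 <- detectDish(g2)
  expect_lt(max(abs(r2@centre - (r1@centre - 25))), 2)
  expect_lt(abs(r2@radius - r1@radius), 2)
})

test_that("mask application zeroes outside pixels and filters by centre", {
  img <- matrix(7, 20, 20)
  roi <- manualMask(mkDisc(6, 20))
  out <- applyMask(img, roi)
  expect_true(all(out[!roi@mask] == 0))
  expect_true(all(out[roi@mask] == 7))
  expect_error(applyMask(matrix(0, 5, 5), roi), "dimensions")

  obj <- data.frame(x = c(9.5, 1), y = c(9.5, 1))
  expect_identical(filterObjectsByMask(obj, roi), c(TRUE, FALSE))
  full <- fullFrameMask(c(20, 20))
  expect_true(all(filterObjectsByMask(obj, full)))
  expect_equal(maskSurface(full), 400)
})
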