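test_that("a featureless spec renders a uniform image at the background level", {
  sp <- sceneSpec(48, 40, backgroundLevel = 120, gradientAmplitude = 0,
                  noiseSigma = 0, seed = 3)
  sc <- renderScene(sp)
  expect_equal(dim(sc$image), c(40, 48, 3))
  expect_true(all(sc$image == 120))
  expect_equal(nrow(sc$truth), 0)
})

test_that("rendering is bit-identical under a fixed seed", {
  sp <- randomPlateSpec(40, width = 320, height = 320, nBubbles = 2,
                        nCracks = 1, nDust = 2, seed = 42)
  a <- renderScene(sp)
  b <- renderScene(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  # and the spec itself regenerates identically from the same seed
  sp2 <- randomPlateSpec(40, width = 320, height = 320, nBubbles = 2,
                         nCracks = 1, nDust = 2, seed = 42)
  expect_identical(sp@colonies, sp2@colonies)
})

test_that("ground truth lists exactly the colonies and artefacts of the spec", {
  sp <- randomPlateSpec(50, clusterFraction = 0, seed = 9)
  sc <- renderScene(sp)
  expect_equal(sum(sc$truth$kind == "colony"), 50)
  expect_equal(sum(sc$truth$kind == "dish_edge"), 1)
  # invariants: centres inside bounds, radii >= 1
  co <- sp@colonies
  expect_true(all(co$radius >= 1))
  expect_true(all(co$cx >= 0 & co$cx < sp@width))
  expect_true(all(co$cy >= 0 & co$cy < sp@height))
})

test_that("scene validity rejects bad geometry", {
  expect_error(sceneSpec(0, 10), "positive")
  expect_error(sceneSpec(64, 64, colonies = data.frame(
    cx = 10, cy = 10, radius = 0.5, offset = 50, r = 1, g = 1, b = 1)),
    "radius")
  expect_error(sceneSpec(64, 64, colonies = data.frame(
    cx = 200, cy = 10, radius = 3, offset = 50, r = 1, g = 1, b = 1)),
    "inside")
})

test_that("translation shifts content, fills margins, and round-trips", {
  sp <- sceneSpec(120, 120, gradientAmplitude = 0, noiseSigma = 0, seed = 1,
                  colonies = data.frame(cx = 100, cy = 100, radius = 6,
                                        offset = 70, r = 1, g = 1, b = 1))
  sc <- renderScene(sp)
  expect_identical(translateImage(sc$image, 0, 0), sc$image)

  # sign convention: dx = dy = +25 moves the disc from (100,100) to (125,125)
  # which is outside this 120 px frame, so shift negatively instead
  sh <- translateImage(sc$image, -25, -25)
  expect_gt(sh[76, 76, 1], sh[40, 40, 1])   # disc now near (75, 75)
  expect_equal(sh[76, 76, 1], sc$image[101, 101, 1])

  rt <- translateImage(translateImage(sc$image, -25, -25), 25, 25)
  interior <- 30:110
  expect_identical(rt[interior, interior, ], sc$image[interior, interior, ])

  expect_error(translateImage(sc$image, 130, 0), "exceeds")
})

test_that("writeScene produces a readable PNG and the ground-truth CSV", {
  dir <- withr::local_tempdir()
  sc <- renderScene(randomPlateSpec(8, width = 320, height = 320, seed = 5))
  paths <- writeScene(sc, dir, "plate1")
  expect_true(all(file.exists(paths)))
  tr <- read.csv(paths["truth"])
  expect_identical(names(tr), c("id", "kind", "cx", "cy", "radius",
                                "r", "g", "b"))
  img <- readPlateImage(paths["image"])
  expect_equal(dim(img), dim(sc$image))
  expect_lt(max(abs(img - round(sc$image))), 1 + 1e-8)  # 8-bit quantisation
})
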