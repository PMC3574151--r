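test_that("background estimation recovers a uniform field exactly", {
  ch <- matrix(100, 50, 50)
  bg <- estimateBackground(ch, radius = 5)
  expect_true(all(abs(bg - 100) < 1e-6))
})

test_that("background subtraction recovers a disc on a linear ramp", {
  n <- 80
  ramp <- outer(rep(1, n), seq(80, 120, length.out = n))
  disc <- mkDisc(5, n, cx = 40, cy = 40) * 50
  ch <- ramp + disc
  bg <- estimateBackground(ch, radius = 10)
  fg <- pmax(ch - bg, 0)
  inside <- mkDisc(3, n, cx = 40, cy = 40)     # interior, away from the rim
  outside <- !mkDisc(8, n, cx = 40, cy = 40)
  outside[c(1:3, (n - 2):n), ] <- FALSE        # median edge effects
  outside[, c(1:3, (n - 2):n)] <- FALSE
  expect_true(all(abs(fg[inside] - 50) < 3))
  expect_true(all(abs(fg[outside]) < 3))
})

test_that("a kernel larger than the image is an error naming the minimum", {
  expect_error(estimateBackground(matrix(0, 10, 10), radius = 10), "21 x 21")
})

test_that("LoG enhancement matches brute-force convolution and preserves plateaus", {
  set.seed(7)
  fg <- matrix(0, 64, 64)
  fg[20:45, 20:45] <- 60                       # wide flat plateau
  noisy <- fg + matrix(runif(64 * 64, 0, 2), 64, 64)
  k <- cfuCounter:::logKernel(2, 9)
  ref <- bruteConv(noisy, k)
  lg <- as.matrix(EBImage::imageData(
    EBImage::filter2(noisy, k, boundary = "replicate")))
  expect_lt(max(abs(lg[6:59, 6:59] - ref[6:59, 6:59])), 1e-6)

  out <- enhanceChannel(fg, 2, 9)
  expect_true(all(out <= fg + 1e-9))           # never exceeds the input
  interior <- matrix(FALSE, 64, 64); interior[27:38, 27:38] <- TRUE
  expect_true(all(abs(out[interior] - fg[interior]) < 1))
  expect_true(all(enhanceChannel(matrix(0, 32, 32)) == 0))
})

test_that("channel merging normalises, averages, and flags constant channels", {
  a <- matrix(seq(0, 100, length.out = 100), 10, 10)
  m <- mergeChannels(list(a, a, a))
  expect_equal(m, (a / 100) * 255, tolerance = 1e-12)

  zero <- matrix(0, 10, 10)
  expect_warning(m2 <- mergeChannels(list(a, a, zero)), "constant channel")
  expect_equal(m2, (a / 100) * 255 * 2 / 3, tolerance = 1e-12)

  # grey-scale convenience path: normalisation only
  expect_equal(mergeChannels(a), (a / 100) * 255, tolerance = 1e-12)
})

test_that("normalisation gain is capped below the minimum contrast", {
  a <- matrix(seq(0, 10, length.out = 100), 10, 10)  # 10 grey levels of range
  m <- mergeChannels(list(a, a, a), minContrast = 60)
  expect_equal(max(m), 10 / 60 * 255, tolerance = 1e-9)
})

test_that("the pipeline output is invariant to a constant intensity offset", {
  sc <- renderScene(randomPlateSpec(12, width = 320, height = 320, seed = 21,
                                    gradientAmplitude = 0, noiseSigma = 0,
                                    offsetRange = c(40, 70),
                                    dishEdge = FALSE))
  p <- colonyParams()
  a <- preprocessImage(sc$image, p)
  b <- preprocessImage(sc$image - 30, p)  # stays within [0, 255]
  expect_equal(dim(a$grey), dim(sc$image)[1:2])
  expect_lt(max(abs(a$grey - b$grey)), 2)
  expect_equal(a$polarity, 1)
})

test_that("dark colonies are auto-detected and handled by polarity", {
  sp <- randomPlateSpec(15, width = 320, height = 320, seed = 33,
                        offsetRange = c(-85, -60), dishEdge = FALSE)
  sc <- renderScene(sp)
  pre <- preprocessImage(sc$image, colonyParams())
  expect_equal(pre$polarity, -1)
  cs <- countColonies(sc$image, autoPetri = FALSE)
  expect_equal(colonyCount(cs), 15)
})
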