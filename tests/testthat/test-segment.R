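test_that("chamfer distances reproduce the stated step weights", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  expect_equal(chamferDistance(m)[3, 3], 1)          # orthogonal step a = 1

  m2 <- matrix(FALSE, 7, 7); m2[3:4, 3:4] <- TRUE
  d2 <- chamferDistance(m2)
  expect_true(all(d2[3:4, 3:4] == 1))                # 2x2 block: all border

  # plus-shaped mask: the centre's orthogonal neighbours are foreground but
  # a diagonal neighbour is background, one diagonal step costs b = 1.4
  m3 <- matrix(FALSE, 9, 9)
  m3[4, 3:5] <- TRUE; m3[3:5, 4] <- TRUE
  expect_equal(chamferDistance(m3)[4, 4], 1.4)

  expect_equal(chamferPointDistance(1, 2), 2.1969)   # knight move c
  expect_equal(chamferPointDistance(2, 2), 2.8)
  expect_equal(chamferPointDistance(0, 3), 3)
})

test_that("the transform equals brute-force shortest chamfer paths", {
  fixtures <- list(
    mkDisc(6, 17),
    mkPair(4, n = 25),
    mkRing(9, 6, 25),
    {
      set.seed(13)
      matrix(runif(32 * 32) > 0.4, 32, 32)
    })
  for (m in fixtures)
    expect_equal(chamferDistance(m), bruteChamfer(m), tolerance = 1e-9)
})

test_that("markers: one per disc, two per dumbbell, none on empty maps", {
  expect_equal(nrow(findMarkers(chamferDistance(mkDisc(8, 30)))), 1)
  dm <- chamferDistance(mkPair(10, dfac = 3, n = 60))  # centres 30 apart
  mk <- findMarkers(dm)
  expect_equal(nrow(mk), 2)
  expect_equal(mk$peak[1], mk$peak[2])
  expect_equal(nrow(findMarkers(matrix(0, 10, 10))), 0)
})

test_that("watershed fills a single disc and splits a dumbbell at the neck", {
  m <- mkDisc(9, 30)
  dm <- chamferDistance(m)
  ws <- constrainedWatershed(dm, findMarkers(dm))
  expect_equal(sum(ws$labels > 0), sum(m))            # entire disc claimed

  db <- mkPair(10, dfac = 1.5, n = 60)
  dmd <- chamferDistance(db)
  wsd <- constrainedWatershed(dmd, findMarkers(dmd))
  expect_equal(max(wsd$labels), 2)
  expect_true(all(sort(unique(as.vector(wsd$labels))) == 0:2))
  expect_true(all(wsd$labels[!db] == 0))              # never touches background
  # boundary lies in the neck: compare to the nearest-marker partition
  mk <- wsd$markers
  lab <- wsd$labels
  pix <- which(lab > 0, arr.ind = TRUE)
  d1 <- sqrt((pix[, 1] - mk$row[1])^2 + (pix[, 2] - mk$col[1])^2)
  d2 <- sqrt((pix[, 1] - mk$row[2])^2 + (pix[, 2] - mk$col[2])^2)
  voronoi <- ifelse(d1 < d2, 1L, 2L)
  disagree <- lab[lab > 0] != voronoi & abs(d1 - d2) > 2
  expect_lt(mean(disagree), 0.02)
})

test_that("watershed regions satisfy their area and marker-distance limits", {
  fixtures <- list(mkDisc(9, 30), mkPair(6), mkPair(10), mkChain3(5),
                   mkChain3(8))
  for (m in fixtures) {
    dm <- chamferDistance(m)
    mk <- findMarkers(dm)
    ws <- constrainedWatershed(dm, mk, kappaArea = 1.3, kappaDist = 1.5)
    for (L in seq_len(nrow(mk))) {
      pix <- which(ws$labels == L, arr.ind = TRUE)
      if (!nrow(pix)) next
      expect_lte(nrow(pix), 1.3 * pi * mk$peak[L]^2)
      dmk <- chamferPointDistance(pix[, 1] - mk$row[L], pix[, 2] - mk$col[L])
      expect_true(all(dmk < 1.5 * mk$peak[L] | dmk == 0))
    }
    # labels partition a subset of the foreground
    expect_true(all(ws$labels[!m] == 0))
  }
})

test_that("the distance map is Lipschitz with respect to the chamfer steps", {
  dm <- chamferDistance(mkPair(8))
  nr <- nrow(dm)
  inner <- dm[2:(nr - 1), 2:(nr - 1)]
  for (dd in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    nb <- dm[2:(nr - 1) + dd[1], 2:(nr - 1) + dd[2]]
    w <- if (all(dd != 0)) 1.4 else 1
    sel <- inner > 0 & nb > 0
    expect_true(all(abs(inner - nb)[sel] <= w + 1e-9))
  }
})

test_that("split-and-validate handles singles, dumbbells, triples and cracks", {
  p <- colonyParams(rMin = 2)
  one <- splitAndValidate(mkDisc(7, 30), p, rMax = 20)
  expect_equal(nrow(one$objects), 1)
  expect_equal(one$objects$cluster_size, 1L)

  two <- splitAndValidate(mkPair(6), p, rMax = 20)
  expect_equal(nrow(two$objects), 2)
  expect_equal(two$objects$cluster_size, c(2L, 2L))

  three <- splitAndValidate(mkChain3(5), p, rMax = 20)
  expect_equal(nrow(three$objects), 3)
  expect_equal(three$objects$cluster_size, rep(3L, 3))

  crack <- matrix(FALSE, 60, 60)
  for (k in 0:39) crack[12 + round(k * 0.45), 10 + k] <- TRUE
  crack <- EBImage::dilate(crack, EBImage::makeBrush(3, "box")) > 0
  none <- splitAndValidate(crack, p, rMax = 20)
  expect_equal(nrow(none$objects), 0)
})

test_that("watershed without markers is an error", {
  dm <- chamferDistance(mkDisc(5, 20))
  expect_error(constrainedWatershed(dm, findMarkers(matrix(0, 5, 5))),
               "marker")
})
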