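mkObjects <- function(cols, clusterSize = 1) {
  data.frame(median_r = cols[, 1], median_g = cols[, 2], median_b = cols[, 3],
             cluster_size = rep(clusterSize, length.out = nrow(cols)))
}

test_that("identical colours give a floored sd and equal likelihoods", {
  obj <- mkObjects(matrix(rep(c(60, 55, 40), each = 8), ncol = 3))
  m <- fitColourModel(obj)
  expect_true(m@usable)
  expect_equal(m@nFit, 8L)
  expect_true(all(m@sd == 0.01))              # floored at eps
  expect_false(any(filterByLikelihood(obj, m, 0.5)))
})

test_that("the fit uses only non-split objects", {
  good <- matrix(rep(c(60, 55, 40), each = 6), ncol = 3)
  outlier <- matrix(c(90, 5, 5), ncol = 3)
  obj <- rbind(mkObjects(good, 1), mkObjects(outlier, 2))
  m <- fitColourModel(obj)
  expect_equal(m@nFit, 6L)
  rel <- c(60, 55, 40) / sum(c(60, 55, 40))
  expect_equal(m@mean, rel, tolerance = 1e-9)
})

test_that("fewer than 3 non-split objects disables the filter", {
  obj <- mkObjects(matrix(c(60, 55, 40, 61, 54, 41), 2, 3, byrow = TRUE))
  expect_warning(m <- fitColourModel(obj), "disabled")
  expect_false(m@usable)
  expect_false(any(filterByLikelihood(obj, m, 0.9)))
})

test_that("minority colour objects are excluded, majority kept", {
  set.seed(4)
  yellow <- matrix(rep(c(70, 65, 48), each = 20), 20, 3) +
    matrix(rnorm(60, 0, 1.5), 20, 3)
  red <- cbind(c(70, 72), c(22, 25), c(20, 22))
  obj <- mkObjects(rbind(yellow, red))
  m <- fitColourModel(obj)
  ex <- filterByLikelihood(obj, m, 0.001)
  expect_identical(ex, c(rep(FALSE, 20), TRUE, TRUE))
  # model mean tracks the majority
  expect_equal(m@mean, colMeans(yellow / rowSums(yellow)), tolerance = 0.05)
})

test_that("cutoff semantics: zero excludes nothing, the mean never goes", {
  set.seed(8)
  cols <- matrix(rep(c(70, 60, 45), each = 12), 12, 3) +
    matrix(rnorm(36, 0, 3), 12, 3)
  obj <- mkObjects(cols)
  m <- fitColourModel(obj)
  expect_false(any(filterByLikelihood(obj, m, 0)))
  atMean <- mkObjects(matrix(m@mean * 150, 1, 3))  # exactly the model mean
  expect_false(filterByLikelihood(atMean, m, 0.999))
})

test_that("raising the cutoff never un-excludes an object", {
  set.seed(12)
  cols <- matrix(rep(c(70, 60, 45), each = 30), 30, 3) +
    matrix(rnorm(90, 0, 6), 30, 3)
  obj <- mkObjects(cols)
  m <- fitColourModel(obj)
  prev <- rep(FALSE, nrow(obj))
  for (q in c(0.001, 0.01, 0.05, 0.2, 0.5)) {
    ex <- filterByLikelihood(obj, m, q)
    expect_true(all(ex[prev]))                 # monotone
    prev <- ex
  }
})

test_that("the kept/excluded partition is invariant to intensity scaling", {
  set.seed(3)
  cols <- matrix(rep(c(70, 60, 45), each = 20), 20, 3) +
    matrix(rnorm(60, 0, 5), 20, 3)
  obj <- mkObjects(cols)
  obj2 <- obj
  obj2[1:3] <- obj2[1:3] * 2.7
  m1 <- fitColourModel(obj)
  m2 <- fitColourModel(obj2)
  expect_identical(filterByLikelihood(obj, m1, 0.05),
                   filterByLikelihood(obj2, m2, 0.05))
})
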