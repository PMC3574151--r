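# Geometric fixtures (built in code) and independent oracles used across the
# suite. The oracles deliberately avoid the package's own C++ primitives:
# labelling via igraph, hole filling via EBImage::fillHull, chamfer distances
# via Bellman-Ford relaxation, convolution by direct evaluation.

mkDisc <- function(r, n = 2 * ceiling(r) + 11, cx = (n - 1) / 2,
                   cy = (n - 1) / 2) {
  xs <- seq_len(n) - 1
  sqrt(outer((xs - cy)^2, (xs - cx)^2, "+")) <= r
}

mkRing <- function(rOut, rIn, n = 2 * ceiling(rOut) + 11) {
  xs <- seq_len(n) - 1
  c0 <- (n - 1) / 2
  d <- sqrt(outer((xs - c0)^2, (xs - c0)^2, "+"))
  d <= rOut & d >= rIn
}

mkPair <- function(r, dfac = 1.5, n = 2 * ceiling(r * 2.6) + 11) {
  xs <- seq_len(n) - 1
  c0 <- (n - 1) / 2
  d <- dfac * r
  sqrt(outer((xs - c0)^2, (xs - c0 - d / 2)^2, "+")) <= r |
    sqrt(outer((xs - c0)^2, (xs - c0 + d / 2)^2, "+")) <= r
}

mkChain3 <- function(r, dfac = 1.5, n = 2 * ceiling(r * 4) + 11) {
  xs <- seq_len(n) - 1
  c0 <- (n - 1) / 2
  d <- dfac * r
  m <- matrix(FALSE, n, n)
  for (cx in c(c0 - d, c0, c0 + d))
    m <- m | sqrt(outer((xs - c0)^2, (xs - cx)^2, "+")) <= r
  m
}

# 8-connected component labelling through igraph (oracle for .ccLabel8)
igraphLabel <- function(mask) {
  skip_if_not_installed("igraph")
  idx <- which(mask)
  if (!length(idx)) return(matrix(0L, nrow(mask), ncol(mask)))
  nr <- nrow(mask)
  rc <- arrayInd(idx, dim(mask))
  id <- seq_along(idx)
  key <- idx
  lookup <- integer(length(mask))
  lookup[key] <- id
  edges <- NULL
  for (dd in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    nrw <- rc[, 1] + dd[1]
    ncl <- rc[, 2] + dd[2]
    ok <- nrw >= 1 & nrw <= nr & ncl >= 1 & ncl <= ncol(mask)
    nidx <- nrw[ok] + (ncl[ok] - 1) * nr
    has <- lookup[nidx] > 0
    edges <- rbind(edges, cbind(id[ok][has], lookup[nidx[has]]))
  }
  if (is.null(edges)) {
    memb <- seq_along(idx)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
  }
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[idx] <- memb
  out
}

# screening features computed from scratch in R (oracle for the sweep)
oracleScreen <- function(mask, pix, params) {
  area <- length(pix)
  if (sqrt(area / pi) < params@rMin) return(FALSE)
  rc <- arrayInd(pix, dim(mask))
  mx <- mean(rc[, 2]); my <- mean(rc[, 1])
  cxx <- mean((rc[, 2] - mx)^2) + 1 / 12
  cyy <- mean((rc[, 1] - my)^2) + 1 / 12
  cxy <- mean((rc[, 2] - mx) * (rc[, 1] - my))
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE,
              only.values = TRUE)$values
  aspect <- sqrt(max(ev) / max(min(ev), 1e-9))
  if (aspect > params@screenAspectMax) return(FALSE)
  comp <- matrix(0L, nrow(mask), ncol(mask))
  comp[pix] <- 1L
  filled <- EBImage::fillHull(comp)
  hollow <- (sum(filled) - area) / area
  hollow <= params@screenHollowMax
}

# naive per-threshold score map re-implementation (oracle for buildScoreMap)
naiveScoreMap <- function(grey, thresholds, params) {
  votes <- matrix(0L, nrow(grey), ncol(grey))
  for (t in thresholds) {
    bw <- grey >= t
    if (!any(bw)) next
    labs <- igraphLabel(bw)
    for (L in seq_len(max(labs))) {
      pix <- which(labs == L)
      if (oracleScreen(bw, pix, params))
        votes[pix] <- votes[pix] + 1L
    }
  }
  votes
}

# all-pairs shortest chamfer path by Bellman-Ford relaxation over the
# 16 offsets of the 5x5 neighbourhood (oracle for chamferDistance)
bruteChamfer <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- rbind(
    cbind(expand.grid(dr = c(-1, 1), dc = 0), w = 1),
    cbind(expand.grid(dr = 0, dc = c(-1, 1)), w = 1),
    cbind(expand.grid(dr = c(-1, 1), dc = c(-1, 1)), w = 1.4),
    cbind(expand.grid(dr = c(-1, 1), dc = c(-2, 2)), w = 2.1969),
    cbind(expand.grid(dr = c(-2, 2), dc = c(-1, 1)), w = 2.1969))
  d <- matrix(0, nr, nc)
  d[mask] <- Inf
  repeat {
    changed <- FALSE
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (!mask[i, j]) next
      v <- d[i, j]
      for (k in seq_len(nrow(offs))) {
        ii <- i + offs$dr[k]; jj <- j + offs$dc[k]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
          w <- d[ii, jj] + offs$w[k]
          if (w < v - 1e-12) v <- w
        }
      }
      if (v < d[i, j]) { d[i, j] <- v; changed <- TRUE }
    }
    if (!changed) break
  }
  d
}

# direct (quadruple-loop free, but evaluated per output pixel) convolution
# with replicate boundary (oracle for the LoG filtering)
bruteConv <- function(x, k) {
  nr <- nrow(x); nc <- ncol(x)
  half <- (nrow(k) - 1) / 2
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -half:half) for (dj in -half:half) {
      ii <- min(max(i + di, 1), nr)
      jj <- min(max(j + dj, 1), nc)
      acc <- acc + x[ii, jj] * k[di + half + 1, dj + half + 1]
    }
    out[i, j] <- acc
  }
  out
}

# greedy matching of detections to ground-truth colonies
matchTruth <- function(rec, truth) {
  tr <- truth[truth$kind == "colony", , drop = FALSE]
  used <- rep(FALSE, nrow(rec))
  missed <- 0L
  for (i in seq_len(nrow(tr))) {
    d <- sqrt((rec$x - tr$cx[i])^2 + (rec$y - tr$cy[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tr$radius[i] + 1)
      used[j] <- TRUE
    else missed <- missed + 1L
  }
  list(missed = missed, extra = sum(!used))
}

luminance3 <- function(img) (img[, , 1] + img[, , 2] + img[, , 3]) / 3
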