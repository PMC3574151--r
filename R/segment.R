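#' Chamfer distance transform
#'
#' Two-pass (forward/backward) chamfer distance transform on a 5 x 5 pixel
#' neighbourhood with step weights a = 1 (orthogonal), b = 1.4 (diagonal) and
#' c = 2.1969 (knight move). Background pixels get 0; each foreground pixel
#' gets the length of the shortest chamfer path to the in-image background.
#'
#' @param mask logical matrix.
#' @return numeric matrix of distances.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
#' chamferDistance(m)[3, 3]   # 1: nearest background one orthogonal step away
#' @export
chamferDistance <- function(mask) {
  if (!is.logical(mask)) mask <- mask > 0
  .chamferCpp(mask)
}

#' Find watershed markers in a distance map
#'
#' Markers are the local maxima of the distance map (8-neighbourhood);
#' plateaus of equal value merge into a single marker placed at the plateau
#' pixel nearest the plateau centroid, except that a plateau longer than
#' 1.2 times its peak value is a flat ridge spanning two fused centres and
#' seeds a marker at each of its two extremal pixels. A candidate closer
#' (chamfer point metric) than \code{max(nmsDist, 0.9 * peak)} to an
#' already accepted higher-or-equal marker is suppressed, where peak is the
#' candidate's own value: a maximum that close to a stronger centre is a
#' digitisation plateau or a ridge saddle, since a genuine second colony of
#' that presumptive radius would put its centre at least about one radius
#' away.
#' The peak value is the presumptive radius of the object seeded there.
#'
#' @param dm distance map from [chamferDistance()].
#' @param nmsDist non-maximum suppression distance.
#' @return data.frame \code{row, col} (1-based pixel indices) and
#'   \code{peak}, sorted by decreasing peak (ties by row then column).
#' @export
findMarkers <- function(dm, nmsDist = 2) {
  nr <- nrow(dm); nc <- ncol(dm)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- dm
  isMax <- dm > 0
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    isMax <- isMax & dm >= pad[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
  }
  if (!any(isMax))
    return(data.frame(row = integer(), col = integer(), peak = numeric()))
  lab <- .ccLabel8(isMax)
  nlab <- attr(lab, "nlab")
  idx <- which(isMax, arr.ind = TRUE)
  lv <- lab[isMax]
  rows <- cols <- peaks <- numeric(0)
  for (L in seq_len(nlab)) {
    pr <- idx[lv == L, , drop = FALSE]
    pk <- dm[pr[1, 1], pr[1, 2]]
    # an elongated plateau is a flat ridge spanning two fused centres, not a
    # single disc centre: seed both of its extremal pixels
    ext <- 0; e1 <- e2 <- 1
    if (nrow(pr) > 1) {
      dd <- as.matrix(dist(pr))
      w <- which(dd == max(dd), arr.ind = TRUE)[1, ]
      ext <- max(dd); e1 <- w[1]; e2 <- w[2]
    }
    if (ext >= 1.2 * pk) {
      rows <- c(rows, pr[e1, 1], pr[e2, 1])
      cols <- c(cols, pr[e1, 2], pr[e2, 2])
      peaks <- c(peaks, pk, pk)
    } else {
      cr <- colMeans(pr)
      k <- which.min((pr[, 1] - cr[1])^2 + (pr[, 2] - cr[2])^2)
      rows <- c(rows, pr[k, 1])
      cols <- c(cols, pr[k, 2])
      peaks <- c(peaks, pk)
    }
  }
  o <- order(-peaks, rows, cols)
  rows <- rows[o]; cols <- cols[o]; peaks <- peaks[o]
  keep <- logical(length(peaks))
  for (i in seq_along(peaks)) {
    ok <- TRUE
    prev <- which(keep[seq_len(i - 1)])
    for (j in prev) {
      d <- chamferPointDistance(rows[j] - rows[i], cols[j] - cols[i])
      if (d < max(nmsDist, 0.9 * peaks[i])) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  data.frame(row = as.integer(rows[keep]), col = as.integer(cols[keep]),
             peak = peaks[keep])
}

#' Marker-constrained watershed on a distance map
#'
#' Region growing from the markers, honouring three rules: a marked pixel may
#' only claim an unmarked neighbour whose distance value is lower or equal
#' (downhill-or-flat growth); a region's area may never exceed
#' \code{kappaArea * pi * peak^2}, where peak is its marker's distance value
#' (the presumptive radius); and the chamfer distance from the original
#' marker to any claimed pixel must stay below \code{kappaDist * peak}.
#' Growth is scheduled through a priority queue by descending distance value
#' with ties broken in (row, column) scan order, so the result does not
#' depend on marker order. Growth proceeds until no region can grow;
#' unclaimed foreground stays unlabelled.
#'
#' @param dm distance map from [chamferDistance()].
#' @param markers data.frame from [findMarkers()] (at least one row).
#' @param kappaArea,kappaDist limit factors.
#' @return list with \code{labels} (integer matrix; 0 = unclaimed) and the
#'   \code{markers} used (label i = row i).
#' @export
constrainedWatershed <- function(dm, markers, kappaArea = 1.3,
                                 kappaDist = 1.5) {
  if (nrow(markers) == 0) stop("constrainedWatershed requires >= 1 marker")
  m <- cbind(markers$row, markers$col, markers$peak)
  lab <- .watershedCpp(dm, m, kappaArea, kappaDist)
  list(labels = lab, markers = markers)
}

#' Segment the detection mask and validate every object
#'
#' Second pass of the detection. The thresholded score map is labelled;
#' every component is classified by the particle filter
#' ([classifyRegion()]): single objects are accepted directly, invalid
#' components are rejected, and multiple-object components are split by
#' [chamferDistance()], [findMarkers()] and [constrainedWatershed()] on
#' their own cropped sub-mask. Each resulting fragment is reassessed by the
#' particle filter: fragments confirming as single objects are accepted,
#' invalid fragments are dropped, and fragments that still classify as
#' multiple objects (e.g. a truncated pair inside a larger cluster) are
#' split again by the same procedure, to a depth of 3. Accepted fragments
#' record how many siblings were accepted from the same original cluster
#' (\code{cluster_size}).
#'
#' @param mask logical detection mask from [thresholdScoreMap()].
#' @param params a [ColonyParams-class].
#' @param rMax resolved maximal radius (defaults to \code{params@rMax}; pass
#'   the image-derived value when \code{params@rMax} is NA).
#' @return list with \code{objects} (data.frame: \code{x, y, area,
#'   perimeter, cluster_size}) and \code{labelMap} (integer matrix mapping
#'   pixels to object ids, for colour measurements), plus \code{splits}
#'   (diagnostic list of watershed results per split cluster).
#' @export
splitAndValidate <- function(mask, params = colonyParams(), rMax = NULL) {
  rMax <- if (!is.null(rMax)) rMax else params@rMax
  lab <- .ccLabel8(mask)
  nlab <- attr(lab, "nlab")
  labelMap <- matrix(0L, nrow(mask), ncol(mask))
  objects <- data.frame(x = numeric(), y = numeric(), area = numeric(),
                        perimeter = numeric(), cluster_size = integer())
  splits <- list()
  if (nlab == 0L)
    return(list(objects = objects, labelMap = labelMap, splits = splits))

  feats <- computeRegionFeatures(lab)
  ok <- screenRegion(feats, params)
  cls <- rep("INVALID", nlab)
  cls[ok] <- classifyRegion(feats[ok, , drop = FALSE], params, rMax = rMax)

  nextId <- 0L
  addObject <- function(fRow, pixIdx, clusterSize) {
    nextId <<- nextId + 1L
    labelMap[pixIdx] <<- nextId
    objects <<- rbind(objects, data.frame(
      x = fRow$cx, y = fRow$cy, area = fRow$area,
      perimeter = fRow$perimeter, cluster_size = as.integer(clusterSize)))
  }

  # Split one cropped cluster mask; returns a list of accepted fragments
  # (features + global pixel indices). Fragments still classifying MULTIPLE
  # recurse while they keep shrinking.
  splitCluster <- function(sub, i0, j0, depth) {
    dm <- chamferDistance(sub)
    mk <- findMarkers(dm, params@markerNmsDist)
    if (nrow(mk) == 0) return(list())
    ws <- constrainedWatershed(dm, mk, params@kappaArea, params@kappaDist)
    wl <- ws$labels
    if (max(wl) == 0L) return(list())
    splits[[length(splits) + 1L]] <<- list(offset = c(i0, j0), dist = dm,
                                           markers = mk, labels = wl)
    wf <- computeRegionFeatures(wl)
    cls <- rep("INVALID", nrow(wf))
    okf <- screenRegion(wf, params)
    cls[okf] <- classifyRegion(wf[okf, , drop = FALSE], params, rMax = rMax)
    out <- list()
    for (F in seq_len(nrow(wf))) {
      if (cls[F] == "INVALID") next
      fpix <- which(wl == F)
      if (cls[F] == "SINGLE") {
        frc <- arrayInd(fpix, dim(wl))
        gidx <- (frc[, 1] + i0 - 1L) + (frc[, 2] + j0 - 2L) * nrow(lab)
        fRow <- wf[F, ]
        fRow$cx <- fRow$cx + j0 - 1L
        fRow$cy <- fRow$cy + i0 - 1L
        out[[length(out) + 1L]] <- list(row = fRow, pix = gidx)
      } else if (depth < 3L && wf$area[F] < 0.95 * sum(sub)) {
        frc <- arrayInd(fpix, dim(wl))
        fi0 <- max(1L, min(frc[, 1]) - 2L)
        fi1 <- min(nrow(wl), max(frc[, 1]) + 2L)
        fj0 <- max(1L, min(frc[, 2]) - 2L)
        fj1 <- min(ncol(wl), max(frc[, 2]) + 2L)
        fsub <- wl[fi0:fi1, fj0:fj1] == F
        out <- c(out, splitCluster(fsub, i0 + fi0 - 1L, j0 + fj0 - 1L,
                                   depth + 1L))
      }
    }
    out
  }

  for (L in seq_len(nlab)) {
    if (cls[L] == "INVALID") next
    pix <- which(lab == L)
    if (cls[L] == "SINGLE") {
      addObject(feats[L, ], pix, 1L)
      next
    }
    # MULTIPLE: split on the cropped component
    rc <- arrayInd(pix, dim(lab))
    i0 <- max(1L, min(rc[, 1]) - 2L); i1 <- min(nrow(lab), max(rc[, 1]) + 2L)
    j0 <- max(1L, min(rc[, 2]) - 2L); j1 <- min(ncol(lab), max(rc[, 2]) + 2L)
    sub <- lab[i0:i1, j0:j1] == L
    frags <- splitCluster(sub, i0, j0, 0L)
    nAccepted <- length(frags)
    for (fr in frags) addObject(fr$row, fr$pix, nAccepted)
  }
  rownames(objects) <- NULL
  list(objects = objects, labelMap = labelMap, splits = splits)
}
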