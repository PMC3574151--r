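#' Full-frame region of interest
#'
#' @param dims image dimensions (rows, cols) or a matrix/array to take them
#'   from.
#' @return a [RoiMask-class] covering the whole frame.
#' @export
fullFrameMask <- function(dims) {
  if (is.matrix(dims) || is.array(dims)) dims <- dim(dims)[1:2]
  new("RoiMask", mask = matrix(TRUE, dims[1], dims[2]), origin = "full_frame",
      centre = c(NA_real_, NA_real_), radius = NA_real_)
}

#' Manual region of interest from a binary mask
#'
#' @param mask logical or numeric matrix (non-zero = inside).
#' @return a [RoiMask-class] with origin \code{"manual"}.
#' @export
manualMask <- function(mask) {
  new("RoiMask", mask = mask > 0, origin = "manual",
      centre = c(NA_real_, NA_real_), radius = NA_real_)
}

# disc mask helper (0-based centre coordinates, x = column)
discMask <- function(dims, cx, cy, radius) {
  xs <- seq_len(dims[2]) - 1
  ys <- seq_len(dims[1]) - 1
  outer((ys - cy)^2, (xs - cx)^2, "+") <= radius^2
}

#' Automatic Petri-dish detection (Hough circle transform)
#'
#' Finds the dominant circle (the dish rim) with a gradient-guided Hough
#' circle transform: edge pixels vote along their gradient direction for
#' circle centres over a range of radii; the best accumulator cell is
#' refined by a least-squares circle fit to the inlier edge pixels. The ROI
#' is a disc of the fitted radius adjusted by \code{margin} (negative
#' shrinks inward, e.g. -25 px). Because the dish is re-detected per image,
#' the ROI follows shifts of the dish between acquisitions. If no circle
#' gathers enough support, the full frame is returned with a warning.
#'
#' @param grey matrix (0-255), typically the raw luminance.
#' @param margin signed radius adjustment in pixels (default -25).
#' @param radiusRange search range as a fraction of \code{min(dim)}.
#' @param accThreshold minimal fraction of the circle circumference that
#'   must be supported by inlier edge pixels.
#' @return a [RoiMask-class] with origin \code{"auto_petri"} (or
#'   \code{"full_frame"} on fallback).
#' @export
detectDish <- function(grey, margin = -25, radiusRange = c(0.25, 0.55),
                       accThreshold = 0.3) {
  nr <- nrow(grey); nc <- ncol(grey)
  m <- min(nr, nc)
  sm <- EBImage::gblur(grey / 255, sigma = 2)
  sm <- as.matrix(EBImage::imageData(sm)) * 255
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)  # Sobel d/dx (columns)
  gx <- as.matrix(EBImage::imageData(
    EBImage::filter2(sm, t(kx), boundary = "replicate")))
  gy <- as.matrix(EBImage::imageData(
    EBImage::filter2(sm, kx, boundary = "replicate")))
  gmag <- sqrt(gx^2 + gy^2)
  thr <- max(0.3 * quantile(gmag, 0.999), 15)
  edge <- which(gmag >= thr)
  if (length(edge) < 60) {
    warning("no circle found: falling back to the full frame")
    return(fullFrameMask(c(nr, nc)))
  }
  er <- (edge - 1) %% nr + 1
  ec <- (edge - 1) %/% nr + 1
  ux <- gx[edge] / gmag[edge]
  uy <- gy[edge] / gmag[edge]
  ex <- ec - 1  # 0-based coordinates
  ey <- er - 1

  # aligned support: inliers on the annulus whose gradient is radial; edge
  # pixels of foreground clutter have random orientation and barely count
  alignedSupport <- function(cx, cy, r, tol = 2) {
    dx <- ex - cx; dy <- ey - cy
    d <- sqrt(dx^2 + dy^2)
    ok <- abs(d - r) <= tol & d > 1
    sum(abs(ux[ok] * dx[ok] + uy[ok] * dy[ok]) / d[ok] >= 0.9)
  }
  refine <- function(cx, cy, r) {
    for (it in 1:3) {
      dx <- ex - cx; dy <- ey - cy
      d <- sqrt(dx^2 + dy^2)
      align <- abs(ux * dx + uy * dy) / pmax(d, 1)
      inl <- abs(d - r) <= 4 & align >= 0.85
      if (sum(inl) < 20) return(NULL)
      A <- cbind(2 * ex[inl], 2 * ey[inl], 1)
      b <- ex[inl]^2 + ey[inl]^2
      sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
      if (is.null(sol)) return(NULL)
      cx <- sol[1]; cy <- sol[2]
      r <- sqrt(max(sol[3] + cx^2 + cy^2, 1))
    }
    c(cx, cy, r)
  }

  bin <- 2
  nbx <- ceiling(nc / bin); nby <- ceiling(nr / bin)
  radii <- seq(radiusRange[1] * m, radiusRange[2] * m, by = 2)
  cand <- data.frame(score = numeric(), r = numeric(), cx = numeric(),
                     cy = numeric())
  for (r in radii) {
    votes <- integer(nbx * nby)
    for (s in c(-1, 1)) {
      cx <- ex + s * r * ux
      cy <- ey + s * r * uy
      okv <- cx >= 0 & cx < nc & cy >= 0 & cy < nr
      if (!any(okv)) next
      bi <- floor(cy[okv] / bin) + nby * floor(cx[okv] / bin) + 1
      votes <- votes + tabulate(bi, nbins = nbx * nby)
    }
    mi <- which.max(votes)
    by0 <- (mi - 1) %% nby
    bx0 <- (mi - 1) %/% nby
    cand <- rbind(cand, data.frame(score = votes[mi] / r, r = r,
                                   cx = bx0 * bin + bin / 2,
                                   cy = by0 * bin + bin / 2))
  }
  cand <- cand[order(-cand$score), , drop = FALSE][seq_len(min(10, nrow(cand))), ]
  best <- list(frac = -Inf, cx = NA, cy = NA, r = NA)
  for (i in seq_len(nrow(cand))) {
    fit <- refine(cand$cx[i], cand$cy[i], cand$r[i])
    if (is.null(fit) || !is.finite(fit[3]) || fit[3] < radiusRange[1] * m / 2)
      next
    frac <- alignedSupport(fit[1], fit[2], fit[3]) / (2 * pi * fit[3])
    if (frac > best$frac)
      best <- list(frac = frac, cx = fit[1], cy = fit[2], r = fit[3])
  }
  cx <- best$cx; cy <- best$cy; r <- best$r
  if (!is.finite(r) || best$frac < accThreshold) {
    warning("no circle found: falling back to the full frame")
    return(fullFrameMask(c(nr, nc)))
  }
  # snap the radius onto the rim centreline: the fitted radius sits between
  # the rim's two edges and can drift by a few pixels when the rim is partly
  # out of frame; the ring of extremal mean intensity is stable
  ringMean <- function(rr) {
    th <- seq(0, 2 * pi, length.out = max(90, round(pi * rr)))
    xi <- round(cx + rr * cos(th))
    yi <- round(cy + rr * sin(th))
    ok <- xi >= 0 & xi < nc & yi >= 0 & yi < nr
    if (!any(ok)) return(NA_real_)
    mean(sm[cbind(yi[ok] + 1, xi[ok] + 1)])
  }
  med <- median(sm)
  rs <- seq(max(r - 5, 2), r + 5, by = 0.25)
  dev <- abs(vapply(rs, ringMean, numeric(1)) - med)
  if (any(is.finite(dev))) r <- rs[which.max(dev)]
  radius <- r + margin
  if (radius <= 2) stop("margin leaves an empty region of interest")
  new("RoiMask", mask = discMask(c(nr, nc), cx, cy, radius),
      origin = "auto_petri", centre = c(cx, cy), radius = radius)
}

#' Apply a region of interest
#'
#' \code{applyMask} zeroes image pixels outside the ROI;
#' \code{filterObjectsByMask} keeps an object iff its centre pixel lies
#' inside the ROI.
#'
#' @param img matrix or h x w x 3 array.
#' @param roi a [RoiMask-class] of matching dimensions.
#' @return \code{applyMask}: the masked image; \code{filterObjectsByMask}: a
#'   logical keep vector.
#' @export
applyMask <- function(img, roi) {
  d <- if (is.matrix(img)) dim(img) else dim(img)[1:2]
  if (!all(d == dim(roi@mask)))
    stop("ROI dimensions do not match the image")
  if (is.matrix(img)) {
    img[!roi@mask] <- 0
  } else {
    for (ch in seq_len(dim(img)[3])) {
      pl <- img[, , ch]; pl[!roi@mask] <- 0; img[, , ch] <- pl
    }
  }
  img
}

#' @rdname applyMask
#' @param objects data.frame with 0-based centre columns \code{x, y}.
#' @export
filterObjectsByMask <- function(objects, roi) {
  if (nrow(objects) == 0) return(logical(0))
  ri <- clamp(round(objects$y) + 1, 1, nrow(roi@mask))
  ci <- clamp(round(objects$x) + 1, 1, ncol(roi@mask))
  roi@mask[cbind(ri, ci)]
}
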