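#' Create a synthetic plate scene description
#'
#' Builds a [SceneSpec-class] from explicit colony and artefact tables. For
#' randomly populated plates matching the validation conditions, see
#' [randomPlateSpec()].
#'
#' @param width,height image size in pixels.
#' @param backgroundLevel mean background grey level (0-255).
#' @param gradientAmplitude amplitude of the smooth bilinear background
#'   gradient in grey levels (0 disables it).
#' @param noiseSigma sd of additive Gaussian noise in grey levels.
#' @param seed integer; fully determines the rendered raster.
#' @param colonies data.frame with columns \code{cx, cy, radius, offset, r, g, b}
#'   (0-based centre, radius in px, signed grey-level offset, colour weights
#'   in [0, 1]); may be empty.
#' @param artefacts data.frame with columns \code{kind, cx, cy, size}; kinds
#'   are \code{bubble} (bright ring, dark interior, size = ring radius),
#'   \code{dish_edge} (dark circular rim, size = radius), \code{crack}
#'   (thin dark polyline, size = length) and \code{dust} (small irregular
#'   high-contrast speck, size = scale); may be empty.
#' @return a validated [SceneSpec-class].
#' @examples
#' sp <- sceneSpec(64, 64, colonies = data.frame(
#'   cx = 32, cy = 32, radius = 8, offset = 80, r = 1, g = 0.9, b = 0.7))
#' sc <- renderScene(sp)
#' dim(sc$image)
#' @export
sceneSpec <- function(width = 640L, height = 640L, backgroundLevel = 175,
                      gradientAmplitude = 8, noiseSigma = 2, seed = 1L,
                      colonies = emptyColonyTable(),
                      artefacts = emptyArtefactTable()) {
  new("SceneSpec", width = as.integer(width), height = as.integer(height),
      backgroundLevel = backgroundLevel,
      gradientAmplitude = gradientAmplitude, noiseSigma = noiseSigma,
      seed = as.integer(seed), colonies = colonies, artefacts = artefacts)
}

#' @rdname sceneSpec
#' @export
emptyColonyTable <- function() {
  data.frame(cx = numeric(), cy = numeric(), radius = numeric(),
             offset = numeric(), r = numeric(), g = numeric(), b = numeric())
}

#' @rdname sceneSpec
#' @export
emptyArtefactTable <- function() {
  data.frame(kind = character(), cx = numeric(), cy = numeric(),
             size = numeric())
}

#' Randomly populated plate scene with known ground truth
#'
#' Emulates a photographed agar plate: a dish rim near the border, colonies of
#' 3-5 px radius at 60-85 grey levels of contrast over a gradually varying
#' background, an optional fraction of colonies fused into pairs and triples
#' (centre distance 1.5 times the mean radius), an optional differently
#' coloured minority sub-population, and bubble / crack / dust artefacts.
#' Single colonies are placed on a jittered grid and clusters by dart
#' throwing, so ground truth counts are exact by construction even on
#' high-load plates.
#'
#' @param nColonies number of colonies (0 for artefact-only plates).
#' @param width,height image size in pixels.
#' @param clusterFraction fraction of colonies belonging to fused pairs or
#'   triples (overlapping discs).
#' @param minorityFraction fraction of colonies drawn with the minority
#'   colour.
#' @param nBubbles,nCracks,nDust artefact counts.
#' @param dishEdge draw the dish rim (radius 0.48 * min(width, height)).
#' @param radiusRange,offsetRange colony radius (px) and contrast (grey
#'   levels) ranges, sampled uniformly.
#' @param majorityColour,minorityColour per-channel colour weights in [0, 1].
#' @param backgroundLevel,gradientAmplitude,noiseSigma as in [sceneSpec()].
#' @param seed integer seed; determines placement and rendering.
#' @return a [SceneSpec-class].
#' @seealso [renderScene()]
#' @export
randomPlateSpec <- function(nColonies, width = 640L, height = 640L,
                            clusterFraction = 0.2, minorityFraction = 0,
                            nBubbles = 0L, nCracks = 0L, nDust = 0L,
                            dishEdge = TRUE,
                            radiusRange = c(3, 5), offsetRange = c(60, 85),
                            majorityColour = c(1, 0.93, 0.68),
                            minorityColour = c(1, 0.35, 0.30),
                            backgroundLevel = 175, gradientAmplitude = 8,
                            noiseSigma = 2, seed = 1L) {
  m <- min(width, height)
  dishR <- 0.48 * m
  placeR <- dishR - 37          # colonies stay inside the -25 px auto-ROI
  cx0 <- (width - 1) / 2
  cy0 <- (height - 1) / 2

  withSeed(seed, {
    nClustCol <- round(clusterFraction * nColonies)
    nTriple <- nClustCol %/% 6
    nPair <- max(0, (nClustCol - 3 * nTriple) %/% 2)
    nClustCol <- 3 * nTriple + 2 * nPair
    nSingle <- nColonies - nClustCol
    nClust <- nTriple + nPair

    # clusters by dart throwing with a generous exclusion radius
    clustC <- matrix(numeric(), ncol = 2)
    tries <- 0
    while (nrow(clustC) < nClust && tries < 8000 + 100 * nClust) {
      tries <- tries + 1
      rr <- sqrt(runif(1)) * (placeR - 12)
      th <- runif(1, 0, 2 * pi)
      p <- c(cx0 + rr * cos(th), cy0 + rr * sin(th))
      if (nrow(clustC) == 0 ||
          min(sqrt((clustC[, 1] - p[1])^2 + (clustC[, 2] - p[2])^2)) >= 26)
        clustC <- rbind(clustC, p)
    }
    if (nrow(clustC) < nClust)
      stop("could not place ", nClust, " colony clusters on the plate")

    # singles on a jittered grid, avoiding cluster territory
    sp <- 11
    g1 <- seq(-floor(placeR / sp) * sp, floor(placeR / sp) * sp, by = sp)
    grid <- expand.grid(x = g1, y = g1)
    grid <- grid[sqrt(grid$x^2 + grid$y^2) <= placeR - 2, , drop = FALSE]
    gx <- grid$x + cx0
    gy <- grid$y + cy0
    if (nClust > 0) {
      ok <- rep(TRUE, length(gx))
      for (i in seq_len(nrow(clustC)))
        ok <- ok & (sqrt((gx - clustC[i, 1])^2 + (gy - clustC[i, 2])^2) >= 19)
      gx <- gx[ok]; gy <- gy[ok]
    }
    if (length(gx) < nSingle)
      stop("plate too small for ", nColonies, " colonies (",
           length(gx), " free sites)")
    pick <- sample.int(length(gx), nSingle)
    sx <- gx[pick] + runif(nSingle, -0.5, 0.5)
    sy <- gy[pick] + runif(nSingle, -0.5, 0.5)

    cxs <- sx; cys <- sy
    radius <- runif(nSingle, radiusRange[1], radiusRange[2])
    if (nClust > 0) {
      sizes <- c(rep(2, nPair), rep(3, nTriple))
      for (i in seq_len(nClust)) {
        k <- sizes[i]
        rads <- runif(k, radiusRange[1], radiusRange[2])
        d <- 1.5 * mean(rads)
        phi <- runif(1, 0, 2 * pi)
        if (k == 2) {
          off <- rbind(c(cos(phi), sin(phi)), -c(cos(phi), sin(phi))) * d / 2
        } else {
          # collinear chain: a compact triangular clover is morphologically
          # indistinguishable from one large round colony
          u <- c(cos(phi), sin(phi))
          off <- rbind(-d * u, c(0, 0), d * u)
        }
        cxs <- c(cxs, clustC[i, 1] + off[, 1])
        cys <- c(cys, clustC[i, 2] + off[, 2])
        radius <- c(radius, rads)
      }
    }
    n <- length(cxs)
    offset <- runif(n, offsetRange[1], offsetRange[2])
    colw <- matrix(rep(majorityColour, each = n), ncol = 3)
    nMin <- round(minorityFraction * n)
    if (nMin > 0) {
      iMin <- sample.int(n, nMin)
      colw[iMin, ] <- matrix(rep(minorityColour, each = nMin), ncol = 3)
    }
    colonies <- data.frame(cx = cxs, cy = cys, radius = radius,
                           offset = offset, r = colw[, 1], g = colw[, 2],
                           b = colw[, 3])

    arte <- emptyArtefactTable()
    if (dishEdge)
      arte <- rbind(arte, data.frame(kind = "dish_edge", cx = cx0, cy = cy0,
                                     size = dishR))
    # extent = spatial footprint radius used for collision checks (a crack of
    # length s wanders around its start point but needs no huge exclusion)
    placeArtefact <- function(nA, sizeFun, extentFun, minColonyDist) {
      out <- NULL
      tries <- 0
      while ((is.null(out) || nrow(out) < nA) && tries < 4000) {
        tries <- tries + 1
        s <- sizeFun()
        e <- extentFun(s)
        rr <- sqrt(runif(1)) * max(placeR - e - 4, 10)
        th <- runif(1, 0, 2 * pi)
        p <- c(cx0 + rr * cos(th), cy0 + rr * sin(th))
        dcol <- if (n > 0)
          min(sqrt((cxs - p[1])^2 + (cys - p[2])^2)) else Inf
        dart <- if (is.null(out)) Inf else
          min(sqrt((out$cx - p[1])^2 + (out$cy - p[2])^2) - out$ext - e)
        if (dcol >= minColonyDist + e && dart >= 6)
          out <- rbind(out, data.frame(cx = p[1], cy = p[2], size = s,
                                       ext = e))
      }
      if (is.null(out) || nrow(out) < nA)
        stop("could not place artefacts on the plate")
      out[c("cx", "cy", "size")]
    }
    if (nBubbles > 0) {
      b <- placeArtefact(nBubbles, function() runif(1, 6, 14), identity, 12)
      arte <- rbind(arte, data.frame(kind = "bubble", b))
    }
    if (nCracks > 0) {
      # cracks run behind opaque colonies (the renderer skips covered
      # pixels), so they need no colony exclusion zone
      ck <- placeArtefact(nCracks, function() 150, function(s) s / 3, -Inf)
      arte <- rbind(arte, data.frame(kind = "crack", ck))
    }
    if (nDust > 0) {
      d <- placeArtefact(nDust, function() runif(1, 1, 2),
                         function(s) s + 2, 12)
      arte <- rbind(arte, data.frame(kind = "dust", d))
    }
    sceneSpec(width = width, height = height,
              backgroundLevel = backgroundLevel,
              gradientAmplitude = gradientAmplitude,
              noiseSigma = noiseSigma, seed = seed,
              colonies = colonies, artefacts = arte)
  })
}

# soft-edged (1 px area-coverage rim) radial coverage helper
discCoverage <- function(d, radius) clamp(radius + 0.5 - d, 0, 1)

ringCoverage <- function(d, radius, halfWidth) {
  clamp(halfWidth + 0.5 - abs(d - radius), 0, 1)
}

#' Render a synthetic plate scene
#'
#' Renders the scene to an 8-bit-scale colour raster plus a ground-truth
#' table. Colonies are anti-aliased filled discs added to a smoothly varying
#' background; overlapping discs fuse naturally into merged clusters. Bubbles
#' are bright rings with a darkened interior, the dish edge is a
#' high-contrast rim, cracks are thin dark polylines and dust specks are
#' small irregular high-contrast dots. The spec seed fully determines the
#' output (bit-identical regeneration).
#'
#' @param spec a [SceneSpec-class].
#' @return list with \code{image} (height x width x 3 array, values 0-255)
#'   and \code{truth} (data.frame \code{id, kind, cx, cy, radius, r, g, b};
#'   one row per colony and per artefact).
#' @export
renderScene <- function(spec) {
  validObject(spec)
  w <- spec@width; h <- spec@height
  if (w <= 0 || h <= 0) stop("scene dimensions must be positive")
  if (nrow(spec@colonies) && any(spec@colonies$radius < 1))
    stop("colony radius must be >= 1")

  withSeed(spec@seed, {
    # smooth background: bilinear interpolation of random corner offsets
    corners <- if (spec@gradientAmplitude > 0)
      runif(4, -spec@gradientAmplitude, spec@gradientAmplitude) else rep(0, 4)
    u <- if (w > 1) (seq_len(w) - 1) / (w - 1) else 0
    v <- if (h > 1) (seq_len(h) - 1) / (h - 1) else 0
    base <- spec@backgroundLevel +
      outer(1 - v, 1 - u) * corners[1] + outer(1 - v, u) * corners[2] +
      outer(v, 1 - u) * corners[3] + outer(v, u) * corners[4]
    img <- array(base, dim = c(h, w, 3))

    addDisc <- function(cx, cy, radius, amp3) {
      j0 <- max(1, floor(cx - radius) ); j1 <- min(w, ceiling(cx + radius) + 2)
      i0 <- max(1, floor(cy - radius) ); i1 <- min(h, ceiling(cy + radius) + 2)
      if (j0 > j1 || i0 > i1) return(invisible())
      xs <- (j0:j1) - 1; ys <- (i0:i1) - 1
      d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
      cov <- discCoverage(d, radius)
      for (ch in 1:3)
        img[i0:i1, j0:j1, ch] <<- img[i0:i1, j0:j1, ch] + cov * amp3[ch]
    }
    addRing <- function(cx, cy, radius, halfWidth, amp) {
      ext <- radius + halfWidth + 2
      j0 <- max(1, floor(cx - ext)); j1 <- min(w, ceiling(cx + ext))
      i0 <- max(1, floor(cy - ext)); i1 <- min(h, ceiling(cy + ext))
      if (j0 > j1 || i0 > i1) return(invisible())
      xs <- (j0:j1) - 1; ys <- (i0:i1) - 1
      d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
      cov <- ringCoverage(d, radius, halfWidth)
      for (ch in 1:3)
        img[i0:i1, j0:j1, ch] <<- img[i0:i1, j0:j1, ch] + cov * amp
    }

    co <- spec@colonies
    for (i in seq_len(nrow(co)))
      addDisc(co$cx[i], co$cy[i], co$radius[i],
              co$offset[i] * c(co$r[i], co$g[i], co$b[i]))

    ar <- spec@artefacts
    for (i in seq_len(nrow(ar))) {
      kind <- ar$kind[i]; ax <- ar$cx[i]; ay <- ar$cy[i]; s <- ar$size[i]
      if (kind == "bubble") {
        addRing(ax, ay, s, 1, 60)                       # bright 2 px ring
        addDisc(ax, ay, s - 1.5, rep(-20, 3))           # darker interior
      } else if (kind == "dish_edge") {
        addRing(ax, ay, s, 1.5, -60)                    # dark 3 px rim
      } else if (kind == "crack") {
        nSeg <- max(3L, round(s / 12))
        ang <- runif(1, 0, 2 * pi)
        px <- ax; py <- ay
        for (seg in seq_len(nSeg)) {
          ang <- ang + runif(1, -0.5, 0.5)
          len <- s / nSeg
          ts <- seq(0, len, by = 0.4)
          qx <- px + ts * cos(ang); qy <- py + ts * sin(ang)
          for (k in seq_along(qx)) {
            jj <- round(qx[k]) + 1; ii <- round(qy[k]) + 1
            if (ii < 1 || ii > h || jj < 1 || jj > w) next
            # the agar crack is hidden where an opaque colony sits on top
            if (nrow(co) && any((co$cx - (jj - 1))^2 + (co$cy - (ii - 1))^2 <=
                                  (co$radius + 1.5)^2)) next
            img[ii, jj, ] <- base[ii, jj] - 50
          }
          px <- px + len * cos(ang); py <- py + len * sin(ang)
        }
      } else if (kind == "dust") {
        nPix <- 3L + sample.int(5L, 1)
        sign <- sample(c(-1, 1), 1)
        px <- round(ax); py <- round(ay)
        for (k in seq_len(nPix)) {
          jj <- px + 1; ii <- py + 1
          if (ii >= 1 && ii <= h && jj >= 1 && jj <= w)
            img[ii, jj, ] <- base[ii, jj] + sign * 80
          step <- sample.int(4L, 1)
          px <- px + c(1, -1, 0, 0)[step]
          py <- py + c(0, 0, 1, -1)[step]
        }
      }
    }

    if (spec@noiseSigma > 0)
      img <- img + array(rnorm(h * w * 3, 0, spec@noiseSigma), dim = c(h, w, 3))
    img <- clamp(img, 0, 255)

    truth <- data.frame(
      id = seq_len(nrow(co) + nrow(ar)),
      kind = c(rep("colony", nrow(co)), as.character(ar$kind)),
      cx = c(co$cx, ar$cx), cy = c(co$cy, ar$cy),
      radius = c(co$radius, ar$size),
      r = c(co$r, rep(NA_real_, nrow(ar))),
      g = c(co$g, rep(NA_real_, nrow(ar))),
      b = c(co$b, rep(NA_real_, nrow(ar))))
    list(image = img, truth = truth)
  })
}

#' Translate an image, padding with the local background estimate
#'
#' Shifts the raster content by an integer number of pixels. Positive
#' \code{dx} moves content towards larger x (right), positive \code{dy}
#' towards larger y (down): a disc centred at (100, 100) shifted by
#' (25, 25) ends up at (125, 125). Vacated margins are filled with the
#' median of the nearest content edge row / column, per channel.
#'
#' @param img matrix or h x w x 3 array.
#' @param dx,dy integer shift in pixels; absolute values must be smaller than
#'   the image dimensions.
#' @return image of identical dimensions.
#' @export
translateImage <- function(img, dx, dy) {
  dx <- as.integer(round(dx)); dy <- as.integer(round(dy))
  shiftChan <- function(ch) {
    h <- nrow(ch); w <- ncol(ch)
    if (abs(dx) >= w || abs(dy) >= h)
      stop("shift exceeds image dimensions")
    out <- ch
    if (dx > 0) {
      out[, (dx + 1):w] <- ch[, 1:(w - dx)]
      out[, 1:dx] <- median(ch[, 1])
    } else if (dx < 0) {
      out[, 1:(w + dx)] <- ch[, (1 - dx):w]
      out[, (w + dx + 1):w] <- median(ch[, w])
    }
    mid <- out
    if (dy > 0) {
      out[(dy + 1):h, ] <- mid[1:(h - dy), ]
      out[1:dy, ] <- median(ch[1, ])
    } else if (dy < 0) {
      out[1:(h + dy), ] <- mid[(1 - dy):h, ]
      out[(h + dy + 1):h, ] <- median(ch[h, ])
    }
    out
  }
  if (is.matrix(img)) return(shiftChan(img))
  for (ch in seq_len(dim(img)[3])) img[, , ch] <- shiftChan(img[, , ch])
  img
}

#' Write a rendered scene to disk
#'
#' Writes the image as PNG and the ground truth as a CSV with header
#' \code{id,kind,cx,cy,radius,r,g,b}.
#'
#' @param scene result of [renderScene()].
#' @param dir output directory (created if missing).
#' @param name basename for the two files.
#' @return invisibly, the two file paths.
#' @export
writeScene <- function(scene, dir, name = "plate") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  imgPath <- file.path(dir, paste0(name, ".png"))
  csvPath <- file.path(dir, paste0(name, "_truth.csv"))
  EBImage::writeImage(imageToEBImage(scene$image), imgPath)
  write.csv(scene$truth, csvPath, row.names = FALSE)
  invisible(c(image = imgPath, truth = csvPath))
}

# h x w x ch (row = y) array on the 0-255 scale -> EBImage Image (x, y order)
imageToEBImage <- function(img) {
  if (is.matrix(img)) return(EBImage::Image(t(img) / 255))
  EBImage::Image(aperm(img, c(2, 1, 3)) / 255, colormode = "Color")
}
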