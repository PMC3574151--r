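#' Read a plate image from disk
#'
#' Reads PNG/TIFF/JPEG into an h x w x 3 array on the 0-255 scale. Grey
#' images are replicated to three channels; an alpha channel is dropped.
#'
#' @param path image file.
#' @return h x w x 3 numeric array.
#' @export
readPlateImage <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)  # (x, y[, ch]) in [0, 1]
  if (length(dim(a)) == 2) {
    arr <- array(rep(t(a), 3L), dim = c(ncol(a), nrow(a), 3L))
    dimnames(arr) <- NULL
    return(arr * 255)
  }
  aperm(a[, , 1:3, drop = FALSE], c(2, 1, 3)) * 255
}

#' Count colonies in one image
#'
#' Runs the full pipeline: region of interest (automatic dish detection by
#' default), preprocessing, score-map accumulation over the threshold sweep,
#' score-map thresholding, particle-filter classification with watershed
#' splitting of merged colonies, colour measurement and the optional colour
#' postfilter.
#'
#' @param img h x w x 3 array (0-255), grey matrix, or a file path.
#' @param params a [ColonyParams-class].
#' @param roi optional [RoiMask-class]; overrides \code{autoPetri}.
#' @param autoPetri detect the dish and use it as ROI (default TRUE).
#' @param margin signed dish-radius margin in pixels (default -25).
#' @param imageName identifier used in the output tables.
#' @return a [ColonySet-class].
#' @examples
#' sc <- renderScene(randomPlateSpec(25, seed = 7))
#' cs <- countColonies(sc$image, imageName = "demo")
#' colonyCount(cs)
#' @export
countColonies <- function(img, params = colonyParams(), roi = NULL,
                          autoPetri = TRUE, margin = -25,
                          imageName = "image") {
  if (is.character(img)) img <- readPlateImage(img)
  img <- asImageArray(img)
  dims <- dim(img)[1:2]
  p <- resolveParams(params, dims)

  if (is.null(roi)) {
    roi <- if (autoPetri) detectDish(luminance(img), margin = margin)
           else fullFrameMask(dims)
  }
  if (!all(dim(roi@mask) == dims))
    stop("ROI dimensions do not match the image")

  emptySet <- function() {
    rec <- data.frame(x = numeric(), y = numeric(), median_r = numeric(),
                      median_g = numeric(), median_b = numeric(),
                      area = numeric(), perimeter = numeric(),
                      cluster_size = integer(), excluded = logical(),
                      reason = character())
    new("ColonySet", records = rec, imageName = imageName,
        maskSurface = maskSurface(roi), roiOrigin = roi@origin,
        params = params)
  }

  # constant channels on a featureless plate are handled via the empty path
  pre <- withCallingHandlers(
    preprocessImage(img, params, roi),
    warning = function(w) {
      if (grepl("constant channel", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  grey <- pre$grey
  if (max(grey) - min(grey) < 3) return(emptySet())

  sm <- buildScoreMap(grey, params)
  mask <- thresholdScoreMap(sm, if (params@autoScore) "auto"
                                else params@scoreThreshold)
  if (!any(mask)) return(emptySet())

  sv <- splitAndValidate(mask, params, rMax = p$rMax)
  obj <- sv$objects
  if (nrow(obj) == 0) return(emptySet())

  # corrected median colour intensities over each object's pixels
  med <- matrix(NA_real_, nrow(obj), 3)
  lm <- sv$labelMap
  pix <- which(lm > 0)
  if (length(pix)) {
    lv <- lm[pix]
    for (ch in 1:3) {
      v <- pre$corrected[, , ch][pix]
      agg <- vapply(split(v, lv), median, numeric(1))
      med[as.integer(names(agg)), ch] <- agg
    }
  }
  obj$median_r <- med[, 1]; obj$median_g <- med[, 2]; obj$median_b <- med[, 3]

  obj <- obj[filterObjectsByMask(obj, roi), , drop = FALSE]
  if (nrow(obj) == 0) return(emptySet())

  obj$excluded <- FALSE
  obj$reason <- ""
  if (params@colourCutoff > 0 && nrow(obj) >= 3) {
    model <- tryCatch(fitColourModel(obj), warning = function(w) NULL)
    if (!is.null(model) && model@usable) {
      ex <- filterByLikelihood(obj, model, params@colourCutoff)
      obj$excluded <- ex
      obj$reason <- ifelse(ex, "colour", "")
    }
  }
  rec <- obj[, c("x", "y", "median_r", "median_g", "median_b", "area",
                 "perimeter", "cluster_size", "excluded", "reason")]
  rownames(rec) <- NULL
  new("ColonySet", records = rec, imageName = imageName,
      maskSurface = maskSurface(roi), roiOrigin = roi@origin,
      params = params)
}

#' Process a batch of images
#'
#' Runs [countColonies()] on every image. Per-image failures are logged as a
#' warning and yield a summary row with \code{count = NA}; the batch never
#' aborts.
#'
#' @param images character vector of file paths, or a named list of in-memory
#'   images (arrays / matrices).
#' @param params a [ColonyParams-class].
#' @param autoPetri,margin,roi as in [countColonies()].
#' @return list with \code{summary} (data.frame \code{image, count,
#'   mask_surface}), \code{detailed} (one row per object) and \code{results}
#'   (the [ColonySet-class] objects).
#' @export
runBatch <- function(images, params = colonyParams(), autoPetri = TRUE,
                     margin = -25, roi = NULL) {
  nm <- if (is.character(images)) basename(images)
        else if (!is.null(names(images))) names(images)
        else paste0("image", seq_along(images))
  results <- vector("list", length(images))
  summary <- data.frame(image = character(), count = numeric(),
                        mask_surface = numeric())
  detailed <- NULL
  for (i in seq_along(images)) {
    res <- tryCatch(
      countColonies(if (is.character(images)) images[i] else images[[i]],
                    params = params, roi = roi, autoPetri = autoPetri,
                    margin = margin, imageName = nm[i]),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("image '", nm[i], "' failed: ", conditionMessage(res))
      summary <- rbind(summary, data.frame(image = nm[i], count = NA_real_,
                                           mask_surface = NA_real_))
      next
    }
    results[[i]] <- res
    summary <- rbind(summary, data.frame(image = nm[i],
                                         count = colonyCount(res),
                                         mask_surface = maskSurface(res)))
    rec <- records(res)
    if (nrow(rec)) {
      det <- data.frame(image = nm[i], mask_surface = maskSurface(res),
                        x = rec$x, y = rec$y,
                        median_r = rec$median_r, median_g = rec$median_g,
                        median_b = rec$median_b, area = rec$area,
                        perimeter = rec$perimeter,
                        cluster_size = rec$cluster_size,
                        excluded = rec$excluded)
      detailed <- rbind(detailed, det)
    }
  }
  if (is.null(detailed))
    detailed <- data.frame(image = character(), mask_surface = numeric(),
                           x = numeric(), y = numeric(),
                           median_r = numeric(), median_g = numeric(),
                           median_b = numeric(), area = numeric(),
                           perimeter = numeric(), cluster_size = integer(),
                           excluded = logical())
  rownames(summary) <- rownames(detailed) <- NULL
  list(summary = summary, detailed = detailed, results = results)
}

#' Write the summary and detailed output tables
#'
#' CSV headers are exactly \code{image,count,mask_surface} (summary; one row
#' per image, count = accepted objects) and
#' \code{image,mask_surface,x,y,median_r,median_g,median_b,area,perimeter,cluster_size,excluded}
#' (detailed; one row per object, excluded objects flagged rather than
#' dropped).
#'
#' @param batch result of [runBatch()].
#' @param summaryPath,detailedPath output file paths (either may be NULL).
#' @return invisibly, the batch.
#' @export
writeOutputs <- function(batch, summaryPath = NULL, detailedPath = NULL) {
  if (!is.null(summaryPath))
    write.csv(batch$summary, summaryPath, row.names = FALSE, quote = FALSE)
  if (!is.null(detailedPath))
    write.csv(batch$detailed, detailedPath, row.names = FALSE, quote = FALSE)
  invisible(batch)
}
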