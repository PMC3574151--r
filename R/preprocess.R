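#' Estimate the smooth background of one channel
#'
#' Local median filter background estimation. The default radius in the
#' pipeline is tied to the maximal expected object radius so that no colony
#' can be absorbed into the background estimate.
#'
#' @param channel numeric matrix, intensities on the 0-255 scale.
#' @param radius median filter radius in pixels (kernel is
#'   \code{2 * radius + 1} square).
#' @return background matrix of identical dimensions.
#' @export
estimateBackground <- function(channel, radius = 20) {
  k <- 2 * radius + 1
  if (min(dim(channel)) < k)
    stop("image must be at least ", k, " x ", k,
         " for a median kernel of radius ", radius)
  bg <- EBImage::medianFilter(channel / 255, radius)
  as.matrix(EBImage::imageData(bg)) * 255
}

# Laplacian-of-Gaussian kernel (sum-normalised to zero)
logKernel <- function(sigma = 2, size = 9L) {
  half <- (size - 1) / 2
  x <- outer(rep(1, size), seq(-half, half))
  y <- t(x)
  r2 <- x^2 + y^2
  k <- (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  k - mean(k)
}

#' Contrast-enhance a foreground channel
#'
#' Subtracts the positive part of the Laplacian of Gaussian of the foreground
#' from itself (clipping at zero). This sharpens object boundaries and
#' suppresses thin, high-curvature structures such as cracks and dish-edge
#' fragments; broad flat plateaus (colony interiors) are left essentially
#' unchanged. The output never exceeds the input.
#'
#' @param foreground background-subtracted channel (non-negative matrix).
#' @param sigma Gaussian sigma of the LoG, in pixels.
#' @param size LoG kernel size (odd).
#' @return enhanced channel, same dimensions, non-negative.
#' @export
enhanceChannel <- function(foreground, sigma = 2, size = 9L) {
  k <- logKernel(sigma, size)
  lg <- EBImage::filter2(foreground, k, boundary = "replicate")
  lg <- as.matrix(EBImage::imageData(lg))
  pmax(foreground - pmax(lg, 0), 0)
}

#' Normalise and merge enhanced channels into one grey image
#'
#' Each channel is normalised to [0, 255] over the region of interest, then
#' the channels are averaged (a constant channel contributes zeros, with a
#' warning). The normalisation gain is \code{255 / max(range, minContrast)}:
#' plain min-max when the channel has at least \code{minContrast} grey
#' levels of dynamic range, but capped below that so a featureless plate
#' does not have its sensor noise stretched into a fake signal. Pixels
#' outside the ROI are set to 0. A single matrix input takes the grey-scale
#' convenience path (normalisation only).
#'
#' @param channels list of 1 or 3 same-sized matrices.
#' @param roi optional logical matrix; normalisation statistics are computed
#'   over ROI pixels only.
#' @param minContrast minimal assumed dynamic range in grey levels.
#' @return matrix with values in [0, 255].
#' @export
mergeChannels <- function(channels, roi = NULL, minContrast = 60) {
  if (is.matrix(channels)) channels <- list(channels)
  d <- dim(channels[[1]])
  sel <- if (is.null(roi)) TRUE else roi
  norm1 <- function(ch) {
    v <- ch[sel]
    mn <- min(v); mx <- max(v)
    if (mx <= mn) {
      warning("constant channel contributes zeros to the merged image")
      return(array(0, d))
    }
    clamp((ch - mn) / max(mx - mn, minContrast) * 255, 0, 255)
  }
  out <- Reduce(`+`, lapply(channels, norm1)) / length(channels)
  if (!is.null(roi)) out[!roi] <- 0
  out
}

#' Preprocess a colour image into a contrast-enhanced grey image
#'
#' Per channel: the background is estimated with a local median filter and
#' subtracted; the deviation in the colony-contrast direction is kept
#' (polarity is auto-detected from the dominant deviation sign unless fixed);
#' the positive Laplacian of Gaussian is subtracted from the foreground; the
#' three channels are min-max normalised over the ROI and averaged.
#'
#' @param img h x w x 3 array (0-255) or grey matrix.
#' @param params a [ColonyParams-class]; uses \code{medianRadius},
#'   \code{logSigma}, \code{logKernel} and \code{polarity}.
#' @param roi optional [RoiMask-class]; pixels outside it are ignored in the
#'   normalisation and zeroed in the output.
#' @return list with \code{grey} (merged image, 0-255), \code{corrected}
#'   (h x w x 3 array of polarity-corrected background-subtracted channels,
#'   used for colour measurements), \code{polarity} (+1 bright, -1 dark) and
#'   \code{background} (h x w x 3 array).
#' @export
preprocessImage <- function(img, params = colonyParams(), roi = NULL) {
  img <- asImageArray(img)
  p <- resolveParams(params, dim(img)[1:2])
  maskM <- if (is.null(roi)) NULL else roi@mask
  if (!is.null(maskM) && !all(dim(maskM) == dim(img)[1:2]))
    stop("ROI dimensions do not match the image")

  bg <- array(0, dim(img))
  signed <- array(0, dim(img))
  for (ch in 1:3) {
    bg[, , ch] <- estimateBackground(img[, , ch], p$medianRadius)
    signed[, , ch] <- img[, , ch] - bg[, , ch]
  }
  sel <- if (is.null(maskM)) array(TRUE, dim(img)[1:2]) else maskM
  pol <- switch(params@polarity,
    bright = 1,
    dark = -1,
    auto = {
      selA <- array(sel, dim(img))
      dev <- signed[selA]
      if (sum(pmax(dev, 0)) >= sum(pmax(-dev, 0))) 1 else -1
    })
  corrected <- pmax(pol * signed, 0)
  enhanced <- lapply(1:3, function(ch)
    enhanceChannel(corrected[, , ch], p$logSigma, p$logKernel))
  grey <- mergeChannels(enhanced, roi = maskM,
                        minContrast = params@minContrast)
  list(grey = grey, corrected = corrected, polarity = pol, background = bg)
}
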