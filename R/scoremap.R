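#' Build the score map by recursive thresholding
#'
#' First pass of the detection: the grey image is binarised at every
#' threshold value; at each threshold, every 8-connected component passing
#' the reject-stage particle filter ([screenRegion()]) has all its pixels
#' incremented in a per-pixel vote map. The map records how recurrently each
#' pixel belonged to a morphologically valid circular region over the
#' threshold sweep. Artefacts (rings, elongated edges) rarely pass at any
#' threshold and stay near zero.
#'
#' @param grey matrix, 0-255 (from [preprocessImage()]; 0 outside the ROI).
#' @param params a [ColonyParams-class] (screening constants and stride).
#' @param thresholds strictly increasing values in (0, 255); the default is
#'   every integer grey level from \code{min + 1} to \code{max - 1} of the
#'   image (over positive pixels), stepped by \code{params@thresholdStride}.
#' @return a [ScoreMap-class].
#' @export
buildScoreMap <- function(grey, params = colonyParams(), thresholds = NULL) {
  if (is.null(thresholds)) {
    lo <- floor(min(grey))
    hi <- ceiling(max(grey))
    if (hi - lo < 2) {
      thresholds <- numeric()
    } else {
      thresholds <- seq(lo + 1, hi - 1, by = params@thresholdStride)
      thresholds <- thresholds[thresholds > 0 & thresholds < 255]
    }
  }
  if (!length(thresholds))
    stop("empty threshold list: the image has no dynamic range to sweep")
  if (any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing")
  if (any(thresholds <= 0 | thresholds >= 255))
    stop("thresholds must lie in (0, 255)")
  v <- .scoremapCpp(grey, as.numeric(thresholds), params@rMin,
                    params@screenAspectMax, params@screenHollowMax)
  new("ScoreMap", votes = v, thresholds = as.numeric(thresholds))
}

#' Threshold a score map into a detection mask
#'
#' Pixels with at least \code{scoreThreshold} votes survive. With
#' \code{scoreThreshold = "auto"} the cut is chosen by Otsu's method on the
#' histogram of non-zero votes (an implementation-defined rule; the
#' recommended fixed settings are 12 votes for high-definition images and 7
#' for webcam images).
#'
#' @param sm a [ScoreMap-class].
#' @param scoreThreshold positive integer \code{<= nThresholds(sm)}, or
#'   \code{"auto"}.
#' @return logical matrix (the detection mask). Raising the threshold never
#'   grows the mask.
#' @export
thresholdScoreMap <- function(sm, scoreThreshold = 12) {
  if (identical(scoreThreshold, "auto")) {
    scoreThreshold <- otsuThreshold(as.vector(sm@votes))
  } else {
    if (!is.numeric(scoreThreshold) || scoreThreshold <= 0)
      stop("scoreThreshold must be a positive number or 'auto'")
    if (scoreThreshold > nThresholds(sm))
      stop("scoreThreshold exceeds the number of thresholds (",
           nThresholds(sm), "): unsatisfiable")
  }
  sm@votes >= scoreThreshold
}
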