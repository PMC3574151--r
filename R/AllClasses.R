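#' Synthetic plate scene description
#'
#' Describes a plate-like scene: image geometry, smooth background, a table of
#' colonies (centre, radius, contrast offset, colour weights) and a table of
#' artefacts (bubbles, dish edge, cracks, dust). The \code{seed} fully
#' determines the rendered raster, so a scene regenerates bit-identically.
#'
#' @slot width,height image size in pixels.
#' @slot backgroundLevel mean background grey level (0-255).
#' @slot gradientAmplitude amplitude (grey levels) of the smooth bilinear
#'   background gradient.
#' @slot noiseSigma standard deviation of additive Gaussian pixel noise.
#' @slot seed integer seed controlling gradient, artefact geometry and noise.
#' @slot colonies data.frame with columns \code{cx, cy, radius, offset, r, g, b}:
#'   centre (0-based pixel coordinates, x = column, y = row), disc radius in
#'   pixels, signed intensity offset, and per-channel colour weights in [0, 1].
#' @slot artefacts data.frame with columns \code{kind, cx, cy, size} where
#'   kind is one of \code{bubble}, \code{dish_edge}, \code{crack}, \code{dust}.
#'
#' @seealso [sceneSpec()], [renderScene()], [randomPlateSpec()]
#' @export
setClass("SceneSpec",
  representation(
    width = "integer", height = "integer",
    backgroundLevel = "numeric", gradientAmplitude = "numeric",
    noiseSigma = "numeric", seed = "integer",
    colonies = "data.frame", artefacts = "data.frame"
  )
)

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (object@width < 1L || object@height < 1L)
    msg <- c(msg, "width and height must be positive")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  co <- object@colonies
  if (nrow(co)) {
    need <- c("cx", "cy", "radius", "offset", "r", "g", "b")
    if (!all(need %in% names(co)))
      msg <- c(msg, paste("colonies needs columns:", paste(need, collapse = ", ")))
    else {
      if (any(co$radius < 1)) msg <- c(msg, "colony radius must be >= 1 px")
      if (any(co$cx < 0 | co$cx > object@width - 1 |
              co$cy < 0 | co$cy > object@height - 1))
        msg <- c(msg, "colony centres must lie inside the image")
    }
  }
  ar <- object@artefacts
  if (nrow(ar)) {
    if (!all(c("kind", "cx", "cy", "size") %in% names(ar)))
      msg <- c(msg, "artefacts needs columns: kind, cx, cy, size")
    else if (!all(ar$kind %in% c("bubble", "dish_edge", "crack", "dust")))
      msg <- c(msg, "unknown artefact kind")
  }
  if (length(msg)) msg else TRUE
})

#' Processing parameters for colony detection
#'
#' Holds every tunable constant of the pipeline: object radius range,
#' preprocessing settings, score-map threshold and the named constants of the
#' morphological particle filter and the constrained watershed. Constants of
#' the particle-filter decision cascade are implementation-chosen defaults,
#' calibrated so that the synthetic artefact suite (bubbles, cracks, dish
#' edges, dust, blank plates) yields no false accepts while clean discs in
#' \code{[rMin, rMax]} are accepted.
#'
#' @slot rMin minimal object radius in pixels (reject stage).
#' @slot rMax maximal object radius in pixels; \code{NA} derives it from the
#'   image as \code{min(width, height) / 10}.
#' @slot medianRadius radius of the local median background filter; \code{NA}
#'   uses \code{min(rMax, 20)} so the largest expected colony cannot be
#'   absorbed into the background estimate.
#' @slot logSigma,logKernel sigma (px) and kernel size of the Laplacian of
#'   Gaussian used for contrast enhancement.
#' @slot polarity \code{"auto"}, \code{"bright"} or \code{"dark"}: whether
#'   colonies are brighter or darker than the background; auto picks the
#'   dominant deviation direction.
#' @slot thresholdStride step between successive binarisation thresholds
#'   (1 = every integer grey level).
#' @slot scoreThreshold score-map threshold (votes); \code{autoScore = TRUE}
#'   replaces it by an Otsu cut on the non-zero vote histogram.
#' @slot autoScore logical, see above.
#' @slot minContrast minimal assumed channel dynamic range for normalisation
#'   (grey levels); caps the gain on featureless plates.
#' @slot screenAspectMax,screenHollowMax reject-stage bounds on aspect ratio
#'   and hollowness.
#' @slot singleCircMin,singleConvMin,singleAspectMax,smallRadiusFactor
#'   single-object evidence: high circularity, or high convexity with low
#'   aspect ratio, or equivalent radius below
#'   \code{smallRadiusFactor * rMin}.
#' @slot confirmConvMin,confirmAspectMax single-object confirmation bounds
#'   (applied together with \code{equiv_radius <= rMax}).
#' @slot multiHollowMax,multiAspectMax,multiConvMin cluster (multiple-object)
#'   bounds; clusters must additionally have area >= 2 * pi * rMin^2.
#' @slot kappaArea,kappaDist watershed growth limits: a region may not exceed
#'   \code{kappaArea * pi * peak^2} pixels nor claim pixels farther than
#'   \code{kappaDist * peak} (chamfer metric) from its marker.
#' @slot markerNmsDist local maxima closer than this (chamfer metric) to a
#'   higher maximum are suppressed.
#' @slot colourCutoff quantile cutoff of the colour postfilter in [0, 1);
#'   0 disables the filter.
#'
#' @seealso [colonyParams()], [countColonies()]
#' @export
setClass("ColonyParams",
  representation(
    rMin = "numeric", rMax = "numeric", medianRadius = "numeric",
    logSigma = "numeric", logKernel = "integer", polarity = "character",
    thresholdStride = "integer", scoreThreshold = "numeric",
    autoScore = "logical", minContrast = "numeric",
    screenAspectMax = "numeric", screenHollowMax = "numeric",
    singleCircMin = "numeric", singleConvMin = "numeric",
    singleAspectMax = "numeric", smallRadiusFactor = "numeric",
    confirmConvMin = "numeric", confirmAspectMax = "numeric",
    multiHollowMax = "numeric", multiAspectMax = "numeric",
    multiConvMin = "numeric",
    kappaArea = "numeric", kappaDist = "numeric", markerNmsDist = "numeric",
    colourCutoff = "numeric"
  )
)

setValidity("ColonyParams", function(object) {
  msg <- character()
  if (object@rMin <= 0) msg <- c(msg, "rMin must be > 0")
  if (!is.na(object@rMax) && object@rMax <= object@rMin)
    msg <- c(msg, "rMax must exceed rMin")
  if (!object@polarity %in% c("auto", "bright", "dark"))
    msg <- c(msg, "polarity must be auto, bright or dark")
  if (object@thresholdStride < 1L) msg <- c(msg, "thresholdStride must be >= 1")
  if (!object@autoScore && object@scoreThreshold < 1)
    msg <- c(msg, "scoreThreshold must be >= 1")
  if (object@kappaArea <= 0 || object@kappaDist <= 0)
    msg <- c(msg, "kappaArea and kappaDist must be positive")
  if (object@colourCutoff < 0 || object@colourCutoff >= 1)
    msg <- c(msg, "colourCutoff must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Per-pixel vote map accumulated over binarisation thresholds
#'
#' @slot votes integer matrix; votes[p] counts the thresholds at which pixel p
#'   belonged to a component passing the reject-stage particle filter.
#' @slot thresholds the threshold values iterated.
#' @export
setClass("ScoreMap",
  representation(votes = "matrix", thresholds = "numeric")
)

setValidity("ScoreMap", function(object) {
  v <- object@votes
  if (any(v < 0) || any(v > length(object@thresholds)))
    "votes must lie in [0, n_thresholds]"
  else TRUE
})

#' Region-of-interest mask
#'
#' @slot mask logical matrix, TRUE inside the region of interest.
#' @slot origin one of \code{"manual"}, \code{"auto_petri"},
#'   \code{"full_frame"}.
#' @slot centre,radius fitted dish centre (x, y; 0-based) and radius after the
#'   margin was applied; NA unless origin is \code{auto_petri}.
#' @export
setClass("RoiMask",
  representation(mask = "matrix", origin = "character",
                 centre = "numeric", radius = "numeric")
)

setValidity("RoiMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  if (sum(object@mask) < 1) return("mask surface must be positive")
  if (!object@origin %in% c("manual", "auto_petri", "full_frame"))
    return("origin must be manual, auto_petri or full_frame")
  TRUE
})

#' Detected colonies of one image
#'
#' @slot records data.frame with one row per accepted object: centre
#'   \code{x, y} (0-based pixels), corrected median colour intensities
#'   \code{median_r, median_g, median_b}, \code{area}, \code{perimeter},
#'   \code{cluster_size} (objects sharing the same original cluster) and the
#'   colour-filter \code{excluded} flag with its \code{reason}.
#' @slot imageName image identifier used in outputs.
#' @slot maskSurface number of pixels in the region of interest.
#' @slot roiOrigin origin of the ROI mask used.
#' @slot params the \code{ColonyParams} the image was processed with.
#' @seealso [countColonies()], [colonyCount()]
#' @export
setClass("ColonySet",
  representation(records = "data.frame", imageName = "character",
                 maskSurface = "numeric", roiOrigin = "character",
                 params = "ColonyParams")
)

#' Normal colour model of non-split objects
#'
#' Per-channel normal model of relative colour intensity (channel medians
#' normalised by their sum), fitted on objects with \code{cluster_size == 1}
#' only, since unsplit objects are less often false positives.
#'
#' @slot mean,sd per-channel mean and standard deviation (sd floored at
#'   \code{eps}).
#' @slot nFit number of objects used in the fit.
#' @slot usable FALSE when fewer than 3 non-split objects were available; the
#'   filter then passes everything.
#' @export
setClass("ColourModel",
  representation(mean = "numeric", sd = "numeric", nFit = "integer",
                 usable = "logical")
)
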