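#' Construct processing parameters
#'
#' All pipeline constants with their defaults. The defaults of the particle
#' filter cascade are calibrated on the synthetic validation suite: they
#' accept clean discs with radii in \code{[rMin, rMax]} and reject rings
#' (bubbles), elongated fragments (cracks, dish edges) and noise blobs.
#'
#' @param rMin,rMax minimal / maximal object radius in pixels; \code{rMax =
#'   NA} derives \code{min(width, height) / 10} from the image.
#' @param medianRadius background median filter radius; \code{NA} uses
#'   \code{min(rMax, 20)}.
#' @param logSigma,logKernel Laplacian-of-Gaussian sigma (px) and kernel
#'   size.
#' @param polarity \code{"auto"}, \code{"bright"} or \code{"dark"}.
#' @param thresholdStride stride of the threshold sweep (1 = exhaustive, the
#'   default; larger trades fidelity for speed).
#' @param scoreThreshold score-map cut in votes (default 12, the
#'   high-definition setting; use 7 for low-definition webcam images).
#' @param autoScore if TRUE, ignore \code{scoreThreshold} and use an Otsu cut
#'   of the non-zero vote histogram (implementation-defined rule).
#' @param minContrast minimal channel dynamic range (grey levels) assumed by
#'   the normalisation: the per-channel gain is \code{255 / max(range,
#'   minContrast)}, so a featureless plate does not have its sensor noise
#'   amplified into the threshold sweep.
#' @param screenAspectMax,screenHollowMax reject-stage bounds.
#' @param singleCircMin,singleConvMin,singleAspectMax,smallRadiusFactor
#'   single-object evidence constants.
#' @param confirmConvMin,confirmAspectMax single-object confirmation bounds.
#' @param multiHollowMax,multiAspectMax,multiConvMin cluster bounds.
#' @param kappaArea,kappaDist watershed area / marker-distance limit factors.
#' @param markerNmsDist marker non-maximum suppression distance (chamfer).
#' @param colourCutoff colour-filter quantile cutoff in [0, 1); 0 = off.
#' @return a validated [ColonyParams-class].
#' @examples
#' p <- colonyParams(rMin = 3, scoreThreshold = 7)
#' p@rMin
#' @export
colonyParams <- function(rMin = 2, rMax = NA_real_, medianRadius = NA_real_,
                         logSigma = 2, logKernel = 9L, polarity = "auto",
                         thresholdStride = 1L, scoreThreshold = 12,
                         autoScore = FALSE, minContrast = 60,
                         screenAspectMax = 3.5, screenHollowMax = 0.15,
                         singleCircMin = 0.95, singleConvMin = 0.92,
                         singleAspectMax = 1.3, smallRadiusFactor = 1.2,
                         confirmConvMin = 0.85, confirmAspectMax = 2.2,
                         multiHollowMax = 0.2, multiAspectMax = 6,
                         multiConvMin = 0.5,
                         kappaArea = 1.3, kappaDist = 1.5, markerNmsDist = 2,
                         colourCutoff = 0) {
  new("ColonyParams", rMin = rMin, rMax = rMax, medianRadius = medianRadius,
      logSigma = logSigma, logKernel = as.integer(logKernel),
      polarity = polarity, thresholdStride = as.integer(thresholdStride),
      scoreThreshold = scoreThreshold, autoScore = autoScore,
      minContrast = minContrast,
      screenAspectMax = screenAspectMax, screenHollowMax = screenHollowMax,
      singleCircMin = singleCircMin, singleConvMin = singleConvMin,
      singleAspectMax = singleAspectMax, smallRadiusFactor = smallRadiusFactor,
      confirmConvMin = confirmConvMin, confirmAspectMax = confirmAspectMax,
      multiHollowMax = multiHollowMax, multiAspectMax = multiAspectMax,
      multiConvMin = multiConvMin,
      kappaArea = kappaArea, kappaDist = kappaDist,
      markerNmsDist = markerNmsDist, colourCutoff = colourCutoff)
}

# fill the NA (image-derived) parameters for a given image size
resolveParams <- function(params, dims) {
  rMax <- if (is.na(params@rMax)) min(dims) / 10 else params@rMax
  medianRadius <- if (is.na(params@medianRadius))
    max(3, round(min(rMax, 20))) else params@medianRadius
  list(rMax = rMax, medianRadius = medianRadius,
       logSigma = params@logSigma, logKernel = params@logKernel)
}

#' Print all parameter defaults
#'
#' Dumps every constant of a [ColonyParams-class] object, one per line
#' (\code{name = value}), mirroring a configuration file section.
#'
#' @param params a [ColonyParams-class].
#' @return invisibly, a named list of the values.
#' @export
dumpParams <- function(params = colonyParams()) {
  sl <- methods::slotNames(params)
  vals <- lapply(sl, function(s) methods::slot(params, s))
  names(vals) <- sl
  for (s in sl) cat(s, "=", format(vals[[s]]), "\n")
  invisible(vals)
}

#' Read parameters from a YAML configuration file
#'
#' Keys mirror the arguments of [colonyParams()]; unknown keys are an error.
#'
#' @param path YAML file path.
#' @return a [ColonyParams-class].
#' @export
readParamsYaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read configuration files")
  cfg <- yaml::read_yaml(path)
  known <- names(formals(colonyParams))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(colonyParams, cfg)
}
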