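#' Morphological features of connected components
#'
#' Computes, for every 8-connected component of a binary mask (or every label
#' of a label matrix), the descriptors used by the particle filter:
#' \describe{
#'   \item{area}{pixel count.}
#'   \item{perimeter}{outer-contour arc length (Moore tracing; diagonal steps
#'     weighted \code{sqrt(2)}), which stabilises circularity across radii.}
#'   \item{convex_area, convexity}{convex hull area over pixel corners and
#'     the ratio \code{area / convex_area} in (0, 1].}
#'   \item{aspect_ratio}{major/minor axis ratio of the moment-fitted ellipse
#'     (>= 1; a 1/12 px^2 pixel-extent term regularises thin components).}
#'   \item{hollowness}{enclosed-hole area / (hole area + area); high for
#'     rings such as bubbles, 0 for solid objects.}
#'   \item{equiv_radius}{\code{sqrt(area / pi)}.}
#'   \item{circularity}{\code{4 * pi * area / perimeter^2} (digitisation can
#'     slightly exceed 1).}
#'   \item{cx, cy}{centroid, 0-based pixel coordinates (x = column).}
#' }
#' Components touching the image border are measured like any others.
#'
#' @param x logical matrix (binary mask) or integer label matrix.
#' @return data.frame with one row per component, in label order, plus a
#'   \code{label} column.
#' @examples
#' m <- matrix(FALSE, 32, 32); m[10:20, 10:20] <- TRUE
#' computeRegionFeatures(m)
#' @export
computeRegionFeatures <- function(x) {
  if (is.logical(x)) {
    lab <- .ccLabel8(x)
    nlab <- attr(lab, "nlab")
  } else {
    lab <- x
    storage.mode(lab) <- "integer"
    nlab <- max(0L, max(lab))
  }
  if (nlab == 0L) {
    out <- data.frame(label = integer(), area = numeric(),
                      perimeter = numeric(), convex_area = numeric(),
                      convexity = numeric(), aspect_ratio = numeric(),
                      hollowness = numeric(), equiv_radius = numeric(),
                      circularity = numeric(), cx = numeric(), cy = numeric())
    return(out)
  }
  f <- .regionFeaturesCpp(lab, nlab)
  data.frame(label = seq_len(nlab), f)
}

#' Reject-stage screening of a region
#'
#' A region survives the first (reject) stage of the particle filter only if
#' all of: its equivalent radius is at least \code{rMin}, its aspect ratio is
#' at most \code{screenAspectMax} and its hollowness is at most
#' \code{screenHollowMax}. Anything failing cannot vote into the score map.
#'
#' @param features data.frame from [computeRegionFeatures()].
#' @param params a [ColonyParams-class].
#' @return logical vector, one element per row of \code{features}.
#' @export
screenRegion <- function(features, params = colonyParams()) {
  features$equiv_radius >= params@rMin &
    features$aspect_ratio <= params@screenAspectMax &
    features$hollowness <= params@screenHollowMax
}

#' Classify a screened region as single object, multiple objects, or invalid
#'
#' Applies the second-stage decision cascade to regions that already passed
#' [screenRegion()]. A region is a single-object candidate if at least one
#' single-evidence criterion holds: high circularity
#' (\code{>= singleCircMin}); or high convexity with low aspect ratio; or a
#' small equivalent radius (\code{<= smallRadiusFactor * rMin}). Candidates
#' are confirmed only if all of: \code{equiv_radius <= rMax}, convexity
#' \code{>= confirmConvMin} and aspect ratio \code{<= confirmAspectMax};
#' otherwise they are invalid. Regions without single evidence are multiple
#' objects only if all cluster criteria hold: hollowness
#' \code{<= multiHollowMax}, aspect ratio \code{<= multiAspectMax}, area
#' consistent with at least two objects of radius \code{rMin}
#' (\code{area >= 2 * pi * rMin^2}) and convexity \code{>= multiConvMin};
#' otherwise invalid.
#'
#' @param features data.frame from [computeRegionFeatures()].
#' @param params a [ColonyParams-class]; \code{rMax} must be resolved
#'   (non-NA) or it is derived from nothing here - pass \code{rMax}
#'   explicitly for image-size defaults.
#' @param rMax optional numeric overriding \code{params@rMax} (used when the
#'   maximal radius is derived from the image dimensions).
#' @return character vector with values \code{"INVALID"}, \code{"SINGLE"},
#'   \code{"MULTIPLE"}.
#' @export
classifyRegion <- function(features, params = colonyParams(), rMax = NULL) {
  rMax <- if (!is.null(rMax)) rMax else params@rMax
  if (is.na(rMax))
    stop("rMax is NA: supply rMax or resolved params")
  evidence <- features$circularity >= params@singleCircMin |
    (features$convexity >= params@singleConvMin &
       features$aspect_ratio <= params@singleAspectMax) |
    features$equiv_radius <= params@smallRadiusFactor * params@rMin
  confirmed <- features$equiv_radius <= rMax &
    features$convexity >= params@confirmConvMin &
    features$aspect_ratio <= params@confirmAspectMax
  cluster <- features$hollowness <= params@multiHollowMax &
    features$aspect_ratio <= params@multiAspectMax &
    features$area >= 2 * pi * params@rMin^2 &
    features$convexity >= params@multiConvMin
  ifelse(evidence, ifelse(confirmed, "SINGLE", "INVALID"),
         ifelse(cluster, "MULTIPLE", "INVALID"))
}
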