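#' @name cfuCounter-accessors
#' @title Accessors for cfuCounter classes
#' @param object an object of the documented class.
#' @description Accessor generics: \code{votes} and \code{nThresholds} for
#'   \code{ScoreMap}; \code{maskSurface} and \code{roiOrigin} for
#'   \code{RoiMask} / \code{ColonySet}; \code{records} and \code{colonyCount}
#'   for \code{ColonySet}.
NULL

#' @rdname cfuCounter-accessors
#' @export
setGeneric("votes", function(object) standardGeneric("votes"))

#' @rdname cfuCounter-accessors
#' @export
setGeneric("nThresholds", function(object) standardGeneric("nThresholds"))

#' @rdname cfuCounter-accessors
#' @export
setGeneric("maskSurface", function(object) standardGeneric("maskSurface"))

#' @rdname cfuCounter-accessors
#' @export
setGeneric("roiOrigin", function(object) standardGeneric("roiOrigin"))

#' @rdname cfuCounter-accessors
#' @export
setGeneric("records", function(object) standardGeneric("records"))

#' @rdname cfuCounter-accessors
#' @export
setGeneric("colonyCount", function(object) standardGeneric("colonyCount"))

#' @rdname cfuCounter-accessors
#' @export
setMethod("votes", "ScoreMap", function(object) object@votes)

#' @rdname cfuCounter-accessors
#' @export
setMethod("nThresholds", "ScoreMap", function(object) length(object@thresholds))

#' @rdname cfuCounter-accessors
#' @export
setMethod("maskSurface", "RoiMask", function(object) sum(object@mask))

#' @rdname cfuCounter-accessors
#' @export
setMethod("maskSurface", "ColonySet", function(object) object@maskSurface)

#' @rdname cfuCounter-accessors
#' @export
setMethod("roiOrigin", "RoiMask", function(object) object@origin)

#' @rdname cfuCounter-accessors
#' @export
setMethod("roiOrigin", "ColonySet", function(object) object@roiOrigin)

#' @rdname cfuCounter-accessors
#' @export
setMethod("records", "ColonySet", function(object) object@records)

#' @rdname cfuCounter-accessors
#' @export
setMethod("colonyCount", "ColonySet", function(object) {
  sum(!object@records$excluded)
})

setMethod("show", "SceneSpec", function(object) {
  cat("SceneSpec:", object@width, "x", object@height, "px,",
      nrow(object@colonies), "colonies,",
      nrow(object@artefacts), "artefacts, seed", object@seed, "\n")
})

setMethod("show", "ScoreMap", function(object) {
  cat("ScoreMap:", nrow(object@votes), "x", ncol(object@votes), "px,",
      length(object@thresholds), "thresholds, max votes",
      max(object@votes), "\n")
})

setMethod("show", "RoiMask", function(object) {
  cat("RoiMask (", object@origin, "): surface ", sum(object@mask), " px",
      sep = "")
  if (!anyNA(object@centre))
    cat(", centre (", round(object@centre[1], 1), ", ",
        round(object@centre[2], 1), "), radius ",
        round(object@radius, 1), sep = "")
  cat("\n")
})

setMethod("show", "ColonySet", function(object) {
  n <- sum(!object@records$excluded)
  cat("ColonySet '", object@imageName, "': ", n, " objects",
      sep = "")
  if (any(object@records$excluded))
    cat(" (+", sum(object@records$excluded), " excluded)", sep = "")
  cat(", ROI ", object@roiOrigin, " (", object@maskSurface, " px)\n", sep = "")
})

setMethod("show", "ColourModel", function(object) {
  if (object@usable)
    cat("ColourModel fitted on", object@nFit, "unsplit objects; mean",
        paste(round(object@mean, 3), collapse = "/"), "\n")
  else cat("ColourModel: unusable (<3 unsplit objects); filter passes all\n")
})
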