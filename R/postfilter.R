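# relative colour intensity: per-object channel medians normalised by their
# sum, making the colour model invariant to illumination scale
relativeIntensity <- function(objects) {
  m <- abs(cbind(objects$median_r, objects$median_g, objects$median_b))
  s <- pmax(rowSums(m), 1e-6)
  m / s
}

#' Fit a normal colour model to non-split objects
#'
#' A per-channel normal distribution is fitted to the relative colour
#' intensities (channel medians divided by their sum) of objects that were
#' not split (\code{cluster_size == 1}), since unsplit objects are less
#' often false positives. With fewer than 3 such objects the model is marked
#' unusable and the filter passes everything (with a warning).
#'
#' @param objects data.frame with columns \code{median_r, median_g,
#'   median_b, cluster_size}.
#' @param eps floor applied to the fitted standard deviations.
#' @return a [ColourModel-class].
#' @export
fitColourModel <- function(objects, eps = 0.01) {
  sel <- objects$cluster_size == 1 &
    is.finite(objects$median_r + objects$median_g + objects$median_b)
  n <- sum(sel)
  if (n < 3) {
    warning("fewer than 3 non-split objects: colour filter disabled")
    return(new("ColourModel", mean = rep(NA_real_, 3), sd = rep(NA_real_, 3),
               nFit = as.integer(n), usable = FALSE))
  }
  rel <- relativeIntensity(objects[sel, , drop = FALSE])
  mu <- colMeans(rel)
  sdv <- pmax(apply(rel, 2, sd), eps)
  new("ColourModel", mean = as.numeric(mu), sd = as.numeric(sdv),
      nFit = as.integer(n), usable = TRUE)
}

#' Partition objects by colour likelihood
#'
#' Each object's likelihood under the model is the product over channels of
#' the normal density at its relative intensity. The user cutoff has
#' quantile semantics: an object is excluded when the tail probability of
#' its squared-deviation statistic (chi-squared with 3 degrees of freedom,
#' a monotone transform of the likelihood) falls below \code{cutoff}. A
#' cutoff of 0 excludes nothing; an object at the model mean is never
#' excluded for any cutoff below 1. Raising the cutoff never un-excludes an
#' object. Excluded objects are flagged, not deleted.
#'
#' @param objects data.frame with \code{median_r, median_g, median_b}.
#' @param model a [ColourModel-class].
#' @param cutoff quantile cutoff in [0, 1).
#' @return logical vector: TRUE = excluded.
#' @export
filterByLikelihood <- function(objects, model, cutoff) {
  if (!model@usable || cutoff <= 0 || nrow(objects) == 0)
    return(rep(FALSE, nrow(objects)))
  rel <- relativeIntensity(objects)
  z <- sweep(sweep(rel, 2, model@mean), 2, model@sd, "/")
  pval <- pchisq(rowSums(z^2), df = 3, lower.tail = FALSE)
  pval < cutoff
}
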