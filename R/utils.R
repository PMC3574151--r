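# internal helpers shared across modules

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# luminance used for dish detection (plain channel mean, 0-255)
luminance <- function(img) {
  if (is.matrix(img)) return(img)
  (img[, , 1] + img[, , 2] + img[, , 3]) / 3
}

# coerce grey image / colour array input, checking range conventions
asImageArray <- function(img) {
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("expected a h x w x 3 array or a matrix")
  img[, , 1:3, drop = FALSE]
}

# Otsu threshold on a vector of non-negative integers (used for the automatic
# score-map cut); returns the smallest value t maximising between-class
# variance of the split x < t vs x >= t.
otsuThreshold <- function(x) {
  x <- x[x > 0]
  if (!length(x)) return(1)
  vals <- sort(unique(x))
  if (length(vals) == 1L) return(vals)
  best <- vals[2]; bestVar <- -1
  for (t in vals[-1]) {
    lo <- x[x < t]; hi <- x[x >= t]
    w0 <- length(lo) / length(x); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > bestVar) { bestVar <- v; best <- t }
  }
  best
}

#' Chamfer metric between two grid points
#'
#' Closed-form length of the shortest obstacle-free chamfer path between two
#' pixels, with orthogonal, diagonal and knight-move step weights 1, 1.4 and
#' 2.1969 (5x5 neighbourhood). Used for the watershed marker-distance limit
#' and the marker non-maximum suppression.
#'
#' @param dr,dc row and column displacement (any sign).
#' @return the chamfer path length.
#' @examples
#' chamferPointDistance(0, 3)   # 3 orthogonal steps
#' chamferPointDistance(2, 2)   # 2 diagonal steps = 2.8
#' chamferPointDistance(1, 2)   # one knight move = 2.1969
#' @export
chamferPointDistance <- function(dr, dc) {
  mapply(function(a, b) .chamferPointCpp(a, b), dr, dc)
}

# evaluate a function with a temporary RNG seed, restoring global state
withSeed <- function(seed, expr) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  force(expr)
}
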