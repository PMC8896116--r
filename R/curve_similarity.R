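#' Cosine distance between two coverage curves
#'
#' `1 - sum(u*v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))`. For non-negative
#' curves the result lies in \[0, 1\]. An all-zero vector makes the distance
#' undefined; it is reported as the maximal distance 1 (with a warning), so
#' a reporter curve depleted to zero — the strongest possible silencer
#' signal — is never discarded on a numerical technicality.
#'
#' @param u,v Numeric vectors of equal length (reporter cDNA and input
#'   insert coverage values).
#' @return The cosine distance.
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v)) stop("u and v must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    warning("all-zero curve: cosine distance undefined, reporting 1")
    return(1)
  }
  1 - sum(u * v) / (nu * nv)
}

#' Euclidean distance between two coverage curves
#'
#' @param u,v Numeric vectors of equal length.
#' @return `sqrt(sum((u - v)^2))`.
#' @export
euclidean_distance <- function(u, v) {
  if (length(u) != length(v)) stop("u and v must have equal length")
  sqrt(sum((u - v)^2))
}

#' Pearson correlation between two coverage curves
#'
#' Standard product-moment correlation. A zero-variance curve makes the
#' correlation undefined; it is reported as 0 ("no similarity evidence",
#' with a warning), so constant curves never count as similar.
#'
#' @param u,v Numeric vectors of equal length `>= 2`.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_correlation <- function(u, v) {
  if (length(u) != length(v)) stop("u and v must have equal length")
  if (length(u) < 2) stop("need at least 2 points")
  if (stats::var(u) == 0 || stats::var(v) == 0) {
    warning("zero-variance curve: Pearson correlation undefined, reporting 0")
    return(0)
  }
  cor(u, v)
}

#' Gradient (slope-correlation) similarity between two coverage curves
#'
#' Differentiates each curve — `G(i) = (y[i+1] - y[i]) / (x[i+1] - x[i])` —
#' and returns the Pearson correlation of the two gradient arrays. Invariant
#' to adding a constant to either curve, so it compares local shape, not
#' level.
#'
#' @param x Shared genomic positions (strictly increasing, length `>= 3`).
#' @param y_u,y_v Coverage values of the two curves at `x`.
#' @return Correlation of the gradients, in \[-1, 1\].
#' @export
gradient_similarity <- function(x, y_u, y_v) {
  if (length(x) < 3) stop("need at least 3 points for gradients")
  if (length(y_u) != length(x) || length(y_v) != length(x))
    stop("curves must share the x grid")
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  dx <- diff(x)
  pearson_correlation(diff(y_u) / dx, diff(y_v) / dx)
}

#' Curve similarity index
#'
#' `-log2(distance)`: larger values mean more similar curves. Distance 0
#' (identical curves) maps to `Inf`, optionally capped for plotting.
#'
#' @param distance Cosine distance(s), `> 0` for a finite result.
#' @param cap Optional finite ceiling applied to the result.
#' @return The similarity index, vectorized.
#' @export
similarity_index <- function(distance, cap = Inf) {
  if (any(distance < 0)) stop("distance must be >= 0")
  pmin(-log2(distance), cap)
}

#' Similarity score on the common thresholding scale
#'
#' Maps each metric onto one "higher = more similar" scale in \[0, 1\] (or
#' \[-1, 1\] for the correlations) so that a single threshold applies:
#' cosine `1 - distance`; euclidean `1 / (1 + distance)`; pearson and
#' gradient as-is.
#'
#' @param u,v Coverage curves over the window (reporter, input).
#' @param metric One of `"cosine"`, `"euclidean"`, `"pearson"`,
#'   `"gradient"`.
#' @param x Genomic positions for the gradient metric; defaults to the unit
#'   grid.
#' @return The similarity score.
#' @export
similarity_score <- function(u, v, metric = c("cosine", "euclidean",
                                              "pearson", "gradient"),
                             x = seq_along(u)) {
  metric <- match.arg(metric)
  switch(metric,
         cosine = 1 - cosine_distance(u, v),
         euclidean = 1 / (1 + euclidean_distance(u, v)),
         pearson = pearson_correlation(u, v),
         gradient = gradient_similarity(x, u, v))
}

#' Does a candidate window pass the curve-similarity filter?
#'
#' A window is discarded (returns `FALSE`) when its similarity score
#' exceeds the threshold: silencer windows are expected to have dissimilar
#' reporter and input curves.
#'
#' @inheritParams similarity_score
#' @param threshold Similarity-score threshold (default 0.9).
#' @return `TRUE` to keep the window, `FALSE` to discard it.
#' @export
passes_similarity <- function(u, v, metric = "cosine", threshold = 0.9,
                              x = seq_along(u)) {
  similarity_score(u, v, metric, x) <= threshold
}
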