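# biweight-midcorrelation transform of one vector: the normalized weighted
# deviation a / sqrt(sum(a^2)); bicor(x, y) is then a plain dot product.
# Returns NULL for a constant vector and uses the Pearson transform
# (standardization) when MAD = 0 but the vector is not constant.
bicor_transform <- function(x, maxPOutliers = 0.05) {
  med <- median(x)
  mad_raw <- median(abs(x - med))
  if (mad_raw == 0) {
    s <- sd(x)
    if (s == 0) return(NULL)
    a <- (x - mean(x)) / s       # Pearson fallback
    return(a / sqrt(sum(a^2)))
  }
  u <- (x - med) / (9 * mad_raw)
  if (maxPOutliers < 0.5) {
    ql <- quantile(x, maxPOutliers, names = FALSE)
    qu <- quantile(x, 1 - maxPOutliers, names = FALSE)
    ul <- (ql - med) / (9 * mad_raw)
    uu <- (qu - med) / (9 * mad_raw)
    if (ul < -1) u[u < 0] <- u[u < 0] / abs(ul)
    if (uu > 1) u[u > 0] <- u[u > 0] / uu
  }
  w <- (1 - u^2)^2 * (abs(u) < 1)
  a <- (x - med) * w
  nrm <- sqrt(sum(a^2))
  if (nrm == 0) return(NULL)
  a / nrm
}

#' Biweight midcorrelation
#'
#' Robust correlation with median/MAD-based biweights. `maxPOutliers` caps,
#' on each side of the median separately, the fraction of observations whose
#' weight can be zeroed: when more than that fraction would fall outside the
#' weighting window, the side is rescaled so the cap quantile sits exactly at
#' the window edge. When a vector's MAD is zero the computation falls back to
#' Pearson standardization; a constant vector yields 0.
#'
#' @param x,y Numeric vectors of equal length >= 3 with finite values.
#' @param maxPOutliers Per-side outlier cap in `(0, 0.5]`.
#' @return Correlation in `[-1, 1]`.
#' @export
#' @examples
#' bicor(1:10, (1:10)^2)
bicor <- function(x, y, maxPOutliers = 0.05) {
  assert_that(length(x) == length(y) && length(x) >= 3,
              "need equal lengths >= 3")
  assert_that(all(is.finite(x)) && all(is.finite(y)),
              "values must be finite")
  ax <- bicor_transform(x, maxPOutliers)
  ay <- bicor_transform(y, maxPOutliers)
  if (is.null(ax) || is.null(ay)) return(0)
  min(1, max(-1, sum(ax * ay)))
}

#' Pairwise biweight midcorrelation matrix
#'
#' Computes all pairwise [bicor()] values between the rows of `mat` via the
#' per-vector biweight transform, so the cost is one matrix product.
#'
#' @param mat Numeric matrix (variables in rows, observations in columns).
#' @param maxPOutliers Per-side outlier cap.
#' @return Symmetric correlation matrix with unit diagonal (0 diagonal for
#'   constant rows).
#' @export
bicor_matrix <- function(mat, maxPOutliers = 0.05) {
  mat <- as.matrix(mat)
  tr <- matrix(0, nrow(mat), ncol(mat))
  ok <- logical(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    a <- bicor_transform(mat[i, ], maxPOutliers)
    if (!is.null(a)) {
      tr[i, ] <- a
      ok[i] <- TRUE
    }
  }
  s <- tcrossprod(tr)
  s[!ok, ] <- 0
  s[, !ok] <- 0
  s <- pmin(pmax(s, -1), 1)
  dimnames(s) <- list(rownames(mat), rownames(mat))
  s
}
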