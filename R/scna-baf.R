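#' Filter heterozygous BAF sites on blood-sample evidence
#'
#' Retains exactly the sites whose matched blood sample supports a
#' confidently heterozygous genotype: blood depth >= 8 reads and blood BAF
#' within `[1/3, 2/3]` (bounds inclusive).
#'
#' @param sites Tibble with at least `blood_depth` and `blood_baf`.
#' @return The retained rows, as a tibble.
#' @export
filter_baf_sites <- function(sites) {
  sites <- as_tibble(sites)
  filter(sites, .data$blood_depth >= 8,
         .data$blood_baf >= 1 / 3, .data$blood_baf <= 2 / 3)
}

#' Folded BAF deviation statistics within a segment
#'
#' devBAF is the folded deviation `|BAF - 0.5|` per site; folding is required
#' for the directional Z test and the `M_dev` thresholds of the
#' classification rules to be meaningful. Both tumour and blood vectors are
#' folded with the same convention.
#'
#' @param sites Retained BAF sites (see [filter_baf_sites()]).
#' @param segment One-row data frame (or list) with `chrom`, `start`, `end`.
#' @return List with `tumor_dev`, `blood_dev`, `n` (site count), `M_dev` and
#'   `SD_dev` (mean/SD of tumour devBAF; `NA` with `defined = FALSE` when no
#'   site falls in the segment).
#' @export
compute_devbaf <- function(sites, segment) {
  sel <- sites$chrom == segment$chrom & sites$pos >= segment$start &
    sites$pos <= segment$end
  tumor_dev <- abs(sites$tumor_baf[sel] - 0.5)
  blood_dev <- abs(sites$blood_baf[sel] - 0.5)
  n <- length(tumor_dev)
  list(tumor_dev = tumor_dev, blood_dev = blood_dev, n = n,
       M_dev = if (n > 0) mean(tumor_dev) else NA_real_,
       SD_dev = if (n > 1) sd(tumor_dev) else NA_real_,
       defined = n > 0)
}

ab_scores <- function(z) {
  r <- rank(z)
  pmin(r, length(z) + 1 - r)
}

#' One-sided Ansari-Bradley scale test for allelic imbalance
#'
#' Tests whether the scale (spread) of tumour devBAF exceeds that of blood
#' devBAF. Larger spread pushes observations to extreme ranks, where the
#' Ansari-Bradley scores `min(rank, N + 1 - rank)` are small, so the one-sided
#' p-value is the lower tail of the tumour score sum. The null distribution is
#' computed by exhaustive enumeration of all group assignments (handling ties
#' through midrank scores) when the combined sample size is at most
#' `exact_limit`, and by the normal approximation with tie-corrected variance
#' otherwise. When every score is identical (no scale information) the
#' p-value is 1 by convention.
#'
#' @param tumor_dev,blood_dev Numeric vectors of folded devBAF, length >= 2
#'   each.
#' @param exact_limit Combined-size cutoff for exact enumeration.
#' @return One-sided p-value `P_ABT`.
#' @export
#' @examples
#' ansari_bradley_scale_test(c(0.01, 0.25, 0.26), c(0.10, 0.12, 0.14))
ansari_bradley_scale_test <- function(tumor_dev, blood_dev,
                                      exact_limit = 20) {
  assert_that(length(tumor_dev) >= 2 && length(blood_dev) >= 2,
              "both devBAF vectors need length >= 2")
  n1 <- length(tumor_dev)
  z <- c(tumor_dev, blood_dev)
  N <- length(z)
  a <- ab_scores(z)
  obs <- sum(a[seq_len(n1)])
  if (length(unique(a)) == 1L) return(1)
  if (N <= exact_limit) {
    sums <- combn(N, n1, FUN = function(idx) sum(a[idx]))
    mean(sums <= obs + 1e-9)
  } else {
    e <- n1 * mean(a)
    v <- n1 * (N - n1) / (N - 1) * (mean(a^2) - mean(a)^2)
    if (v <= 0) return(1)
    pnorm((obs - e) / sqrt(v))
  }
}

#' Z test for a directional shift of folded devBAF away from zero
#'
#' `Z = M_dev / SD_dev` referred to the standard normal, two-sided. With
#' `SD_dev = 0` the p-value is 0 when `M_dev > 0` and 1 otherwise
#' (a degenerate but perfectly shifted, respectively unshifted, segment).
#'
#' @param tumor_dev Folded tumour devBAF vector, length >= 2.
#' @return Two-sided p-value `P_dev`.
#' @export
devbaf_z_test <- function(tumor_dev) {
  assert_that(length(tumor_dev) >= 2, "need >= 2 sites for the Z test")
  m <- mean(tumor_dev)
  s <- sd(tumor_dev)
  if (s == 0) return(if (m > 0) 0 else 1)
  2 * pnorm(-abs(m / s))
}
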