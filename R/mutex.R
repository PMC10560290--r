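#' Merge SCNA categories into the event matrix convention
#'
#' Applies the category-merging rules used before mutual-exclusivity testing:
#' whole-chromosome losses of chromosomes 1, 3, 7, 4, 6 and 18 are folded
#' into `1p-LOSS`, `3p-LOSS`, `7p-LOSS`, `4p-LOSS`, `6q-LOSS` and `18q-LOSS`
#' respectively; whole-chromosome CN-LOH is counted together with the
#' corresponding whole-chromosome GAIN (regaining copy neutrality after an
#' initial loss requires a gain); and `22q-LOSS` is only counted when the
#' loss overlaps the *NF2* locus. Unknown categories pass through with a
#' warning.
#'
#' @param events Tibble with `sample`, `category` and, for 22q losses,
#'   `chrom`, `start`, `end` of the underlying event (used for the *NF2*
#'   overlap rule; rows without coordinates are kept).
#' @param nf2_locus List/one-row data frame `chrom`, `start`, `end` of *NF2*
#'   (GRCh37 `chr22:29999545-30094589` by default).
#' @return Binary samples-by-categories matrix (class `matrix`).
#' @export
merge_categories <- function(events,
                             nf2_locus = list(chrom = "chr22",
                                              start = 29999545,
                                              end = 30094589)) {
  events <- as_tibble(events)
  loss_fold <- c("1-LOSS" = "1p-LOSS", "3-LOSS" = "3p-LOSS",
                 "7-LOSS" = "7p-LOSS", "4-LOSS" = "4p-LOSS",
                 "6-LOSS" = "6q-LOSS", "18-LOSS" = "18q-LOSS")
  cat <- events$category
  cat <- ifelse(cat %in% names(loss_fold), loss_fold[cat], cat)
  # whole-chromosome CN-LOH (no arm designation) -> whole-chromosome GAIN
  wc_cnloh <- grepl("^[0-9XY]+-CN-LOH$", cat)
  cat[wc_cnloh] <- sub("CN-LOH$", "GAIN", cat[wc_cnloh])
  events$category <- cat
  is_22q_loss <- events$category == "22q-LOSS"
  if (any(is_22q_loss) && all(c("chrom", "start", "end") %in% names(events))) {
    keep <- !is_22q_loss |
      (!is.na(events$start) &
         events$chrom == nf2_locus$chrom &
         events$start <= nf2_locus$end & events$end >= nf2_locus$start)
    events <- events[keep, , drop = FALSE]
  }
  known <- grepl("^[0-9XY]+[pq]?-(LOSS|GAIN|CN-LOH|GAIN-filtered)$",
                 events$category) |
    !grepl("-", events$category)  # driver-gene labels pass silently
  if (any(!known)) {
    warn(sprintf("unknown categories passed through: %s",
                 paste(unique(events$category[!known]), collapse = ", ")))
  }
  samples <- sort(unique(events$sample))
  cats <- sort(unique(events$category))
  m <- matrix(0L, length(samples), length(cats),
              dimnames = list(samples, cats))
  m[cbind(match(events$sample, samples), match(events$category, cats))] <- 1L
  m
}

#' Fit the per-sample / per-event logistic background model
#'
#' Maximum-entropy background for a binary event matrix:
#' `p_ij = plogis(mu_i + lambda_j)` fitted by coordinate-wise Newton updates
#' (iterative scaling) until every expected row and column sum matches the
#' observed one within `tol`. Degenerate margins (all-zero or all-one rows or
#' columns) are clamped half an event away from the boundary so the logistic
#' parameters stay finite.
#'
#' @param x Binary samples-by-events matrix.
#' @param tol Convergence tolerance on the marginal residuals.
#' @param max_iter Maximum number of full sweeps.
#' @return Object of class `mutex_background`: list with `p` (probability
#'   matrix), `mu`, `lambda`, `iterations`, `residual`.
#' @export
fit_background <- function(x, tol = 1e-6, max_iter = 500) {
  x <- as.matrix(x)
  assert_that(all(x %in% c(0, 1)), "event matrix must be binary")
  n <- nrow(x); m <- ncol(x)
  rs <- pmin(pmax(rowSums(x), 0.5), m - 0.5)
  cs <- pmin(pmax(colSums(x), 0.5), n - 0.5)
  # rescale clamped column sums so both margin totals agree
  cs <- cs * sum(rs) / sum(cs)
  mu <- stats::qlogis(rs / m)
  lambda <- rep(0, m)
  newton <- function(offset, target) {
    # solve sum(plogis(t + offset)) = target for t
    t0 <- 0
    for (it in 1:50) {
      p <- stats::plogis(t0 + offset)
      f <- sum(p) - target
      if (abs(f) < tol / 10) break
      g <- sum(p * (1 - p))
      t0 <- t0 - f / max(g, 1e-12)
    }
    t0
  }
  for (iter in seq_len(max_iter)) {
    for (i in seq_len(n)) mu[i] <- newton(lambda, rs[i])
    for (j in seq_len(m)) lambda[j] <- newton(mu, cs[j])
    p <- stats::plogis(outer(mu, lambda, `+`))
    resid <- max(abs(rowSums(p) - rs), abs(colSums(p) - cs))
    if (resid < tol) {
      out <- list(p = p, mu = mu, lambda = lambda, iterations = iter,
                  residual = resid, x = x)
      dimnames(out$p) <- dimnames(x)
      return(structure(out, class = "mutex_background"))
    }
  }
  abort(sprintf("background fit did not converge; residual = %.3g", resid))
}

#' @export
print.mutex_background <- function(x, ...) {
  cat("<mutex_background> ", nrow(x$p), " samples x ", ncol(x$p),
      " events; residual ", format(x$residual, digits = 3), " after ",
      x$iterations, " sweeps\n", sep = "")
  invisible(x)
}

#' @export
glance.mutex_background <- function(x, ...) {
  tibble(n_samples = nrow(x$p), n_events = ncol(x$p),
         iterations = x$iterations, residual = x$residual)
}

#' @export
tidy.mutex_background <- function(x, ...) {
  bind_rows(
    tibble(term = rownames(x$p) %||% paste0("S", seq_len(nrow(x$p))),
           type = "sample", estimate = x$mu),
    tibble(term = colnames(x$p) %||% paste0("E", seq_len(ncol(x$p))),
           type = "event", estimate = x$lambda)
  )
}

#' Exact Poisson-binomial tail probability
#'
#' Dynamic-programming convolution of independent, non-identically
#' distributed Bernoulli variables; returns `P(X <= k)` (`tail = "lower"`) or
#' `P(X >= k)` (`tail = "upper"`) exactly.
#'
#' @param probs Success probabilities in `[0, 1]`.
#' @param k Integer count, `0 <= k <= length(probs)`.
#' @param tail `"lower"` or `"upper"`.
#' @return Tail probability.
#' @export
#' @examples
#' poisson_binomial_tail(c(0.1, 0.2, 0.3), 0, "lower")  # 0.9 * 0.8 * 0.7
poisson_binomial_tail <- function(probs, k, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  assert_that(all(probs >= 0 & probs <= 1), "probs must lie in [0, 1]")
  assert_that(k >= 0 && k <= length(probs), "k out of range")
  pmf <- c(1)
  for (p in probs) {
    pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  }
  if (tail == "lower") {
    sum(pmf[seq_len(k + 1)])
  } else {
    sum(pmf[seq(k + 1, length(pmf))])
  }
}

#' Pairwise mutual-exclusivity / co-occurrence screen
#'
#' For every pair of event columns, the observed overlap count is compared to
#' its Poisson-binomial null with per-sample success probabilities
#' `p_Ai * p_Bi` from the fitted background: the lower tail tests mutual
#' exclusivity, the upper tail co-occurrence. Benjamini-Hochberg q-values are
#' computed over all pairs; the significant set is `q < fdr`.
#'
#' @param x Binary event matrix.
#' @param model A [fit_background()] fit for `x` (fitted internally when
#'   `NULL`).
#' @param mode `"exclusivity"` or `"cooccurrence"`.
#' @param fdr Significance level on the q-value.
#' @return Tibble of class `mutex_screen`: `event_a`, `event_b`, `observed`,
#'   `expected`, `p_value`, `q_value`, `significant`.
#' @export
test_pairs <- function(x, model = NULL,
                       mode = c("exclusivity", "cooccurrence"),
                       fdr = 0.05) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (is.null(model)) model <- fit_background(x)
  m <- ncol(x)
  cn <- colnames(x) %||% paste0("E", seq_len(m))
  pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  res <- map(seq_len(nrow(pairs)), function(r) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    probs <- model$p[, a] * model$p[, b]
    k <- sum(x[, a] == 1 & x[, b] == 1)
    p <- if (mode == "exclusivity") {
      poisson_binomial_tail(probs, k, "lower")
    } else {
      poisson_binomial_tail(probs, k, "upper")
    }
    tibble(event_a = cn[a], event_b = cn[b], observed = k,
           expected = sum(probs), p_value = p)
  }) |> list_rbind()
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res$significant <- res$q_value < fdr
  stamp(arrange(res, .data$p_value), "mutex_screen")
}

#' @export
tidy.mutex_screen <- function(x, ...) as_tibble(x)

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact two-sided p-value by summing hypergeometric probabilities no larger
#' than that of the observed table (the classical convention). A zero margin
#' gives p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(10, 3, 0, 8), 2))  # 0.001
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  assert_that(all(dim(tab) == c(2, 2)) && all(tab >= 0) &&
                all(tab == round(tab)),
              "need a 2x2 table of non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  fisher.test(tab)$p.value
}
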