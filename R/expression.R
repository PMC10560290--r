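#' Median-of-ratios size-factor normalization
#'
#' The per-gene geometric mean over samples serves as a pseudo-reference;
#' each sample's size factor is the median, over genes with a positive
#' geometric mean in all samples, of the count-to-reference ratio. When no
#' gene is positive in every sample the reference falls back to the genes
#' positive wherever observed, with a warning.
#'
#' @param counts Genes-by-samples count matrix.
#' @return List with `size_factors`, `normalized` (counts divided by
#'   factors) and `log2` (`log2(normalized + 1)`, the working transform for
#'   downstream clustering).
#' @export
size_factor_normalize <- function(counts) {
  counts <- as.matrix(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    warn("no gene positive in all samples; using positive-subset reference")
    log_geo <- apply(counts, 1, function(x) mean(log(x[x > 0])))
    usable <- is.finite(log_geo)
  } else {
    log_geo <- rowMeans(log(counts))
    usable <- all_pos
  }
  sf <- apply(counts, 2, function(x) {
    exp(median((log(x) - log_geo)[usable & x > 0]))
  })
  normalized <- sweep(counts, 2, sf, "/")
  list(size_factors = sf, normalized = normalized,
       log2 = log2(normalized + 1))
}

#' Remove unwanted variation via MDS dimension 1
#'
#' Library-preparation bias dominates the leading dimension of a classical
#' (Torgerson) MDS of Euclidean sample distances on normalized expression;
#' this is regressed out of every gene by simple linear regression, and the
#' residuals are returned. A user-supplied per-sample covariate can replace
#' the automatic MDS dimension. A constant covariate carries no removable
#' variation: the input is returned unchanged with a warning.
#'
#' @param mat Genes-by-samples normalized (log-scale) expression matrix.
#' @param covariate Optional numeric per-sample covariate; `NULL` uses MDS
#'   dimension 1.
#' @return List with `residuals` (same shape as `mat`) and `covariate` (the
#'   vector that was removed).
#' @export
remove_unwanted_variation <- function(mat, covariate = NULL) {
  mat <- as.matrix(mat)
  assert_that(ncol(mat) >= 3, "need at least 3 samples")
  if (is.null(covariate)) {
    covariate <- cmdscale(dist(t(mat)), k = 1)[, 1]
  }
  assert_that(length(covariate) == ncol(mat),
              "covariate must have one value per sample")
  if (sd(covariate) == 0) {
    warn("constant covariate: nothing to remove")
    return(list(residuals = mat, covariate = covariate))
  }
  x <- covariate - mean(covariate)
  beta <- (mat %*% x) / sum(x^2)
  fitted <- beta %*% t(x)
  centered <- mat - rowMeans(mat)
  list(residuals = centered - fitted, covariate = covariate)
}

#' Select high-variability genes for clustering
#'
#' Keeps exactly the autosomal, non-rRNA genes with (a) fewer than 2 samples
#' at zero expression, (b) maximum normalized log2 count strictly between
#' `log2(2)` and the maximum log2 raw count plus 2 (guards against
#' normalization blow-ups on near-empty genes), and (c) residual standard
#' deviation strictly above `sd_threshold`.
#'
#' @param counts Raw count matrix (genes x samples).
#' @param norm_log2 Normalized log2 matrix (same shape).
#' @param residuals Residual matrix from [remove_unwanted_variation()].
#' @param gene_meta Tibble with `gene`, `autosomal`, `rRNA` aligned to rows.
#' @param sd_threshold Strict residual-SD cutoff (default 0.38).
#' @return Character vector of selected gene names.
#' @export
select_variable_genes <- function(counts, norm_log2, residuals, gene_meta,
                                  sd_threshold = 0.38) {
  counts <- as.matrix(counts)
  zeros_ok <- rowSums(counts == 0) < 2
  max_norm <- apply(norm_log2, 1, max)
  max_raw <- apply(log2(counts + 1), 1, max)
  range_ok <- max_norm > log2(2) & max_norm < max_raw + 2
  sd_ok <- apply(residuals, 1, sd) > sd_threshold
  meta_ok <- gene_meta$autosomal & !gene_meta$rRNA
  rownames(counts)[zeros_ok & range_ok & sd_ok & meta_ok]
}

#' Gram-matrix sample similarity
#'
#' Mean-centres each gene, forms sample-by-sample inner products of the
#' residual expression vectors, and rescales the whole matrix so its largest
#' absolute entry is exactly 1.
#'
#' @param residuals Genes-by-samples residual matrix (restricted to the
#'   selected genes).
#' @return Symmetric samples-by-samples similarity matrix with max |entry|
#'   = 1.
#' @export
gram_similarity <- function(residuals) {
  r <- as.matrix(residuals)
  assert_that(ncol(r) >= 2, "need at least 2 samples")
  r <- r - rowMeans(r)
  s <- crossprod(r)
  mx <- max(abs(s))
  assert_that(mx > 0, "all-zero residuals")
  s / mx
}

#' Ng-Jordan-Weiss spectral clustering with eigengap model selection
#'
#' Builds the non-negative affinity (negative similarities clipped to 0,
#' zero diagonal), symmetrically normalizes it, extracts the top-k
#' eigenvectors, row-normalizes them, and assigns memberships with a
#' full-covariance Gaussian mixture on the spectral embedding. When
#' `k = "auto"` the number of clusters is the k in `2..k_max` maximizing the
#' eigengap `lambda_k - lambda_(k+1)`. Zero-degree samples (disconnected
#' from the affinity graph) are assigned singleton clusters.
#'
#' @param similarity Symmetric similarity matrix (e.g. [gram_similarity()]).
#' @param k Integer number of clusters, or `"auto"`.
#' @param k_max Largest k considered by the eigengap search.
#' @param seed Seed for the (rarely needed) k-means fallback.
#' @return Object of class `cluster_solution`: list with `k`, `labels`,
#'   `memberships` (soft assignment matrix), `eigenvalues`, `embedding`,
#'   `similarity`.
#' @export
njw_spectral_cluster <- function(similarity, k = "auto", k_max = 10,
                                 seed = 1) {
  s <- as.matrix(similarity)
  assert_that(isTRUE(all.equal(s, t(s), tolerance = 1e-8)),
              "similarity must be symmetric")
  n <- nrow(s)
  a <- pmax(s, 0)
  diag(a) <- 0
  deg <- rowSums(a)
  isolated <- which(deg == 0)
  keep <- setdiff(seq_len(n), isolated)
  labels <- rep(NA_integer_, n)
  a2 <- a[keep, keep, drop = FALSE]
  d_inv <- 1 / sqrt(rowSums(a2))
  l <- t(a2 * d_inv) * d_inv
  eig <- eigen((l + t(l)) / 2, symmetric = TRUE)
  vals <- eig$values
  if (identical(k, "auto")) {
    k_hi <- min(k_max, length(keep) - 1)
    gaps <- vals[seq_len(k_hi)] - vals[seq_len(k_hi) + 1]
    k <- which.max(replace(gaps, 1, -Inf))
  }
  u <- eig$vectors[, seq_len(k), drop = FALSE]
  nrm <- sqrt(rowSums(u^2))
  u_n <- u / ifelse(nrm > 0, nrm, 1)
  z <- NULL
  fit <- tryCatch(
    mclust::Mclust(u_n, G = k, modelNames = "VVV", verbose = FALSE),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    fit <- tryCatch(
      mclust::Mclust(u_n, G = k, verbose = FALSE),
      error = function(e) NULL
    )
  }
  if (!is.null(fit)) {
    labels[keep] <- fit$classification
    z <- fit$z
  } else {
    labels[keep] <- with_seed(seed, stats::kmeans(u_n, k,
                                                  nstart = 10)$cluster)
  }
  if (length(isolated)) {
    labels[isolated] <- k + seq_along(isolated)
  }
  structure(
    list(k = k, labels = labels, memberships = z, eigenvalues = vals,
         embedding = u_n, similarity = s, isolated = isolated),
    class = "cluster_solution"
  )
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("<cluster_solution> k = ", x$k, "; sizes: ",
      paste(table(x$labels), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
glance.cluster_solution <- function(x, ...) {
  gap <- if (length(x$eigenvalues) > x$k) {
    x$eigenvalues[x$k] - x$eigenvalues[x$k + 1]
  } else NA_real_
  tibble(k = x$k, n_samples = length(x$labels), eigengap = gap,
         n_isolated = length(x$isolated))
}

#' @export
tidy.cluster_solution <- function(x, ...) {
  tibble(sample = rownames(x$similarity) %||%
           paste0("S", seq_along(x$labels)),
         cluster = x$labels)
}

#' @export
autoplot.cluster_solution <- function(object, ...) {
  emb <- object$embedding
  keep <- setdiff(seq_along(object$labels), object$isolated)
  df <- tibble(dim1 = emb[, 1],
               dim2 = if (ncol(emb) > 1) emb[, 2] else 0,
               cluster = factor(object$labels[keep]))
  ggplot(df, aes(.data$dim1, .data$dim2, colour = .data$cluster)) +
    geom_point(size = 2) +
    labs(x = "eigenvector 1", y = "eigenvector 2",
         title = "Spectral embedding") +
    theme_minimal()
}

#' Full expression-clustering pipeline
#'
#' Size-factor normalization, confound removal on MDS dimension 1, variable
#' gene selection, Gram similarity and NJW spectral clustering, chained in
#' the order the stages are meant to run.
#'
#' @param counts Genes-by-samples raw counts.
#' @param gene_meta Gene metadata tibble (`gene`, `autosomal`, `rRNA`).
#' @param covariate Optional known per-sample confound.
#' @param sd_threshold Residual-SD gene-selection cutoff.
#' @param k Cluster count or `"auto"`.
#' @param k_max Eigengap search bound.
#' @return A `cluster_solution` with the selected `genes` attached.
#' @export
cluster_expression <- function(counts, gene_meta = NULL, covariate = NULL,
                               sd_threshold = 0.38, k = "auto", k_max = 10) {
  counts <- as.matrix(counts)
  if (is.null(gene_meta)) {
    gene_meta <- tibble(gene = rownames(counts), autosomal = TRUE,
                        rRNA = FALSE)
  }
  nrm <- size_factor_normalize(counts)
  ruv <- remove_unwanted_variation(nrm$log2, covariate)
  genes <- select_variable_genes(counts, nrm$log2, ruv$residuals, gene_meta,
                                 sd_threshold)
  assert_that(length(genes) >= 2, "fewer than 2 genes pass selection")
  s <- gram_similarity(ruv$residuals[genes, , drop = FALSE])
  dimnames(s) <- list(colnames(counts), colnames(counts))
  sol <- njw_spectral_cluster(s, k = k, k_max = k_max)
  sol$genes <- genes
  sol
}
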