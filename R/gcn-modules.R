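#' Parameters of the co-expression network chain
#'
#' Bundles the tunable constants of the quasi-clique module chain with the
#' defaults used throughout: seed-edge weight threshold `gamma = 0.3`
#' (applied to normalized adjacency weights), density-decay `lambda = 1` and
#' offset `t = 1` of the growth criterion
#' `density >= 1 - 1/(2 * lambda * (|C| + t))`, overlap-merge threshold
#' `beta = 0.6`, pruning cutoffs `kme_min = 0.5` and `kim_min = 0.6` (scaled
#' intramodular connectivity), eigengene-correlation merge threshold 0.8,
#' `maxPOutliers = 0.05` for bicor, and the staged size floors 4/8/10.
#'
#' @param gamma,lambda,t,beta,kme_min,kim_min,merge_bicor,max_p_outliers
#'   See description.
#' @param min_detect,min_merge,min_final Size floors applied after
#'   detection, after eigengene merging and after expansion.
#' @return A `gcn_params` list.
#' @export
gcn_params <- function(gamma = 0.3, lambda = 1, t = 1, beta = 0.6,
                       kme_min = 0.5, kim_min = 0.6, merge_bicor = 0.8,
                       max_p_outliers = 0.05, min_detect = 4, min_merge = 8,
                       min_final = 10) {
  assert_that(gamma > 0 && beta > 0 && beta < 1 && kme_min >= 0 &&
                kim_min >= 0 && merge_bicor > 0,
              "parameter out of range")
  structure(list(gamma = gamma, lambda = lambda, t = t, beta = beta,
                 kme_min = kme_min, kim_min = kim_min,
                 merge_bicor = merge_bicor,
                 max_p_outliers = max_p_outliers, min_detect = min_detect,
                 min_merge = min_merge, min_final = min_final),
            class = "gcn_params")
}

#' Signed-hybrid co-expression adjacency
#'
#' Ranks genes by variance, keeps the `top_n` most variable (restricted to
#' genes with usable identifiers when a `has_ids` flag is supplied), computes
#' pairwise bicor, zeroes negative correlations (signed hybrid) and zeroes
#' the diagonal, so weights live on the correlation scale in `[0, 1]` — the
#' scale on which the seed threshold `gamma` and the quasi-clique density
#' criterion are calibrated. The symmetric degree normalization
#' `D^(-1/2) A D^(-1/2)` is available via `normalize = TRUE` for inspection,
#' but note that it shrinks the internal weights of an m-gene module to about
#' `1/(m - 1)`, putting any non-trivial module below reachable seed/density
#' thresholds; module detection therefore runs on the unnormalized weights.
#' Isolated genes keep their zero rows.
#'
#' @param residuals Genes-by-samples residual expression matrix.
#' @param top_n Number of most-variable genes to keep.
#' @param params A [gcn_params()].
#' @param has_ids Optional logical flag per gene (identifier availability).
#' @param normalize Apply the symmetric degree normalization.
#' @return Adjacency matrix (entries in `[0, 1]`, zero diagonal).
#' @export
build_adjacency <- function(residuals, top_n = 10000,
                            params = gcn_params(), has_ids = NULL,
                            normalize = FALSE) {
  r <- as.matrix(residuals)
  if (!is.null(has_ids)) r <- r[has_ids, , drop = FALSE]
  v <- apply(r, 1, var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(top_n, nrow(r)))]
  r <- r[sort(keep), , drop = FALSE]
  a <- bicor_matrix(r, params$max_p_outliers)
  a[a < 0] <- 0
  diag(a) <- 0
  if (normalize) {
    d <- rowSums(a)
    d_inv <- ifelse(d > 0, 1 / sqrt(d), 0)
    a <- t(a * d_inv) * d_inv
    a <- (a + t(a)) / 2
  }
  a
}

# contribution bound of the quasi-clique growth; tends to 1 as |C| grows
lmqcm_alpha <- function(size, params) {
  1 - 1 / (2 * params$lambda * (size + params$t))
}

# greedy quasi-clique growth from `members` over candidate set `pool`: the
# vertex with maximal average connection to the module joins while the grown
# module retains at least alpha_n(|C|) of the current density — a relative
# criterion, so growth behaves identically on rescaled weights
grow_module <- function(adj, members, pool, params) {
  m <- length(members)
  wsum <- sum(adj[members, members]) / 2
  repeat {
    pool <- setdiff(pool, members)
    if (!length(pool)) break
    conn <- if (m == 1L) {
      adj[pool, members]
    } else {
      colSums(adj[members, pool, drop = FALSE])
    }
    v <- pool[which.max(conn)]  # which.max -> lowest index on ties
    density <- if (m < 2) 1 else wsum / (m * (m - 1) / 2)
    new_density <- (wsum + conn[match(v, pool)]) / ((m + 1) * m / 2)
    if (new_density >= lmqcm_alpha(m, params) * density) {
      members <- c(members, v)
      wsum <- wsum + conn[match(v, pool)]
      m <- m + 1L
    } else {
      break
    }
  }
  sort(members)
}

#' Local-maximal quasi-clique module detection
#'
#' Seeds are local maximal edges — edges at least as heavy as every edge
#' incident to either endpoint — with weight >= `gamma`, processed in
#' descending weight order. A seed is skipped only when both of its endpoints
#' already co-occur in one previously grown module (the corrected discard
#' rule; the uncorrected variant discards a seed whenever each endpoint has
#' been seen in any module, which wrongly kills seeds bridging two different
#' modules). Each surviving seed is grown greedily: the vertex with maximal
#' average connection to the current module joins while that average
#' connection is at least `alpha_n(|C|) = 1 - 1/(2 * lambda * (|C| + t))`
#' times the module's current density — a self-scaling contribution
#' criterion, invariant to rescaling the weights. Modules smaller than
#' `min_detect` are discarded. Modules may overlap.
#'
#' @param adj Normalized adjacency from [build_adjacency()].
#' @param params A [gcn_params()].
#' @return List of integer vectors (gene indices into `adj`), possibly empty
#'   (with a warning when no seed passes `gamma`).
#' @export
lmqcm_detect <- function(adj, params = gcn_params()) {
  n <- nrow(adj)
  rowmax <- apply(adj, 1, max)
  idx <- which(upper.tri(adj) & adj >= params$gamma, arr.ind = TRUE)
  if (nrow(idx)) {
    w <- adj[idx]
    is_seed <- w >= rowmax[idx[, 1]] - 1e-12 & w >= rowmax[idx[, 2]] - 1e-12
    idx <- idx[is_seed, , drop = FALSE]
    w <- w[is_seed]
  }
  if (!nrow(idx)) {
    warn("no local-maximal edge reaches gamma: empty module set")
    return(list())
  }
  ord <- order(-w, idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  modules <- list()
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    if (any(vapply(modules, function(m) i %in% m && j %in% m, logical(1)))) {
      next
    }
    modules[[length(modules) + 1]] <- grow_module(adj, c(i, j), seq_len(n),
                                                  params)
  }
  modules[lengths(modules) >= params$min_detect]
}

#' Module eigengene
#'
#' First principal component over samples of the gene-wise standardized
#' member expression, sign-aligned to correlate positively with the average
#' member expression. Zero-variance genes are dropped from the PCA with a
#' flag.
#'
#' @param expr Genes-by-samples expression matrix.
#' @param genes Member gene indices or names (length >= 2).
#' @return List with `eigengene` (unit-norm per-sample vector),
#'   `var_explained`, `dropped` (zero-variance members).
#' @export
module_eigengene <- function(expr, genes) {
  assert_that(length(genes) >= 2, "module must have >= 2 genes")
  x <- expr[genes, , drop = FALSE]
  sds <- apply(x, 1, sd)
  dropped <- genes[sds == 0]
  x <- x[sds > 0, , drop = FALSE]
  assert_that(nrow(x) >= 1, "all member genes have zero variance")
  z <- (x - rowMeans(x)) / apply(x, 1, sd)
  sv <- svd(z)
  e <- sv$v[, 1]
  avg <- colMeans(z)
  if (sum(e * avg) < 0) e <- -e
  list(eigengene = e, var_explained = sv$d[1]^2 / sum(sv$d^2),
       dropped = dropped)
}

#' Module membership and intramodular connectivity
#'
#' `kME(g)` is the bicor of gene g's expression with the module eigengene;
#' `kIM(g)` the summed adjacency from g to the other members; `scaled kIM`
#' divides by the module maximum.
#'
#' @param expr Genes-by-samples expression matrix.
#' @param adj Adjacency matrix aligned to `expr` rows.
#' @param genes Member gene indices (length >= 2).
#' @param eigengene Module eigengene (computed when `NULL`).
#' @param maxPOutliers Passed to [bicor()].
#' @return Tibble: `gene`, `kME`, `kIM`, `scaled_kIM`.
#' @export
compute_kme_kim <- function(expr, adj, genes, eigengene = NULL,
                            maxPOutliers = 0.05) {
  assert_that(length(genes) >= 2, "singleton module: connectivity undefined")
  if (is.null(eigengene)) eigengene <- module_eigengene(expr, genes)$eigengene
  kme <- vapply(genes, function(g) bicor(expr[g, ], eigengene, maxPOutliers),
                numeric(1))
  sub <- adj[genes, genes, drop = FALSE]
  diag(sub) <- 0
  kim <- rowSums(sub)
  tibble(gene = genes, kME = kme, kIM = kim,
         scaled_kIM = if (max(kim) > 0) kim / max(kim) else 0)
}

#' Prune poorly connected module members
#'
#' Single pass removing genes with `kME < kme_min`, scaled `kIM < kim_min`,
#' or a negative bicor with any other member; module statistics are meant to
#' be recomputed afterwards (the chain does so).
#'
#' @inheritParams compute_kme_kim
#' @param params A [gcn_params()].
#' @return Integer vector of retained genes (may fall below the size floors,
#'   which the caller enforces).
#' @export
prune_module <- function(expr, adj, genes, params = gcn_params()) {
  if (length(genes) < 2) return(genes)
  stats <- compute_kme_kim(expr, adj, genes,
                           maxPOutliers = params$max_p_outliers)
  member_cor <- bicor_matrix(expr[genes, , drop = FALSE],
                             params$max_p_outliers)
  diag(member_cor) <- 1
  neg_any <- apply(member_cor < 0, 1, any)
  keep <- stats$kME >= params$kme_min & stats$scaled_kIM >= params$kim_min &
    !neg_any
  genes[keep]
}

#' Merge modules with highly correlated eigengenes
#'
#' Greedy highest-correlation-first agglomeration: while some module pair has
#' eigengene bicor >= `merge_bicor` (0.8), the most correlated pair is
#' unioned and eigengenes are recomputed. Afterwards each module is pruned
#' and the `min_merge` size floor applied.
#'
#' @param modules List of gene-index vectors.
#' @param expr Genes-by-samples expression.
#' @param adj Adjacency matrix.
#' @param params A [gcn_params()].
#' @return List of merged, pruned gene-index vectors.
#' @export
merge_correlated_modules <- function(modules, expr, adj,
                                     params = gcn_params()) {
  modules <- lapply(modules, sort)
  repeat {
    if (length(modules) < 2) break
    eig <- lapply(modules, function(g) module_eigengene(expr, g)$eigengene)
    best <- c(0, 0); best_cor <- -Inf
    for (i in seq_len(length(modules) - 1)) {
      for (j in seq(i + 1, length(modules))) {
        cc <- bicor(eig[[i]], eig[[j]], params$max_p_outliers)
        if (cc > best_cor) {
          best_cor <- cc; best <- c(i, j)
        }
      }
    }
    if (best_cor < params$merge_bicor) break
    merged <- sort(union(modules[[best[1]]], modules[[best[2]]]))
    modules <- c(modules[-best], list(merged))
  }
  modules <- lapply(modules, function(g) prune_module(expr, adj, g, params))
  modules[lengths(modules) >= params$min_merge]
}

overlap_k <- function(modules) {
  k <- numeric(length(modules))
  for (i in seq_along(modules)) {
    others <- modules[-i]
    if (!length(others)) { k[i] <- 0; next }
    k[i] <- max(vapply(others, function(y) {
      length(intersect(modules[[i]], y)) / length(modules[[i]])
    }, numeric(1)))
  }
  k
}

#' Overlap-based module merging
#'
#' The connectivity-preserving overlap merger: (1) remove modules that are
#' complete subsets of a larger module; (2) order modules so the maximum
#' relative overlap `K(x) = max_y |x intersect y| / |x|` is non-increasing
#' (sorting by ascending size, then descending K); (3) while the head module
#' has `K >= beta`, union it into every arg-max partner and remove it;
#' (4) iterate. Each iteration removes one module, so the procedure
#' terminates.
#'
#' @param modules List of gene-index (or name) vectors.
#' @param beta Overlap threshold in (0, 1); default 0.6.
#' @return List of merged modules.
#' @export
overlap_merge <- function(modules, beta = 0.6) {
  modules <- lapply(modules, sort)
  # step 1: drop complete subsets of a larger (or duplicate, later) module
  drop <- rep(FALSE, length(modules))
  for (i in seq_along(modules)) {
    for (j in seq_along(modules)) {
      if (i == j || drop[j]) next
      sub <- all(modules[[i]] %in% modules[[j]])
      if (sub && (length(modules[[i]]) < length(modules[[j]]) ||
                  (length(modules[[i]]) == length(modules[[j]]) && i > j))) {
        drop[i] <- TRUE
        break
      }
    }
  }
  modules <- modules[!drop]
  repeat {
    if (length(modules) < 2) break
    k <- overlap_k(modules)
    ord <- order(-k, lengths(modules), seq_along(modules))
    modules <- modules[ord]
    k <- k[ord]
    if (k[1] < beta) break
    x1 <- modules[[1]]
    ov <- vapply(modules[-1], function(y) {
      length(intersect(x1, y)) / length(x1)
    }, numeric(1))
    targets <- which(abs(ov - k[1]) < 1e-12) + 1L
    for (tgt in targets) modules[[tgt]] <- sort(union(modules[[tgt]], x1))
    modules <- modules[-1]
  }
  modules
}

#' Expand modules over previously unassigned genes
#'
#' Genes belonging to no module are offered to each module through the same
#' greedy density-bounded growth used at detection (pre-existing members are
#' never removed at this step); eigengenes are then recomputed, modules
#' pruned, correlated modules merged, and the final `min_final` size floor
#' applied.
#'
#' @param modules List of gene-index vectors.
#' @param expr Genes-by-samples expression.
#' @param adj Adjacency matrix.
#' @param params A [gcn_params()].
#' @return Final module list.
#' @export
expand_modules <- function(modules, expr, adj, params = gcn_params()) {
  assigned <- unique(unlist(modules))
  pool <- setdiff(seq_len(nrow(adj)), assigned)
  if (length(pool)) {
    modules <- lapply(modules, function(m) {
      grow_module(adj, m, union(m, pool), params)
    })
  }
  modules <- merge_correlated_modules(modules, expr, adj, params)
  modules[lengths(modules) >= params$min_final]
}

#' Full co-expression module chain
#'
#' Detection, overlap reduction, characterization, pruning, eigengene-based
#' merging and expansion, with the staged size floors 4 / 8 / 10.
#'
#' @param expr Genes-by-samples residual expression matrix.
#' @param params A [gcn_params()].
#' @param top_n Most-variable gene cap for the adjacency.
#' @return Object of class `gcn_result`: list with `modules` (gene-name
#'   list), `eigengenes` (samples x modules matrix), `membership` tibble
#'   (gene, module, kME, kIM, scaled_kIM), `adjacency`, `params`.
#' @export
build_gcn <- function(expr, params = gcn_params(), top_n = 10000) {
  expr <- as.matrix(expr)
  adj <- build_adjacency(expr, top_n = top_n, params = params)
  genes_used <- rownames(adj) %||% as.character(seq_len(nrow(adj)))
  expr_used <- expr[genes_used, , drop = FALSE]
  idx_mods <- lmqcm_detect(adj, params)
  idx_mods <- overlap_merge(idx_mods, params$beta)
  idx_mods <- lapply(idx_mods, function(g) prune_module(expr_used, adj, g,
                                                        params))
  idx_mods <- idx_mods[lengths(idx_mods) >= params$min_detect]
  idx_mods <- merge_correlated_modules(idx_mods, expr_used, adj, params)
  idx_mods <- expand_modules(idx_mods, expr_used, adj, params)
  eig <- vapply(idx_mods, function(g) {
    module_eigengene(expr_used, g)$eigengene
  }, numeric(ncol(expr_used)))
  if (length(idx_mods)) {
    colnames(eig) <- paste0("M", seq_along(idx_mods))
    rownames(eig) <- colnames(expr_used)
  }
  membership <- imap(idx_mods, function(g, mi) {
    st <- compute_kme_kim(expr_used, adj, g,
                          maxPOutliers = params$max_p_outliers)
    mutate(st, module = paste0("M", mi),
           gene = genes_used[.data$gene])
  }) |> list_rbind()
  structure(
    list(modules = lapply(idx_mods, function(g) genes_used[g]),
         eigengenes = eig, membership = membership, adjacency = adj,
         params = params),
    class = "gcn_result"
  )
}

#' @export
print.gcn_result <- function(x, ...) {
  cat("<gcn_result> ", length(x$modules), " modules; sizes: ",
      paste(lengths(x$modules), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.gcn_result <- function(x, ...) as_tibble(x$membership)

#' @export
glance.gcn_result <- function(x, ...) {
  tibble(n_modules = length(x$modules),
         n_genes_assigned = length(unique(unlist(x$modules))),
         median_size = median(lengths(x$modules)))
}

#' Module-trait association by linear regression
#'
#' Regresses each module eigengene on each trait indicator and tests the
#' slope; the Holm correction is applied over the whole family of tests.
#' Constant traits are skipped with a flag.
#'
#' @param eigengenes Samples-by-modules matrix.
#' @param traits Samples-by-traits data frame (binary or numeric columns).
#' @return Tibble: `module`, `trait`, `estimate`, `p_value`, `p_holm`,
#'   `skipped`.
#' @export
module_trait_association <- function(eigengenes, traits) {
  eigengenes <- as.matrix(eigengenes)
  traits <- as.data.frame(traits)
  res <- list()
  for (m in seq_len(ncol(eigengenes))) {
    for (tr in seq_len(ncol(traits))) {
      x <- traits[[tr]]
      if (sd(x) == 0) {
        res[[length(res) + 1]] <- tibble(
          module = colnames(eigengenes)[m] %||% paste0("M", m),
          trait = colnames(traits)[tr], estimate = NA_real_,
          p_value = NA_real_, skipped = TRUE)
        next
      }
      fit <- summary(lm(eigengenes[, m] ~ x))$coefficients
      res[[length(res) + 1]] <- tibble(
        module = colnames(eigengenes)[m] %||% paste0("M", m),
        trait = colnames(traits)[tr], estimate = fit[2, 1],
        p_value = fit[2, 4], skipped = FALSE)
    }
  }
  out <- list_rbind(res)
  out$p_holm <- NA_real_
  tested <- !out$skipped
  out$p_holm[tested] <- p.adjust(out$p_value[tested], method = "holm")
  out
}

#' Hypergeometric over-representation of gene sets in a module
#'
#' Upper-tail hypergeometric test of the overlap between a module and each
#' gene set within a common universe, with Benjamini-Hochberg correction
#' over the per-module family. Empty sets are skipped.
#'
#' @param module Character vector of member genes (subset of `universe`).
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector of all testable genes.
#' @return Tibble: `set`, `overlap`, `set_size`, `p_value`, `q_value`.
#' @export
ora_hypergeometric <- function(module, gene_sets, universe) {
  module <- intersect(module, universe)
  res <- imap(gene_sets, function(genes, nm) {
    genes <- intersect(genes, universe)
    if (!length(genes)) return(NULL)
    k <- length(intersect(module, genes))
    p <- phyper(k - 1, length(genes), length(universe) - length(genes),
                length(module), lower.tail = FALSE)
    tibble(set = nm, overlap = k, set_size = length(genes), p_value = p)
  }) |> list_rbind()
  if (is.null(res) || nrow(res) == 0) {
    return(tibble(set = character(), overlap = integer(),
                  set_size = integer(), p_value = numeric(),
                  q_value = numeric()))
  }
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res
}
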