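test_that("bicor hits exact values and tracks Pearson on clean data", {
  x <- rnorm(20)
  expect_equal(bicor(x, x), 1)
  expect_equal(bicor(x, -x), -1)
  expect_equal(bicor(rep(1, 10), rnorm(10)), 0)  # constant -> 0
  set.seed(51)
  z <- MASS::mvrnorm(1000, c(0, 0),
                     matrix(c(1, 0.6, 0.6, 1), 2))
  expect_lt(abs(bicor(z[, 1], z[, 2]) - cor(z[, 1], z[, 2])), 0.05)
  # robustness: one gross outlier barely moves bicor, unlike Pearson
  xo <- c(rnorm(50), 20); yo <- c(rnorm(50), -20)
  expect_lt(abs(bicor(xo, yo)), 0.3)
  expect_gt(abs(cor(xo, yo)), 0.5)
  # matrix form agrees with pairwise calls
  m <- matrix(rnorm(5 * 30), 5, 30)
  bm <- bicor_matrix(m)
  expect_equal(bm[2, 4], bicor(m[2, ], m[4, ]))
  expect_equal(diag(bm), rep(1, 5))
})

test_that("adjacency is signed-hybrid with zero diagonal", {
  set.seed(52)
  f <- rnorm(30)
  expr <- rbind(g1 = f + rnorm(30, 0, 0.01),
                g2 = f + rnorm(30, 0, 0.01),
                g3 = -f + rnorm(30, 0, 0.01))
  a <- build_adjacency(expr, top_n = 3)
  expect_gt(a["g1", "g2"], 0.95)
  expect_equal(a["g1", "g3"], 0)      # anti-correlated pair zeroed
  expect_equal(diag(a), setNames(rep(0, 3), rownames(expr)))
  # optional degree normalization keeps a regular graph uniform
  an <- build_adjacency(expr, top_n = 3, normalize = TRUE)
  expect_true(all(an >= 0 & an <= 1))
})

make_clique_bed <- function() {
  # two 6-cliques sharing gene 6, against weak background
  a <- matrix(0.05, 12, 12)
  a[1:6, 1:6] <- 0.9
  a[6:11, 6:11] <- 0.85
  a[12, ] <- a[, 12] <- 0.02
  diag(a) <- 0
  (a + t(a)) / 2
}

test_that("lmQCM detects planted cliques; corrected rule keeps shared seeds", {
  a <- matrix(0.05, 20, 20)
  a[1:6, 1:6] <- 0.9
  diag(a) <- 0
  mods <- lmqcm_detect(a, gcn_params(gamma = 0.5))
  expect_equal(length(mods), 1)
  expect_setequal(mods[[1]], 1:6)
  # gamma above the max weight yields no seeds
  expect_warning(none <- lmqcm_detect(a, gcn_params(gamma = 0.95)),
                 "no local-maximal edge")
  expect_equal(length(none), 0)
  # two cliques sharing one gene: both detected, shared gene in both
  a2 <- make_clique_bed()
  mods2 <- lmqcm_detect(a2, gcn_params(gamma = 0.5))
  expect_equal(length(mods2), 2)
  expect_true(all(vapply(mods2, function(m) 6 %in% m, logical(1))))
  expect_setequal(sort(unique(unlist(mods2))), 1:11)
})

test_that("module eigengene aligns with average expression", {
  set.seed(53)
  f <- rnorm(40)
  expr <- rbind(g1 = f, g2 = f, g3 = f)
  e <- module_eigengene(expr, 1:3)
  expect_equal(e$var_explained, 1)
  expect_gt(cor(e$eigengene, f), 0.999)
  # two-gene module with correlation rho: variance explained (1 + rho) / 2
  g4 <- 0.6 * scale(f)[, 1] + sqrt(1 - 0.36) * scale(rnorm(40))[, 1]
  expr2 <- rbind(a = scale(f)[, 1], b = g4)
  rho <- cor(expr2[1, ], expr2[2, ])
  e2 <- module_eigengene(expr2, 1:2)
  expect_equal(e2$var_explained, (1 + rho) / 2, tolerance = 1e-8)
  # sign-flipping the input leaves the aligned eigengene consistent
  e3 <- module_eigengene(-expr, 1:3)
  expect_gt(cor(e3$eigengene, colMeans(-expr)), 0.999)
})

test_that("kME/kIM and pruning follow their thresholds", {
  set.seed(54)
  f <- rnorm(50)
  expr <- rbind(
    g1 = f + rnorm(50, 0, 0.1), g2 = f + rnorm(50, 0, 0.1),
    g3 = f + rnorm(50, 0, 0.1), g4 = f + rnorm(50, 0, 0.1),
    g5 = rnorm(50),                    # unrelated: low kME, low kIM
    g6 = -f + rnorm(50, 0, 0.1)        # negatively correlated member
  )
  adj <- build_adjacency(expr, top_n = 6)
  st <- compute_kme_kim(expr, adj, 1:5)
  expect_gt(min(st$kME[1:4]), 0.9)
  expect_lt(st$kME[5], 0.5)
  expect_equal(max(st$scaled_kIM), 1)
  pruned <- prune_module(expr, adj, 1:5, gcn_params())
  expect_setequal(pruned, 1:4)
  pruned2 <- prune_module(expr, adj, c(1:4, 6), gcn_params())
  expect_false(6 %in% pruned2)
  # a clean clique is untouched and pruning is idempotent there
  expect_setequal(prune_module(expr, adj, 1:4, gcn_params()), 1:4)
  expect_error(compute_kme_kim(expr, adj, 3), "singleton")
})

test_that("eigengene-correlation merging respects the 0.8 boundary", {
  set.seed(55)
  f1 <- rnorm(60); f2 <- rnorm(60)
  mk <- function(f, n, noise) {
    t(vapply(seq_len(n), function(i) f + rnorm(60, 0, noise),
             numeric(60)))
  }
  expr <- rbind(mk(f1, 10, 0.1), mk(f1, 10, 0.1), mk(f2, 10, 0.1))
  rownames(expr) <- paste0("g", 1:30)
  adj <- build_adjacency(expr, top_n = 30)
  merged <- merge_correlated_modules(list(1:10, 11:20, 21:30), expr, adj,
                                     gcn_params())
  expect_equal(length(merged), 2)
  expect_setequal(merged[[which.max(lengths(merged))]], 1:20)
  # independent factors stay separate (eigengene bicor << 0.8)
  merged2 <- merge_correlated_modules(list(1:10, 21:30), expr, adj,
                                      gcn_params())
  expect_equal(length(merged2), 2)
})

test_that("overlap merging implements subset removal and the beta rule", {
  # complete subset removed up front
  m <- overlap_merge(list(1:5, 1:10), beta = 0.6)
  expect_equal(m, list(1:10))
  # |A| = 10 sharing 6 with B: K = 0.6 >= beta -> merged
  a <- 1:10; b <- c(5:10, 20:30)
  m2 <- overlap_merge(list(a, b), beta = 0.6)
  expect_equal(length(m2), 1)
  expect_setequal(m2[[1]], union(a, b))
  # overlap 5 of 10: K = 0.5 < beta -> untouched
  b2 <- c(6:10, 20:30)
  m3 <- overlap_merge(list(a, b2), beta = 0.6)
  expect_equal(length(m3), 2)
  # disjoint modules pass through, independent of input order
  d1 <- list(1:8, 11:18, 21:28)
  expect_setequal(lapply(overlap_merge(d1, 0.6), sort), d1)
  expect_setequal(lapply(overlap_merge(rev(d1), 0.6), sort), d1)
})

test_that("expansion grows modules over unassigned genes only", {
  set.seed(56)
  f <- rnorm(60)
  expr <- t(vapply(1:14, function(i) f + rnorm(60, 0, 0.15), numeric(60)))
  expr <- rbind(expr, t(vapply(1:6, function(i) rnorm(60), numeric(60))))
  rownames(expr) <- paste0("g", 1:20)
  adj <- build_adjacency(expr, top_n = 20)
  start <- list(1:10)   # planted members 11:14 initially unassigned
  out <- expand_modules(start, expr, adj, gcn_params(gamma = 0.5))
  expect_equal(length(out), 1)
  expect_true(all(1:10 %in% out[[1]]))
  expect_true(any(11:14 %in% out[[1]]))
  expect_false(any(15:20 %in% out[[1]]))
})

test_that("full chain recovers planted modules on the benchmark bed", {
  sim <- simulate_gcn_benchmark(9)
  g <- build_gcn(sim$residuals, sim$params, top_n = 400)
  truth <- split(rownames(sim$counts)[!is.na(sim$truth$module)],
                 sim$truth$module[!is.na(sim$truth$module)])
  jac <- module_recovery_jaccard(g$modules, truth)
  expect_gte(mean(jac), 0.8)
  expect_true(all(lengths(g$modules) >= 10))
  expect_equal(nrow(glance(g)), 1)
  expect_true(all(c("gene", "module", "kME") %in% names(tidy(g))))
})

test_that("module-trait association applies Holm over the whole family", {
  set.seed(57)
  eig <- matrix(rnorm(40 * 3), 40, 3,
                dimnames = list(NULL, paste0("M", 1:3)))
  traits <- data.frame(hh = as.numeric(eig[, 2] > 0), flat = 1,
                       noise = rnorm(40))
  res <- module_trait_association(eig, traits)
  expect_true(all(res$skipped[res$trait == "flat"]))
  expect_true(all(res$p_holm >= res$p_value, na.rm = TRUE))
  top <- res[which.min(res$p_holm), ]
  expect_equal(top$module, "M2")
  expect_equal(top$trait, "hh")
  # perfectly matching trait: essentially zero p-value
  traits2 <- data.frame(exact = eig[, 1])
  # lm warns about the essentially perfect fit; that is the point here
  res2 <- suppressWarnings(module_trait_association(eig, traits2))
  expect_lt(res2$p_value[1], 1e-20)
})

test_that("over-representation equals the exact hypergeometric tail", {
  universe <- paste0("g", 1:20)
  module <- paste0("g", 1:5)
  sets <- list(hit = paste0("g", c(1:4, 10)), miss = paste0("g", 15:19))
  res <- ora_hypergeometric(module, sets, universe)
  manual <- sum(dhyper(4:5, 5, 15, 5))
  expect_equal(res$p_value[res$set == "hit"], manual)
  expect_gt(res$p_value[res$set == "miss"], 0.5)
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  # module identical to the set: minimal possible p for those margins
  res2 <- ora_hypergeometric(module, list(self = module), universe)
  expect_equal(res2$p_value, dhyper(5, 5, 15, 5))
})

test_that("GMT reader returns named gene sets", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4"), f)
  sets <- read_gmt(f)
  expect_equal(names(sets), c("setA", "setB"))
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  writeLines("bad\tonlydesc", f)
  expect_error(read_gmt(f), "line 1")
})
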