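#' Canned simulation designs for pipeline validation
#'
#' These helpers freeze the study conditions under which the pipelines are
#' validated, so tests, examples and the acceptance script all exercise the
#' same designs.
#'
#' `simulate_scna_benchmark()` plants 3-5 non-overlapping LOSS / GAIN /
#' CN-LOH events of 8-20 Mb at tumour purity 0.5-0.9 on the default
#' three-chromosome genome, with logCR noise SD 0.12 and 80x/40x
#' tumour/blood depths at 5 heterozygous sites per Mb (>= 40 sites per
#' event).
#'
#' `simulate_cluster_benchmark()` draws 60 samples in 5 planted clusters of
#' 12 over 600 genes: each cluster carries a private 30-gene signature
#' module (+3 log2 in its own cluster, latent-factor loading 0.4), NB
#' dispersion 0.08, and a technical confound (strength 2.5) strong enough to
#' dominate MDS dimension 1 — the regime the clustering pipeline is designed
#' for.
#'
#' `simulate_gcn_benchmark()` plants five co-expression modules of sizes 15,
#' 20, 25, 32 and 40 (loading 0.8) among 400 genes over 60 samples with no
#' cluster structure; the returned `params` carry the seed threshold
#' calibrated for this bed (`gamma = 0.5`, chosen once by examining the
#' module-count curve against gamma, the same calibration the method
#' prescribes).
#'
#' @param seed Integer seed.
#' @return A list; see each description. All three include a `truth`
#'   element.
#' @name benchmarks
NULL

#' @rdname benchmarks
#' @export
simulate_scna_benchmark <- function(seed) {
  spec <- genome_spec()
  slots <- tibble(
    chrom = c("chr1", "chr1", "chr2", "chr2", "chr3"),
    lo = c(5e6, 55e6, 5e6, 40e6, 5e6),
    hi = c(35e6, 85e6, 33e6, 75e6, 40e6)
  )
  events <- with_seed(seed, {
    keep <- runif(nrow(slots)) < 0.8
    if (!any(keep)) keep[1] <- TRUE
    s <- slots[keep, ]
    len <- runif(nrow(s), 8e6, 20e6)
    start <- s$lo + runif(nrow(s)) * pmax(0, s$hi - s$lo - len)
    tibble(chrom = s$chrom, start = round(start),
           end = round(start + len),
           type = sample(c("LOSS", "GAIN", "CN-LOH"), nrow(s),
                         replace = TRUE),
           purity = runif(nrow(s), 0.5, 0.9), extra_copies = 1)
  })
  profile <- simulate_scna_profile(spec, events, noise_sd = 0.12,
                                   tumor_depth = 80, blood_depth = 40,
                                   seed = seed + 1L)
  c(profile, list(events = events))
}

#' @rdname benchmarks
#' @export
simulate_cluster_benchmark <- function(seed) {
  k <- 5
  clusters <- rep(seq_len(k), each = 12)
  modules <- tibble(
    genes = lapply(seq_len(k) - 1, function(i) i * 30 + 1:30),
    loading = rep(0.4, k),
    effects = lapply(seq_len(k), function(i) {
      e <- rep(0, k); e[i] <- 3; e
    })
  )
  simulate_expression(600, length(clusters), clusters, modules,
                      dispersion = 0.08, confound_strength = 2.5,
                      seed = seed)
}

#' @rdname benchmarks
#' @export
simulate_gcn_benchmark <- function(seed) {
  sizes <- c(15, 20, 25, 32, 40)
  gene_sets <- split(seq_len(sum(sizes)), rep(seq_along(sizes), sizes))
  modules <- tibble(genes = unname(gene_sets), loading = 0.8,
                    effects = vector("list", length(sizes)))
  sim <- simulate_expression(400, 60, rep(1, 60), modules,
                             dispersion = 0.08, confound_strength = 0,
                             seed = seed)
  lg <- log2(size_factor_normalize(sim$counts)$normalized + 1)
  sim$residuals <- lg - rowMeans(lg)
  sim$params <- gcn_params(gamma = 0.5)
  sim
}

#' Recovery metrics of classified SCNA segments against planted truth
#'
#' A planted event counts as recovered when more than half of its length is
#' covered by segments carrying the matching final call (`TANDEM_DUP` and
#' chromothripsis loss pieces match `GAIN` and `LOSS` respectively); a
#' called non-neutral segment counts as correct when more than half of its
#' length overlaps planted events of the matching type.
#'
#' @param calls Classified segments ([call_scna()] output).
#' @param truth Truth table from the simulator.
#' @return One-row tibble: `sensitivity`, `precision`, `n_events`,
#'   `n_called`.
#' @export
scna_recovery_metrics <- function(calls, truth) {
  truth <- truth |>
    filter(.data$type != "NEUTRAL") |>
    mutate(expect = dplyr::recode(.data$type, TANDEM_DUP = "GAIN",
                                  CHROMOTHRIPSIS = "LOSS",
                                  .default = .data$type))
  called <- filter(as_tibble(calls),
                   .data$final_call %in% c("LOSS", "GAIN", "CN-LOH"))
  ov <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
  recovered <- vapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    m <- called[called$chrom == tr$chrom & called$final_call == tr$expect, ]
    if (!nrow(m)) return(FALSE)
    sum(ov(m$start, m$end, tr$start, tr$end)) > 0.5 * (tr$end - tr$start + 1)
  }, logical(1))
  correct <- vapply(seq_len(nrow(called)), function(i) {
    cs <- called[i, ]
    m <- truth[truth$chrom == cs$chrom & truth$expect == cs$final_call, ]
    if (!nrow(m)) return(FALSE)
    sum(ov(m$start, m$end, cs$start, cs$end)) > 0.5 * (cs$end - cs$start + 1)
  }, logical(1))
  tibble(sensitivity = if (nrow(truth)) mean(recovered) else NA_real_,
         precision = if (nrow(called)) mean(correct) else NA_real_,
         n_events = nrow(truth), n_called = nrow(called))
}

#' Best-match Jaccard overlap of detected modules against planted modules
#'
#' @param detected List of gene-name vectors (e.g. `gcn_result$modules`).
#' @param truth_modules List of planted gene-name vectors.
#' @return Numeric vector: for each planted module, the best Jaccard overlap
#'   with any detected module (0 when nothing was detected).
#' @export
module_recovery_jaccard <- function(detected, truth_modules) {
  vapply(truth_modules, function(tm) {
    if (!length(detected)) return(0)
    max(vapply(detected, function(d) {
      length(intersect(d, tm)) / length(union(d, tm))
    }, numeric(1)))
  }, numeric(1))
}
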