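#' Simulate a binary samples-by-events matrix with heterogeneous rates
#'
#' Event indicators are drawn independently with per-cell probability
#' `p_ij = sample_rate_i * event_rate_j / mean(sample_rate)`, so the expected
#' column marginal equals the requested event rate while samples differ in
#' overall burden. Planted pairs are post-processed: an `exclusive` pair has
#' its overlap forced to zero (events are moved, preserving both marginals
#' when possible); a `co-occurring` pair has carriers aligned.
#'
#' @param n_samples Number of samples (rows). Below 10 a warning is raised:
#'   downstream tests will be underpowered.
#' @param sample_rates Per-sample relative burden in `[0, 1]`; recycled.
#' @param event_rates Per-event marginal frequency in `[0, 1]`; its length
#'   sets the number of event columns.
#' @param planted Optional tibble of planted pairs with columns `event_a`,
#'   `event_b` (column indices or names) and `mode`
#'   (`"exclusive"`/`"co-occurring"`).
#' @param seed Integer seed.
#' @return List with `matrix` (binary, dimnames set) and `truth` (the planted
#'   pair table, possibly empty).
#' @export
simulate_event_matrix <- function(n_samples, sample_rates = 0.5,
                                  event_rates = rep(0.3, 8),
                                  planted = NULL, seed = 1) {
  assert_that(all(sample_rates >= 0 & sample_rates <= 1) &&
                all(event_rates >= 0 & event_rates <= 1),
              "rates must lie in [0, 1]")
  if (n_samples < 10) warn("n_samples < 10: tests will be underpowered")
  sample_rates <- rep_len(sample_rates, n_samples)
  m <- length(event_rates)
  with_seed(seed, {
    scale <- mean(sample_rates)
    p <- outer(sample_rates, event_rates) / max(scale, .Machine$double.eps)
    p <- pmin(pmax(p, 0), 1)
    x <- matrix(rbinom(n_samples * m, 1, as.vector(p)), n_samples, m)
    dimnames(x) <- list(paste0("S", seq_len(n_samples)),
                        paste0("E", seq_len(m)))
    truth <- tibble(event_a = integer(), event_b = integer(),
                    mode = character())
    if (!is.null(planted) && nrow(planted) > 0) {
      planted <- as_tibble(planted)
      for (r in seq_len(nrow(planted))) {
        a <- planted$event_a[r]; b <- planted$event_b[r]
        if (is.character(a)) a <- match(a, colnames(x))
        if (is.character(b)) b <- match(b, colnames(x))
        assert_that(!is.na(a) && !is.na(b) && a <= m && b <= m,
                    "planted events must exist among columns")
        if (planted$mode[r] == "exclusive") {
          both <- which(x[, a] == 1 & x[, b] == 1)
          for (i in both) {
            x[i, b] <- 0L
            free <- which(x[, a] == 0 & x[, b] == 0)
            if (length(free)) x[sample(free, 1), b] <- 1L
          }
        } else {
          carriers_a <- which(x[, a] == 1)
          x[, b] <- 0L
          k <- min(length(carriers_a),
                   max(1L, round(sum(p[, b]))))
          if (k > 0) x[carriers_a[seq_len(k)], b] <- 1L
        }
      }
      truth <- planted
    }
    list(matrix = x, truth = truth)
  })
}

#' Simulate negative-binomial expression with planted clusters and modules
#'
#' Counts follow `NB(mu, size = 1/dispersion)` with
#' `log2 mu = baseline + loading * factor + effect + confound`. Genes inside a
#' module share a latent per-sample factor; each module may carry a
#' cluster-specific log2 fold effect (the designated module upregulated in one
#' cluster emulates a pathway-activation signature). A per-sample confound
#' (library-preparation bias) loads on all genes, emulating the unwanted
#' variation the clustering stage removes via MDS dimension 1.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param clusters Integer vector of length `n_samples` giving the planted
#'   partition (every cluster must be non-empty).
#' @param modules Tibble with columns `genes` (list-column of gene indices),
#'   `loading` (latent-factor loading, log2 units) and `effects` (list-column:
#'   numeric per-cluster log2 fold effects, or NULL).
#' @param dispersion NB dispersion (1/size).
#' @param confound_strength SD of the per-sample confound on the log2 scale.
#' @param baseline_log2_mean,baseline_log2_sd Per-gene baseline abundance.
#' @param seed Integer seed.
#' @return List with `counts` (genes x samples), `gene_meta` (autosomal/rRNA
#'   flags, all TRUE/FALSE by default), `truth` (clusters, module membership,
#'   confound vector).
#' @export
simulate_expression <- function(n_genes, n_samples, clusters,
                                modules = NULL, dispersion = 0.1,
                                confound_strength = 0, seed = 1,
                                baseline_log2_mean = 5,
                                baseline_log2_sd = 1.5) {
  assert_that(length(clusters) == n_samples,
              "clusters must have one entry per sample")
  k <- length(unique(clusters))
  assert_that(all(tabulate(match(clusters, sort(unique(clusters)))) > 0),
              "empty cluster")
  with_seed(seed, {
    base <- rnorm(n_genes, baseline_log2_mean, baseline_log2_sd)
    log2mu <- matrix(base, n_genes, n_samples)
    confound <- rnorm(n_samples, 0, 1)
    if (confound_strength > 0) {
      gene_load <- rnorm(n_genes, 1, 0.2)
      log2mu <- log2mu + confound_strength * outer(gene_load, confound)
    }
    member <- rep(NA_integer_, n_genes)
    if (!is.null(modules) && nrow(modules) > 0) {
      modules <- as_tibble(modules)
      cl_idx <- match(clusters, sort(unique(clusters)))
      for (mi in seq_len(nrow(modules))) {
        g <- modules$genes[[mi]]
        member[g] <- mi
        factor_s <- rnorm(n_samples)
        log2mu[g, ] <- log2mu[g, ] +
          modules$loading[mi] * matrix(factor_s, length(g), n_samples,
                                       byrow = TRUE)
        eff <- modules$effects[[mi]]
        if (!is.null(eff)) {
          assert_that(length(eff) == k,
                      "module effects must give one value per cluster")
          log2mu[g, ] <- log2mu[g, ] +
            matrix(eff[cl_idx], length(g), n_samples, byrow = TRUE)
        }
      }
    }
    mu <- 2^log2mu
    counts <- matrix(rnbinom(n_genes * n_samples, mu = as.vector(mu),
                             size = 1 / dispersion),
                     n_genes, n_samples)
    dimnames(counts) <- list(paste0("G", seq_len(n_genes)),
                             paste0("S", seq_len(n_samples)))
    gene_meta <- tibble(gene = rownames(counts), autosomal = TRUE,
                        rRNA = FALSE, has_ids = TRUE)
    list(counts = counts, gene_meta = gene_meta,
         truth = list(clusters = clusters, module = member,
                      confound = confound))
  })
}

#' Simulate a ranked enhancer landscape with a planted super-enhancer tail
#'
#' Background stitched-region signals are drawn from a gamma law; a fraction
#' `tail_fraction` of regions receives an additional heavy exponential tail
#' shifted above the background maximum, so the rank-ordered signal curve has
#' the hockey-stick shape the tangent cutoff exploits.
#'
#' @param n_regions Number of stitched regions.
#' @param tail_fraction Planted super-enhancer fraction, in (0, 0.5).
#' @param signal_law Either `"gamma-exponential"` (default) or `"constant"`
#'   (degenerate all-equal signals, for edge-case checks).
#' @param mapped_treatment,mapped_input Library sizes for the emitted
#'   coverage summaries.
#' @param seed Integer seed.
#' @return List with `regions` (chrom/start/end plus treatment/input read
#'   counts whose CPM difference reproduces the planted signal) , `mapped`
#'   (named totals) and `truth` (logical super-enhancer flag).
#' @export
simulate_enhancer_landscape <- function(n_regions, tail_fraction = 0.05,
                                        signal_law = "gamma-exponential",
                                        mapped_treatment = 2e7,
                                        mapped_input = 1e7, seed = 1) {
  assert_that(tail_fraction > 0 && tail_fraction < 0.5,
              "tail_fraction must be in (0, 0.5)")
  with_seed(seed, {
    n_se <- max(1L, round(n_regions * tail_fraction))
    if (signal_law == "constant") {
      signal <- rep(10, n_regions)
      is_se <- rep(FALSE, n_regions)
    } else {
      signal <- stats::rgamma(n_regions, shape = 2, rate = 0.5)
      is_se <- rep(FALSE, n_regions)
      idx <- sample.int(n_regions, n_se)
      signal[idx] <- max(signal) * 1.5 + rexp(n_se, rate = 1 / 40)
      is_se[idx] <- TRUE
    }
    input_cpm <- stats::rgamma(n_regions, shape = 4, rate = 2)
    starts <- seq(1, by = 20000, length.out = n_regions)
    regions <- tibble(
      chrom = "chr1", start = starts, end = starts + 9999,
      treatment_reads = (signal + input_cpm) * mapped_treatment / 1e6,
      input_reads = input_cpm * mapped_input / 1e6
    )
    list(regions = regions,
         mapped = c(treatment = mapped_treatment, input = mapped_input),
         truth = is_se)
  })
}

#' Simulate two significant-loop lists with planted set structure
#'
#' Loops are bin-aligned anchor pairs at the given bin size; the truth table
#' labels each loop `shared`, `td_only` (present only in the rearranged set)
#' or `control_only`.
#'
#' @param shared,td_only,control_only Loop counts per stratum (>= 0).
#' @param bin_size Anchor bin size in bp.
#' @param seed Integer seed.
#' @return List with `td` and `control` loop tibbles (`chrom1`, `start1`,
#'   `chrom2`, `start2`, `q_value`) and `truth`.
#' @export
simulate_loop_sets <- function(shared, td_only, control_only,
                               bin_size = 50000, seed = 1) {
  assert_that(shared >= 0 && td_only >= 0 && control_only >= 0,
              "loop counts must be >= 0")
  with_seed(seed, {
    n <- shared + td_only + control_only
    a1 <- sample.int(4000, n, replace = FALSE) * bin_size
    off <- sample.int(40, n, replace = TRUE) * bin_size
    loops <- tibble(chrom1 = "chr2", start1 = pmin(a1, a1 + off),
                    chrom2 = "chr2", start2 = pmax(a1, a1 + off),
                    q_value = runif(n, 0, 0.01))
    lab <- rep(c("shared", "td_only", "control_only"),
               c(shared, td_only, control_only))
    list(td = loops[lab != "control_only", ],
         control = loops[lab != "td_only", ],
         truth = mutate(loops, label = lab),
         bin_size = bin_size)
  })
}
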