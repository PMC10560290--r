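#' Stitch enhancer peaks into regions
#'
#' Peaks on the same chromosome whose gap is at most `stitch_distance`
#' (12,500 bp by default, the classical rank-ordering convention) are
#' unioned transitively; singleton peaks become their own region.
#' Overlapping input peaks are merged first with a warning.
#'
#' @param peaks Tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @param stitch_distance Maximum gap (bp) bridged by stitching, inclusive.
#' @return Tibble: `chrom`, `start`, `end`, `n_peaks`.
#' @export
stitch_peaks <- function(peaks, stitch_distance = 12500) {
  peaks <- as_tibble(peaks) |> arrange(.data$chrom, .data$start)
  out <- list()
  for (cn in unique(peaks$chrom)) {
    p <- filter(peaks, .data$chrom == cn)
    ir <- IRanges::IRanges(p$start, p$end)
    red <- IRanges::reduce(ir)
    if (length(red) < length(ir)) {
      warn("overlapping input peaks merged before stitching")
    }
    st <- IRanges::reduce(red, min.gapwidth = stitch_distance + 1)
    counts <- IRanges::countOverlaps(st, ir)
    out[[cn]] <- tibble(chrom = cn, start = IRanges::start(st),
                        end = IRanges::end(st), n_peaks = as.integer(counts))
  }
  bind_rows(out)
}

#' Input-corrected region signal in counts per million
#'
#' Converts per-region treatment and input read totals to CPM using the
#' mapped library totals and reports the input-corrected signal
#' `max(0, treatment_cpm - input_cpm)`.
#'
#' @param regions Tibble with `treatment_reads` and `input_reads` columns.
#' @param mapped_treatment,mapped_input Total mapped reads per library (> 0).
#' @return `regions` with `treatment_cpm`, `input_cpm`, `signal` columns.
#' @export
region_signal <- function(regions, mapped_treatment, mapped_input) {
  assert_that(mapped_treatment > 0 && mapped_input > 0,
              "mapped totals must be > 0")
  regions <- as_tibble(regions)
  regions$treatment_cpm <- regions$treatment_reads * 1e6 / mapped_treatment
  regions$input_cpm <- regions$input_reads * 1e6 / mapped_input
  regions$signal <- pmax(0, regions$treatment_cpm - regions$input_cpm)
  regions
}

#' Tangent-slope cutoff on the rank-ordered signal curve
#'
#' Signals are sorted ascending and rescaled, together with their ranks, to
#' the unit square; the threshold is the signal at the point where the
#' unit-slope line is tangent to the curve from below — the point minimizing
#' (scaled signal - scaled rank). Ties resolve to the highest rank. Regions
#' with signal strictly above the threshold are super-enhancers; when all
#' signals are equal there is no super-enhancer by convention.
#'
#' @param signals Numeric vector of corrected signals (length >= 3).
#' @return List with `threshold` and logical `is_super` aligned to
#'   `signals`.
#' @export
rose_cutoff <- function(signals) {
  assert_that(length(signals) >= 3, "need >= 3 regions")
  if (max(signals) == min(signals)) {
    return(list(threshold = max(signals),
                is_super = rep(FALSE, length(signals))))
  }
  s <- sort(signals)
  n <- length(s)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1]) / (s[n] - s[1])
  d <- y - x
  i <- max(which(d <= min(d) + 1e-12))  # tangent point, highest rank on ties
  thr <- s[i]
  list(threshold = thr, is_super = signals > thr)
}

#' Super-enhancer calls from stitched regions
#'
#' Combines [region_signal()] and [rose_cutoff()] into a ranked table.
#'
#' @param regions Stitched regions with read totals.
#' @param mapped_treatment,mapped_input Mapped library totals.
#' @return Tibble of class `se_calls`, ranked by decreasing signal, with
#'   `rank`, `signal`, `is_super` and a `threshold` attribute.
#' @export
call_super_enhancers <- function(regions, mapped_treatment, mapped_input) {
  r <- region_signal(regions, mapped_treatment, mapped_input)
  cut <- rose_cutoff(r$signal)
  r$is_super <- cut$is_super
  r <- arrange(r, dplyr::desc(.data$signal))
  r$rank <- seq_len(nrow(r))
  attr(r, "threshold") <- cut$threshold
  stamp(r, "se_calls")
}

#' @export
autoplot.se_calls <- function(object, ...) {
  df <- tibble(rank = rev(object$rank), signal = sort(object$signal),
               is_super = object$is_super[order(object$signal)])
  ggplot(df, aes(.data$rank, .data$signal, colour = .data$is_super)) +
    geom_point(size = 1) +
    geom_hline(yintercept = attr(object, "threshold"), linetype = 2) +
    labs(x = "regions ranked by signal", y = "input-corrected signal (CPM)",
         colour = "super-enhancer") +
    theme_minimal()
}

#' Proportion of samples with a super-enhancer overlapping a region
#'
#' Fraction of samples whose super-enhancer interval set overlaps the query
#' region by at least one base.
#'
#' @param se_intervals Tibble `sample`, `chrom`, `start`, `end` of
#'   super-enhancer calls across the cohort.
#' @param region List/one-row data frame `chrom`, `start`, `end`.
#' @param samples Optional full sample roster (samples with no rows in
#'   `se_intervals` count in the denominator).
#' @return Proportion in `[0, 1]`.
#' @export
recurrent_se_proportion <- function(se_intervals, region, samples = NULL) {
  samples <- samples %||% unique(se_intervals$sample)
  assert_that(length(samples) >= 1, "need >= 1 sample")
  hit <- se_intervals |>
    filter(.data$chrom == region$chrom, .data$start <= region$end,
           .data$end >= region$start) |>
    pull(.data$sample) |>
    unique()
  length(intersect(samples, hit)) / length(samples)
}

loop_keys <- function(loops, bin_size) {
  b1 <- floor(loops$start1 / bin_size)
  b2 <- floor(loops$start2 / bin_size)
  lo <- pmin(b1, b2); hi <- pmax(b1, b2)
  paste(loops$chrom1, lo, loops$chrom2, hi, sep = ":")
}

#' Neo-loops: significant loops private to the rearranged set
#'
#' Compares two significant-loop lists on binned anchor keys: loops present
#' only in the tandem-duplication (rearranged) set are neo-loops; loops in
#' both sets are shared. `neo` and `shared` partition the TD list exactly.
#' Anchors are snapped to `bin_size` bins, so anchors differing by less than
#' one bin are the same key.
#'
#' @param td_loops,control_loops Loop tibbles with `chrom1`, `start1`,
#'   `chrom2`, `start2`.
#' @param bin_size Anchor bin size (bp); both lists must share it.
#' @param query Optional region (`chrom`, `start`, `end`) restricting
#'   reported loops to those with an anchor in the region.
#' @return List with `neo`, `shared` (TD-list rows) and `control_only`.
#' @export
neo_loops <- function(td_loops, control_loops, bin_size = 50000,
                      query = NULL) {
  td_loops <- as_tibble(td_loops)
  control_loops <- as_tibble(control_loops)
  kt <- loop_keys(td_loops, bin_size)
  kc <- loop_keys(control_loops, bin_size)
  neo <- td_loops[!kt %in% kc, , drop = FALSE]
  shared <- td_loops[kt %in% kc, , drop = FALSE]
  ctrl_only <- control_loops[!kc %in% kt, , drop = FALSE]
  if (!is.null(query)) {
    in_query <- function(l) {
      (l$chrom1 == query$chrom & l$start1 <= query$end &
         l$start1 + bin_size - 1 >= query$start) |
        (l$chrom2 == query$chrom & l$start2 <= query$end &
           l$start2 + bin_size - 1 >= query$start)
    }
    neo <- neo[in_query(neo), , drop = FALSE]
    shared <- shared[in_query(shared), , drop = FALSE]
    ctrl_only <- ctrl_only[in_query(ctrl_only), , drop = FALSE]
  }
  list(neo = neo, shared = shared, control_only = ctrl_only)
}
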