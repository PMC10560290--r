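#' Sample-level quality control of a copy-number profile
#'
#' A sample fails statistical use when its coverage log-ratios or
#' segmentation are untrustworthy, i.e. when (1) `mad(logCR) > 0.2`, or
#' (2) more than 20% of segments contain fewer than 10 targets AND
#' (`mad(logCR) > 0.15` or the segment count exceeds 3,000). `mad()` is the
#' usual consistency-scaled median absolute deviation. Failed samples were
#' triaged by manual review in the original workflow into "usable" (targeted
#' large events still callable) or "mutation-only"; this function reports the
#' automatic verdict plus the metrics that drive that review.
#'
#' @param target_logcr Per-target logCR vector for the sample.
#' @param segments Segment tibble with an `n_T` column.
#' @return One-row tibble: `status` (`"pass"`/`"fail"`), `mad_logcr`,
#'   `prop_small_segments`, `n_segments`, and the two failure flags.
#' @export
sample_qc <- function(target_logcr, segments) {
  assert_that(nrow(segments) >= 1, "need at least one segment")
  m <- mad(target_logcr, na.rm = TRUE)
  prop_small <- mean(segments$n_T < 10)
  n_seg <- nrow(segments)
  fail1 <- m > 0.2
  fail2 <- prop_small > 0.2 && (m > 0.15 || n_seg > 3000)
  tibble(status = if (fail1 || fail2) "fail" else "pass",
         mad_logcr = m, prop_small_segments = prop_small,
         n_segments = n_seg, fail_scatter = fail1, fail_fragmented = fail2)
}

arm_table <- function(spec) {
  ch <- spec$chromosomes
  bind_rows(
    tibble(chrom = ch$name, arm = "p", start = 1, end = ch$p_length,
           acrocentric = ch$acrocentric)[ch$p_length > 0 & !ch$acrocentric, ],
    tibble(chrom = ch$name, arm = "q", start = ch$p_length + 1,
           end = ch$p_length + ch$q_length, acrocentric = ch$acrocentric)
  )
}

#' Per-arm SCNA event sizes
#'
#' Segmentation tends to shatter one biological event into pieces, so event
#' size is estimated as the total length of same-type segments on the same
#' chromosome arm. Segments spanning the centromere are split across arms
#' before summation. An event is `large` when the total strictly exceeds
#' `large_threshold` (9 Mb by default; 1 Mb is the secondary threshold used
#' when re-analysing mutation-negative samples for shorter events).
#'
#' @param segments Classified segments (`final_call` column); only `LOSS`,
#'   `GAIN`, `CN-LOH` rows are counted (`GAIN-filtered` is recoded to `GAIN`
#'   when `include_gain_filtered = TRUE`).
#' @param spec A [genome_spec()] providing arm boundaries.
#' @param large_threshold Strict lower bound (bp) for the `is_large` flag.
#' @param include_gain_filtered Count `GAIN-filtered` segments as gains.
#' @return Tibble: `chrom`, `arm`, `type`, `total_length`, `frac_arm`,
#'   `is_large`.
#' @export
arm_event_sizes <- function(segments, spec, large_threshold = 9e6,
                            include_gain_filtered = FALSE) {
  segs <- as_tibble(segments)
  if (include_gain_filtered) {
    segs$final_call[segs$final_call == "GAIN-filtered"] <- "GAIN"
  }
  segs <- filter(segs, .data$final_call %in% c("LOSS", "GAIN", "CN-LOH"))
  arms <- arm_table(spec)
  if (nrow(segs) == 0) {
    return(tibble(chrom = character(), arm = character(), type = character(),
                  total_length = numeric(), frac_arm = numeric(),
                  is_large = logical()))
  }
  pieces <- map(seq_len(nrow(arms)), function(i) {
    a <- arms[i, ]
    s <- filter(segs, .data$chrom == a$chrom,
                .data$start <= a$end, .data$end >= a$start)
    if (nrow(s) == 0) return(NULL)
    tibble(chrom = a$chrom, arm = a$arm, type = s$final_call,
           length = pmin(s$end, a$end) - pmax(s$start, a$start) + 1,
           arm_length = a$end - a$start + 1)
  }) |> list_rbind()
  pieces |>
    group_by(.data$chrom, .data$arm, .data$type) |>
    summarise(total_length = sum(.data$length),
              frac_arm = sum(.data$length) / .data$arm_length[1],
              .groups = "drop") |>
    mutate(is_large = .data$total_length > large_threshold)
}

#' Categorize arm events, folding whole-chromosome events together
#'
#' An event type covering at least 50% of both arms of a chromosome is
#' re-labelled with a whole-chromosome category (e.g. `20-GAIN` instead of
#' `20p-GAIN`/`20q-GAIN`), which avoids double counting aneuploidies. For
#' acrocentric chromosomes, whose p arm carries no callable coverage, the q
#' arm stands in for both. The `covers_80pct` flag marks whole-chromosome
#' events covering >= 80% of the chromosome (or of the q arm when
#' acrocentric).
#'
#' @param arm_events Result of [arm_event_sizes()].
#' @param spec The [genome_spec()].
#' @return Tibble: `category`, `chrom`, `type`, `total_length`, `is_large`,
#'   `whole_chromosome`, `covers_80pct`.
#' @export
categorize_whole_chromosome <- function(arm_events, spec) {
  ch <- spec$chromosomes
  label <- function(chrom) sub("^chr", "", chrom)
  out <- list()
  for (cn in unique(arm_events$chrom)) {
    acro <- ch$acrocentric[match(cn, ch$name)]
    ev <- filter(arm_events, .data$chrom == cn)
    for (ty in unique(ev$type)) {
      e <- filter(ev, .data$type == ty)
      fp <- e$frac_arm[e$arm == "p"]
      fq <- e$frac_arm[e$arm == "q"]
      fp <- if (length(fp)) fp else 0
      fq <- if (length(fq)) fq else 0
      whole <- if (acro) fq >= 0.5 else (fp >= 0.5 && fq >= 0.5)
      tot <- sum(e$total_length)
      chrom_len <- ch$p_length[match(cn, ch$name)] +
        ch$q_length[match(cn, ch$name)]
      cover_base <- if (acro) ch$q_length[match(cn, ch$name)] else chrom_len
      if (whole) {
        out[[length(out) + 1]] <- tibble(
          category = paste0(label(cn), "-", ty), chrom = cn, type = ty,
          total_length = tot, is_large = any(e$is_large),
          whole_chromosome = TRUE,
          covers_80pct = tot / cover_base >= 0.8
        )
      } else {
        out[[length(out) + 1]] <- tibble(
          category = paste0(label(cn), e$arm, "-", ty), chrom = cn,
          type = ty, total_length = e$total_length, is_large = e$is_large,
          whole_chromosome = FALSE, covers_80pct = FALSE
        )
      }
    }
  }
  list_rbind(out)
}

#' Maximal interval of shared copy neutrality across samples
#'
#' Intersects, across samples, the copy-neutral coverage within a query
#' region — the operation that pins down a short segment whose copy number is
#' preserved (or regained) in every rearranged sample. The reported `length`
#' is the distance between the boundary coordinates (`end - start`).
#'
#' @param neutral_intervals Tibble `sample`, `chrom`, `start`, `end` of
#'   copy-neutral intervals per sample.
#' @param region List or one-row data frame with `chrom`, `start`, `end`.
#' @return Tibble of intersection intervals (possibly empty), widest first,
#'   with `chrom`, `start`, `end`, `length`.
#' @export
#' @examples
#' iv <- tibble::tibble(
#'   sample = c("a", "b"),
#'   chrom = "chr2",
#'   start = c(219800000, 219825716),
#'   end = c(219950000, 220000000)
#' )
#' shared_neutral_interval(iv, list(chrom = "chr2", start = 219650000,
#'                                  end = 220150000))
shared_neutral_interval <- function(neutral_intervals, region) {
  assert_that(nrow(neutral_intervals) >= 1, "need at least one sample")
  q <- IRanges::IRanges(region$start, region$end)
  per_sample <- neutral_intervals |>
    filter(.data$chrom == region$chrom) |>
    (\(d) split(d, d$sample))()
  if (length(per_sample) == 0 ||
      length(per_sample) < length(unique(neutral_intervals$sample))) {
    # a sample with no neutral coverage in the region empties the intersection
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  length = numeric()))
  }
  acc <- q
  for (d in per_sample) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
    acc <- IRanges::intersect(acc, ir)
    if (length(acc) == 0) break
  }
  out <- tibble(chrom = region$chrom, start = IRanges::start(acc),
                end = IRanges::end(acc)) |>
    mutate(length = .data$end - .data$start) |>
    arrange(dplyr::desc(.data$length))
  out
}
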