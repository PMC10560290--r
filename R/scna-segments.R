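#' Read a BED file of intervals
#'
#' Minimal three-column BED reader converting 0-based half-open records to the
#' 1-based inclusive convention used internally. Malformed lines raise an
#' error naming the offending line.
#'
#' @param path Path to a plain-text BED file.
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t| +")
  bad <- which(vapply(parts, function(p) {
    length(p) < 3 || anyNA(suppressWarnings(as.numeric(p[2:3])))
  }, logical(1)))
  if (length(bad)) {
    abort(sprintf("malformed BED record at line %d: '%s'", bad[1],
                  lines[bad[1]]))
  }
  tibble(
    chrom = vapply(parts, `[[`, character(1), 1),
    start = vapply(parts, function(p) as.numeric(p[2]), numeric(1)) + 1,
    end = vapply(parts, function(p) as.numeric(p[3]), numeric(1))
  )
}

#' Flag segments overlapping low-complexity regions
#'
#' A segment is dropped when strictly more than `max_fraction` (default 70%)
#' of its bases overlap the (normalized) low-complexity mask.
#'
#' @param segments Segment tibble (`chrom`, `start`, `end`, ...).
#' @param mask Mask intervals as a tibble (`chrom`, `start`, `end`, 1-based
#'   inclusive; see [read_bed()]).
#' @param max_fraction Strict upper bound on the masked fraction.
#' @return `segments` with added `masked_fraction` and logical `kept`.
#' @export
exclude_low_complexity <- function(segments, mask, max_fraction = 0.70) {
  segments <- as_tibble(segments)
  if (is.null(mask) || nrow(mask) == 0) {
    return(mutate(segments, masked_fraction = 0, kept = TRUE))
  }
  ov <- vapply(seq_len(nrow(segments)), function(i) {
    overlap_bases(segments$chrom[i], segments$start[i], segments$end[i], mask)
  }, numeric(1))
  segments$masked_fraction <- ov / (segments$end - segments$start + 1)
  segments$kept <- segments$masked_fraction <= max_fraction
  segments
}

seg_stats_row <- function(chrom, start, end, sites) {
  d <- compute_devbaf(sites, list(chrom = chrom, start = start, end = end))
  tibble(n = d$n, M_dev = d$M_dev, SD_dev = d$SD_dev)
}

merge_rule <- function(a, b, logcr_tol = 0.05) {
  if (a$chrom != b$chrom || a$exomecnv_call != b$exomecnv_call) return(FALSE)
  if (a$n < 3 || b$n < 3) return(TRUE)  # few-site override: always merge
  if (abs(a$logCR - b$logCR) > logcr_tol) return(FALSE)
  sd_half <- 0.5 * mean(c(a$SD_dev, b$SD_dev))
  abs(a$M_dev - b$M_dev) <= sd_half
}

#' Merge consecutive segments with concordant statistics
#'
#' Left-to-right sequential concatenation, repeated to a fixpoint: two
#' consecutive same-chromosome segments merge when they carry the same caller
#' event type and either (a) their logCR values differ by at most 0.05 AND
#' their mean devBAF values differ by at most half the (averaged) devBAF SD,
#' or (b) either segment contains fewer than three SNV sites (the few-site
#' override). The merged segment's statistics are recomputed from the pooled
#' target counts and pooled sites.
#'
#' @param segments Coordinate-sorted segment tibble with `chrom`, `start`,
#'   `end`, `exomecnv_call`, `logCR`, `n_T`.
#' @param sites Retained BAF sites.
#' @param logcr_tol logCR concordance tolerance.
#' @return Merged segment tibble with refreshed `n`, `M_dev`, `SD_dev`.
#' @export
merge_segments <- function(segments, sites, logcr_tol = 0.05) {
  segments <- as_tibble(segments)
  ord <- order(segments$chrom, segments$start)
  if (!identical(ord, seq_len(nrow(segments)))) {
    abort("segments must be coordinate-sorted per chromosome")
  }
  segs <- segments |>
    mutate(stats = pmap(list(.data$chrom, .data$start, .data$end),
                        seg_stats_row, sites = sites)) |>
    tidyr::unnest("stats")
  repeat {
    changed <- FALSE
    i <- 1L
    while (i < nrow(segs)) {
      a <- segs[i, ]
      b <- segs[i + 1L, ]
      if (merge_rule(a, b, logcr_tol)) {
        w <- c(max(a$n_T, 0), max(b$n_T, 0))
        if (sum(w) == 0) w <- c(1, 1)
        merged <- tibble(
          chrom = a$chrom, start = a$start, end = b$end,
          exomecnv_call = a$exomecnv_call,
          logCR = sum(c(a$logCR, b$logCR) * w) / sum(w),
          n_T = a$n_T + b$n_T
        )
        st <- seg_stats_row(merged$chrom, merged$start, merged$end, sites)
        merged <- bind_rows(cbind(merged, st))
        segs <- bind_rows(
          if (i > 1) segs[seq_len(i - 1L), ],
          merged,
          if (i + 1L < nrow(segs)) segs[seq(i + 2L, nrow(segs)), ]
        )
        changed <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!changed) break
  }
  segs
}

# evaluate one classification rule set; clauses is a list of logicals
# (each possibly NA); returns "call", "none" or "indeterminate"
eval_clauses <- function(clauses) {
  vals <- unlist(clauses)
  if (any(vals %in% TRUE)) return("call")
  if (anyNA(vals)) return("indeterminate")
  "none"
}

classify_one <- function(call, P_ABT, P_dev, M_dev, n, n_T, logCR, CR,
                         gain_filtered) {
  if (is.na(call)) return("indeterminate")
  if (call == "deletion") {
    cl <- list(P_ABT < 0.05 & P_dev < 0.1 & M_dev >= 0.1,
               P_ABT >= 0.05 & P_dev < 0.05 & M_dev >= 0.15,
               n > 0 & n < 3 & n_T >= 10 & M_dev >= 0.17)
    r <- eval_clauses(cl)
    return(switch(r, call = "LOSS", none = "NEUTRAL", r))
  }
  if (call == "amplification") {
    cl <- list(P_ABT < 0.01 & n >= 20 & logCR > 1.11,
               P_ABT < 0.05 & P_dev < 0.1,
               P_ABT >= 0.05 & P_dev < 0.05 & M_dev >= 0.1,
               n_T >= 100 & CR >= 1.3)
    r <- eval_clauses(cl)
    if (r == "call") return("GAIN")
    if (gain_filtered) {
      gf <- eval_clauses(list(n_T >= 60 & M_dev >= 0.08))
      if (gf == "call") return("GAIN-filtered")
      if (gf == "indeterminate" || r == "indeterminate") {
        return("indeterminate")
      }
      return("NEUTRAL")
    }
    return(switch(r, none = "NEUTRAL", r))
  }
  if (call == "neutral") {
    cl <- list(P_ABT < 0.05 & P_dev < 0.1 & M_dev >= 0.15,
               P_ABT >= 0.05 & P_dev < 0.05 & M_dev >= 0.2)
    r <- eval_clauses(cl)
    return(switch(r, call = "CN-LOH", none = "NEUTRAL", r))
  }
  "indeterminate"
}

#' Final SCNA classification of segments
#'
#' Applies the rule tables mapping the upstream caller label plus the
#' allelic-imbalance statistics to a final call:
#'
#' * deletion -> `LOSS` if `(P_ABT < 0.05 & P_dev < 0.1 & M_dev >= 0.1)` or
#'   `(P_ABT >= 0.05 & P_dev < 0.05 & M_dev >= 0.15)` or
#'   `(n > 0 & n < 3 & n_T >= 10 & M_dev >= 0.17)`;
#' * amplification -> `GAIN` if `(P_ABT < 0.01 & n >= 20 & logCR > 1.11)` or
#'   `(P_ABT < 0.05 & P_dev < 0.1)` or
#'   `(P_ABT >= 0.05 & P_dev < 0.05 & M_dev >= 0.1)` or
#'   `(n_T >= 100 & CR >= 1.3)`; with `gain_filtered = TRUE`, amplification
#'   segments failing all GAIN clauses but satisfying
#'   `n_T >= 60 & M_dev >= 0.08` become `GAIN-filtered`;
#' * neutral -> `CN-LOH` if `(P_ABT < 0.05 & P_dev < 0.1 & M_dev >= 0.15)` or
#'   `(P_ABT >= 0.05 & P_dev < 0.05 & M_dev >= 0.2)`;
#' * anything else -> `NEUTRAL`. A clause that cannot be evaluated because a
#'   required statistic is missing yields `indeterminate`, never a silent
#'   NEUTRAL.
#'
#' @param segments Tibble with `exomecnv_call`, `P_ABT`, `P_dev`, `M_dev`,
#'   `n`, `n_T`, `logCR` (and optionally `CR`; computed as `2^logCR` when
#'   absent).
#' @param gain_filtered Enable the weaker `GAIN-filtered` rescue rule.
#' @return `segments` with a `final_call` column.
#' @export
classify_segment <- function(segments, gain_filtered = FALSE) {
  segments <- as_tibble(segments)
  if (!"CR" %in% names(segments)) segments$CR <- 2^segments$logCR
  segments$final_call <- vapply(seq_len(nrow(segments)), function(i) {
    classify_one(segments$exomecnv_call[i], segments$P_ABT[i],
                 segments$P_dev[i], segments$M_dev[i], segments$n[i],
                 segments$n_T[i], segments$logCR[i], segments$CR[i],
                 gain_filtered)
  }, character(1))
  segments
}

#' End-to-end SCNA calling from segments and BAF sites
#'
#' Convenience pipeline: filter BAF sites, optionally drop low-complexity
#' segments, merge consecutive segments, compute the Ansari-Bradley and Z
#' test statistics per segment, and classify.
#'
#' @param segments Segment tibble (`chrom`, `start`, `end`, `exomecnv_call`,
#'   `logCR`, `n_T`).
#' @param baf_sites Raw BAF site tibble (filtered internally).
#' @param mask Optional low-complexity mask tibble.
#' @param gain_filtered Enable the `GAIN-filtered` rescue rule.
#' @param merge Run the consecutive-segment merging pass.
#' @return Classified segment tibble of class `scna_calls`.
#' @export
call_scna <- function(segments, baf_sites, mask = NULL,
                      gain_filtered = FALSE, merge = TRUE) {
  sites <- filter_baf_sites(baf_sites)
  segments <- as_tibble(segments)
  if (!is.null(mask)) {
    segments <- exclude_low_complexity(segments, mask) |>
      filter(.data$kept) |>
      select(-"masked_fraction", -"kept")
  }
  segments <- arrange(segments, .data$chrom, .data$start)
  segs <- if (merge) {
    merge_segments(segments, sites)
  } else {
    segments |>
      mutate(stats = pmap(list(.data$chrom, .data$start, .data$end),
                          seg_stats_row, sites = sites)) |>
      tidyr::unnest("stats")
  }
  tests <- map(seq_len(nrow(segs)), function(i) {
    d <- compute_devbaf(sites, segs[i, ])
    if (d$n >= 2 && length(d$blood_dev) >= 2) {
      tibble(P_ABT = ansari_bradley_scale_test(d$tumor_dev, d$blood_dev),
             P_dev = devbaf_z_test(d$tumor_dev))
    } else {
      tibble(P_ABT = NA_real_, P_dev = NA_real_)
    }
  }) |> list_rbind()
  out <- classify_segment(bind_rows(cbind(segs, tests)), gain_filtered)
  stamp(out, "scna_calls")
}
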