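#' Naive mean-shift segmentation of a coverage profile
#'
#' A deliberately simple changepoint fallback for self-contained
#' demonstrations: recursive binary splitting of each chromosome's
#' target-level logCR at the point maximizing the between-segment mean
#' shift, accepted while the shift exceeds `min_shift` and both sides keep
#' `min_targets` targets. Production workflows consume segmentation from a
#' dedicated caller; this exists so the classification stage can be
#' exercised from a bare coverage table.
#'
#' @param coverage Tibble `chrom`, `start`, `end`, `logCR` (per target).
#' @param min_shift Minimal absolute mean difference to accept a split.
#' @param min_targets Minimal targets per side.
#' @param del_threshold,amp_threshold Mean-logCR cutoffs used to label each
#'   segment deletion / amplification / neutral.
#' @return Segment tibble (`chrom`, `start`, `end`, `exomecnv_call`,
#'   `logCR`, `n_T`) ready for [call_scna()].
#' @export
naive_segment <- function(coverage, min_shift = 0.2, min_targets = 10,
                          del_threshold = -0.15, amp_threshold = 0.15) {
  split_rec <- function(y) {
    n <- length(y)
    if (n < 2 * min_targets) return(n)
    cands <- seq(min_targets, n - min_targets)
    shift <- vapply(cands, function(i) {
      abs(mean(y[seq_len(i)]) - mean(y[seq(i + 1, n)]))
    }, numeric(1))
    best <- which.max(shift)
    if (shift[best] < min_shift) return(n)
    i <- cands[best]
    c(split_rec(y[seq_len(i)]), split_rec(y[seq(i + 1, n)]))
  }
  out <- list()
  for (cn in unique(coverage$chrom)) {
    d <- coverage[coverage$chrom == cn, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    sizes <- split_rec(d$logCR)
    ends <- cumsum(sizes)
    starts <- c(1, head(ends, -1) + 1)
    out[[cn]] <- tibble(
      chrom = cn,
      start = d$start[starts], end = d$end[ends],
      logCR = vapply(seq_along(starts), function(k) {
        mean(d$logCR[starts[k]:ends[k]])
      }, numeric(1)),
      n_T = sizes
    )
  }
  segs <- bind_rows(out)
  segs$exomecnv_call <- dplyr::case_when(
    segs$logCR < del_threshold ~ "deletion",
    segs$logCR > amp_threshold ~ "amplification",
    TRUE ~ "neutral"
  )
  select(segs, "chrom", "start", "end", "exomecnv_call", "logCR", "n_T")
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) < 3)
  if (length(bad)) {
    abort(sprintf("malformed GMT record at line %d", bad[1]))
  }
  setNames(lapply(parts, function(p) p[-(1:2)]),
           vapply(parts, `[[`, character(1), 1))
}
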