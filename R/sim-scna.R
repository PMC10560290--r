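#' Define a synthetic genome layout
#'
#' A genome specification hosts per-chromosome arm lengths plus the sampling
#' density of exome targets and heterozygous SNV sites. Coordinates are
#' 1-based inclusive; the p arm occupies `[1, p_length]` and the q arm
#' `[p_length + 1, p_length + q_length]`. Acrocentric chromosomes carry no
#' usable p-arm coverage: no targets or SNV sites are generated there.
#'
#' @param chromosomes Data frame with columns `name`, `p_length`, `q_length`
#'   (base pairs) and logical `acrocentric`. Defaults to a compact three
#'   chromosome layout adequate for simulation studies.
#' @param target_spacing Spacing of exome target intervals in bp.
#' @param snv_per_mb Expected density of usable heterozygous SNV sites per Mb.
#' @return A `genome_spec` list.
#' @export
#' @examples
#' genome_spec()
genome_spec <- function(chromosomes = NULL,
                        target_spacing = 50000,
                        snv_per_mb = 5) {
  if (is.null(chromosomes)) {
    chromosomes <- tibble(
      name = c("chr1", "chr2", "chr3"),
      p_length = c(40e6, 30e6, 0),
      q_length = c(60e6, 70e6, 50e6),
      acrocentric = c(FALSE, FALSE, TRUE)
    )
  }
  chromosomes <- as_tibble(chromosomes)
  assert_that(all(c("name", "p_length", "q_length", "acrocentric") %in%
                    names(chromosomes)),
              "chromosomes must have name/p_length/q_length/acrocentric")
  assert_that(all(chromosomes$q_length > 0), "q-arm lengths must be > 0")
  assert_that(all(chromosomes$p_length >= 0), "p-arm lengths must be >= 0")
  assert_that(all(chromosomes$p_length[!chromosomes$acrocentric] > 0),
              "non-acrocentric chromosomes need p-arm length > 0")
  structure(
    list(chromosomes = chromosomes,
         target_spacing = target_spacing,
         snv_per_mb = snv_per_mb),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("<genome_spec> ", nrow(x$chromosomes), " chromosomes, targets every ",
      x$target_spacing, " bp, ", x$snv_per_mb, " SNV sites/Mb\n", sep = "")
  invisible(x)
}

chrom_length <- function(spec, chrom) {
  i <- match(chrom, spec$chromosomes$name)
  spec$chromosomes$p_length[i] + spec$chromosomes$q_length[i]
}

# expected tumour copy number for each planted event type
event_copy_number <- function(type, extra_copies) {
  dplyr::case_when(
    type == "LOSS" ~ 1,
    type == "CN-LOH" ~ 2,
    type == "GAIN" ~ 2 + extra_copies,
    type == "TANDEM_DUP" ~ 2 + extra_copies,
    TRUE ~ 2
  )
}

# alt-allele copies for the two possible phases of an event; folded devBAF is
# identical for both, so the phase only flips the sign of the BAF shift
event_baf_pair <- function(type, extra_copies, rho) {
  cn <- event_copy_number(type, extra_copies)
  denom <- cn * rho + 2 * (1 - rho)
  m_hi <- dplyr::case_when(
    type == "LOSS" ~ 1,
    type == "CN-LOH" ~ 2,
    type %in% c("GAIN", "TANDEM_DUP") ~ 1 + extra_copies,
    TRUE ~ 1
  )
  hi <- (m_hi * rho + (1 - rho)) / denom
  list(hi = hi, lo = 1 - hi)
}

# expand CHROMOTHRIPSIS rows into >= 6 alternating LOSS/NEUTRAL sub-segments
# with one designated preserved copy-neutral window
expand_chromothripsis <- function(events, n_pieces = 8) {
  assert_that(n_pieces >= 6, "chromothripsis needs >= 6 pieces")
  out <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (ev$type != "CHROMOTHRIPSIS") {
      out[[i]] <- mutate(ev, preserved = FALSE)
      next
    }
    cuts <- round(seq(ev$start, ev$end + 1, length.out = n_pieces + 1))
    piece_type <- rep(c("LOSS", "NEUTRAL"), length.out = n_pieces)
    neutral_idx <- which(piece_type == "NEUTRAL")
    preserved_piece <- neutral_idx[ceiling(length(neutral_idx) / 2)]
    out[[i]] <- tibble(
      chrom = ev$chrom,
      start = cuts[-(n_pieces + 1)],
      end = cuts[-1] - 1,
      type = piece_type,
      purity = ev$purity,
      extra_copies = ev$extra_copies,
      preserved = seq_len(n_pieces) == preserved_piece
    )
  }
  bind_rows(out)
}

validate_events <- function(events, spec) {
  needed <- c("chrom", "start", "end", "type", "purity")
  assert_that(all(needed %in% names(events)),
              "events must have chrom/start/end/type/purity")
  if (!"extra_copies" %in% names(events)) events$extra_copies <- 1
  assert_that(all(events$start <= events$end), "event start must be <= end")
  assert_that(all(events$purity > 0 & events$purity <= 1),
              "purity must be in (0, 1]")
  assert_that(all(events$extra_copies >= 1), "extra_copies must be >= 1")
  ok_types <- c("LOSS", "GAIN", "CN-LOH", "TANDEM_DUP", "CHROMOTHRIPSIS",
                "NEUTRAL")
  assert_that(all(events$type %in% ok_types),
              "unknown event type(s): %s",
              paste(setdiff(events$type, ok_types), collapse = ", "))
  assert_that(all(events$chrom %in% spec$chromosomes$name),
              "event chromosome not in genome spec")
  assert_that(all(events$end <= chrom_length(spec, events$chrom)),
              "event extends past chromosome end")
  events
}

check_nonoverlap <- function(expanded) {
  by_chr <- split(expanded, expanded$chrom)
  for (d in by_chr) {
    d <- arrange(d, .data$start)
    if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)])) {
      abort("planted events overlap after chromothripsis expansion")
    }
  }
  invisible(TRUE)
}

#' Simulate a tumour-normal SCNA profile with planted events
#'
#' Generates per-target coverage log-ratios and per-site B-allele frequencies
#' under a purity mixture of tumour and normal cells. A target inside an event
#' of local tumour copy number `c` at purity `rho` has expected
#' `logCR = log2((2 * (1 - rho) + c * rho) / 2)`; heterozygous-site tumour BAF
#' is drawn around the corresponding purity-mixed allelic fraction and blood
#' BAF around 0.5. With `noise_sd = 0` the profile is fully deterministic
#' (exact expected values, no read resampling), which the worked examples and
#' oracle tests rely on.
#'
#' @param spec A [genome_spec()].
#' @param events Data frame of planted events: `chrom`, `start`, `end`
#'   (1-based inclusive bp), `type` (`LOSS`, `GAIN`, `CN-LOH`, `TANDEM_DUP`,
#'   `CHROMOTHRIPSIS`), `purity` in (0, 1], and optionally `extra_copies`
#'   (>= 1, gains only).
#' @param noise_sd Gaussian noise SD on per-target logCR; 0 disables all
#'   stochastic components.
#' @param tumor_depth,blood_depth Sequencing depth at SNV sites used for
#'   read-count resampling of BAFs.
#' @param baf_overdispersion Beta-binomial overdispersion in `[0, 1)` for BAF
#'   read counts; 0 gives plain binomial sampling.
#' @param seed Integer seed; the generator is bit-reproducible given
#'   (parameters, seed).
#' @return A list with tibbles `coverage` (chrom, start, end, logCR),
#'   `baf` (chrom, pos, tumor_baf, blood_baf, tumor_depth, blood_depth) and
#'   `truth` (every planted sub-segment with its copy number and purity).
#' @export
#' @examples
#' sp <- genome_spec()
#' ev <- tibble::tibble(chrom = "chr1", start = 1e6, end = 20e6,
#'                      type = "LOSS", purity = 1)
#' prof <- simulate_scna_profile(sp, ev, noise_sd = 0, seed = 1)
#' mean(prof$coverage$logCR[prof$coverage$start < 20e6])  # log2(1/2) = -1
simulate_scna_profile <- function(spec, events, noise_sd = 0.15,
                                  tumor_depth = 80, blood_depth = 40,
                                  baf_overdispersion = 0, seed = 1) {
  assert_that(inherits(spec, "genome_spec"), "spec must be a genome_spec")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  events <- validate_events(as_tibble(events), spec)
  expanded <- expand_chromothripsis(events)
  check_nonoverlap(expanded)

  with_seed(seed, {
    cov_list <- list()
    baf_list <- list()
    for (i in seq_len(nrow(spec$chromosomes))) {
      chr <- spec$chromosomes[i, ]
      lo <- if (chr$acrocentric) chr$p_length + 1 else 1
      hi <- chr$p_length + chr$q_length
      starts <- seq(lo, hi - spec$target_spacing + 1,
                    by = spec$target_spacing)
      cov_list[[i]] <- tibble(chrom = chr$name, start = starts,
                              end = starts + spec$target_spacing - 1)
      n_sites <- round((hi - lo + 1) / 1e6 * spec$snv_per_mb)
      pos <- sort(sample.int(hi - lo + 1, n_sites) + lo - 1)
      baf_list[[i]] <- tibble(chrom = chr$name, pos = pos)
    }
    coverage <- bind_rows(cov_list)
    baf <- bind_rows(baf_list)

    ev_act <- filter(expanded, .data$type != "NEUTRAL")
    loc_cn <- rep(2, nrow(coverage))
    loc_rho <- rep(1, nrow(coverage))
    ev_idx_cov <- rep(NA_integer_, nrow(coverage))
    mid <- (coverage$start + coverage$end) / 2
    for (j in seq_len(nrow(ev_act))) {
      sel <- coverage$chrom == ev_act$chrom[j] & mid >= ev_act$start[j] &
        mid <= ev_act$end[j]
      loc_cn[sel] <- event_copy_number(ev_act$type[j], ev_act$extra_copies[j])
      loc_rho[sel] <- ev_act$purity[j]
      ev_idx_cov[sel] <- j
    }
    mu_cr <- (2 * (1 - loc_rho) + loc_cn * loc_rho) / 2
    coverage$logCR <- log2(mu_cr) +
      if (noise_sd > 0) rnorm(nrow(coverage), 0, noise_sd) else 0

    baf_mu <- rep(0.5, nrow(baf))
    for (j in seq_len(nrow(ev_act))) {
      sel <- baf$chrom == ev_act$chrom[j] & baf$pos >= ev_act$start[j] &
        baf$pos <= ev_act$end[j]
      if (!any(sel)) next
      pair <- event_baf_pair(ev_act$type[j], ev_act$extra_copies[j],
                             ev_act$purity[j])
      phase_hi <- if (noise_sd > 0) {
        rbinom(sum(sel), 1, 0.5) == 1
      } else {
        # deterministic alternation keeps folded devBAF exact
        seq_len(sum(sel)) %% 2 == 0
      }
      baf_mu[sel] <- ifelse(phase_hi, pair$hi, pair$lo)
    }
    if (noise_sd > 0) {
      t_alt <- rcounts_bb(length(baf_mu), tumor_depth, baf_mu,
                          baf_overdispersion)
      b_alt <- rcounts_bb(length(baf_mu), blood_depth, 0.5,
                          baf_overdispersion)
      baf$tumor_baf <- t_alt / tumor_depth
      baf$blood_baf <- b_alt / blood_depth
    } else {
      baf$tumor_baf <- baf_mu
      baf$blood_baf <- 0.5
    }
    baf$tumor_depth <- tumor_depth
    baf$blood_depth <- blood_depth

    truth <- expanded |>
      mutate(copy_number = ifelse(.data$type == "NEUTRAL", 2,
                                  event_copy_number(.data$type,
                                                    .data$extra_copies))) |>
      select("chrom", "start", "end", "type", "copy_number", "purity",
             "preserved")
    list(coverage = coverage, baf = baf, truth = truth, spec = spec)
  })
}

# beta-binomial counts; rho = 0 degrades to binomial
rcounts_bb <- function(n, size, prob, rho) {
  prob <- rep_len(prob, n)
  if (rho <= 0) return(rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  rbinom(n, size, rbeta(n, a, b))
}

#' Build an ExomeCNV-style segment table from a simulated profile
#'
#' Converts the truth intervals of [simulate_scna_profile()] (plus the gaps
#' between them) into the coordinate-sorted segment table the SCNA
#' post-processing stage consumes, labelling each segment deletion,
#' amplification or neutral from its mean target logCR the way an upstream
#' coverage-based caller would.
#'
#' @param profile Result of [simulate_scna_profile()].
#' @param del_threshold,amp_threshold Mean-logCR cutoffs for the
#'   deletion/amplification labels.
#' @return Segment tibble: `chrom`, `start`, `end`, `exomecnv_call`, `logCR`,
#'   `n_T`.
#' @export
segments_from_truth <- function(profile, del_threshold = -0.15,
                                amp_threshold = 0.15) {
  spec <- profile$spec
  segs <- list()
  for (i in seq_len(nrow(spec$chromosomes))) {
    chr <- spec$chromosomes[i, ]
    lo <- if (chr$acrocentric) chr$p_length + 1 else 1
    hi <- chr$p_length + chr$q_length
    tr <- profile$truth |>
      filter(.data$chrom == chr$name) |>
      arrange(.data$start)
    bounds <- sort(unique(c(lo, tr$start, tr$end + 1, hi + 1)))
    bounds <- bounds[bounds >= lo & bounds <= hi + 1]
    if (length(bounds) < 2) bounds <- c(lo, hi + 1)
    segs[[i]] <- tibble(chrom = chr$name,
                        start = head(bounds, -1),
                        end = tail(bounds, -1) - 1)
  }
  segs <- bind_rows(segs)
  cov <- profile$coverage
  mid <- (cov$start + cov$end) / 2
  segs <- segs |>
    mutate(stats = pmap(list(.data$chrom, .data$start, .data$end),
                        function(ch, s, e) {
      sel <- cov$chrom == ch & mid >= s & mid <= e
      tibble(logCR = if (any(sel)) mean(cov$logCR[sel]) else NA_real_,
             n_T = sum(sel))
    })) |>
    tidyr::unnest("stats") |>
    filter(.data$n_T > 0)
  segs$exomecnv_call <- dplyr::case_when(
    segs$logCR < del_threshold ~ "deletion",
    segs$logCR > amp_threshold ~ "amplification",
    TRUE ~ "neutral"
  )
  select(segs, "chrom", "start", "end", "exomecnv_call", "logCR", "n_T")
}
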