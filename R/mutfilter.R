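#' Read-orientation bias filter
#'
#' Sequencing artifacts (e.g. oxidative damage) show up as an imbalance of
#' read-pair orientations supporting the alternate allele. The designated
#' orientation proportion is `F1R2 / (F1R2 + F2R1)` for indels and for SNVs
#' with reference base G or T, and `F2R1 / (F1R2 + F2R1)` for SNVs with
#' reference base A or C; a variant is dropped when that proportion is below
#' 0.05 or above 0.95. Variants with zero orientation-informative reads are
#' kept but flagged.
#'
#' @param variants Tibble with `ref`, `is_indel`, `f1r2`, `f2r1`.
#' @return `variants` with added `orientation_prop`, `orientation_keep`,
#'   `orientation_flag` (TRUE when no orientation reads were available).
#' @export
orientation_bias_filter <- function(variants) {
  v <- as_tibble(variants)
  tot <- v$f1r2 + v$f2r1
  use_f1r2 <- v$is_indel | v$ref %in% c("G", "T")
  prop <- ifelse(use_f1r2, v$f1r2, v$f2r1) / tot
  v$orientation_prop <- prop
  v$orientation_flag <- tot == 0
  v$orientation_keep <- ifelse(tot == 0, TRUE,
                               prop >= 0.05 & prop <= 0.95)
  v
}

#' Base-quality and allele-frequency filters
#'
#' Applies the post-caller clauses, each with a reason code:
#' `alt_bq` — tumour alternate-allele base quality < 25;
#' `low_vaf` — tumour VAF (computed directly from allelic depths,
#' `alt / (ref + alt)`) < 0.02;
#' `tn_ratio` — when the normal sample has at least one alternate read, the
#' base-quality-weighted allele-frequency ratio
#' `(VAF_t * BQalt_t) / (VAF_n * BQalt_n)` < 4;
#' `ref_bq` — reference base quality < 20 in either sample;
#' `no_coverage` — zero total tumour depth. A variant is kept iff no clause
#' fires (pure conjunction, order-independent).
#'
#' @param variants Tibble with `tumor_ref_ad`, `tumor_alt_ad`,
#'   `normal_ref_ad`, `normal_alt_ad`, `tumor_alt_bq`, `normal_alt_bq`,
#'   `tumor_ref_bq`, `normal_ref_bq`.
#' @return `variants` with `tumor_vaf`, `qual_keep` and a `reasons`
#'   comma-separated reason-code column (empty when kept).
#' @export
quality_vaf_filters <- function(variants) {
  v <- as_tibble(variants)
  tot_t <- v$tumor_ref_ad + v$tumor_alt_ad
  vaf_t <- ifelse(tot_t > 0, v$tumor_alt_ad / tot_t, NA_real_)
  tot_n <- v$normal_ref_ad + v$normal_alt_ad
  vaf_n <- ifelse(tot_n > 0, v$normal_alt_ad / tot_n, 0)
  reasons <- map(seq_len(nrow(v)), function(i) {
    r <- character()
    if (tot_t[i] == 0) return("no_coverage")
    if (!is.na(v$tumor_alt_bq[i]) && v$tumor_alt_bq[i] < 25) {
      r <- c(r, "alt_bq")
    }
    if (vaf_t[i] < 0.02) r <- c(r, "low_vaf")
    if (v$normal_alt_ad[i] >= 1) {
      denom <- vaf_n[i] * v$normal_alt_bq[i]
      ratio <- (vaf_t[i] * v$tumor_alt_bq[i]) / denom
      if (is.finite(ratio) && ratio < 4) r <- c(r, "tn_ratio")
    }
    if (v$tumor_ref_bq[i] < 20 || v$normal_ref_bq[i] < 20) {
      r <- c(r, "ref_bq")
    }
    r
  })
  v$tumor_vaf <- vaf_t
  v$reasons <- vapply(reasons, paste, character(1), collapse = ",")
  v$qual_keep <- v$reasons == ""
  v
}

#' Poisson consistency bound on a population allele frequency
#'
#' Tests whether an observed allele count is consistent with a true
#' population allele frequency of at most `af0`: with `lambda = an * af0`,
#' the variant is flagged germline-like when `P(X >= ac | Poisson(lambda))`
#' falls below `alpha` — the observed count is then too high for a frequency
#' this low at the 95% confidence bound.
#'
#' @param ac Observed allele count (>= 0).
#' @param an Allele number (population sample size x ploidy, > 0).
#' @param af0 Allele-frequency bound (default 1e-4).
#' @param alpha Tail level (default 0.05).
#' @return TRUE when consistent with `AF <= af0`, FALSE when germline-like.
#' @export
#' @examples
#' poisson_af_bound(0, 1e5)      # always consistent
#' poisson_af_bound(4, 10000)    # P(X >= 4 | lambda = 1) ~ 0.019: germline
poisson_af_bound <- function(ac, an, af0 = 1e-4, alpha = 0.05) {
  assert_that(all(an > 0) && all(ac >= 0), "need an > 0 and ac >= 0")
  lambda <- an * af0
  p_ge <- ppois(ac - 1, lambda, lower.tail = FALSE)
  p_ge >= alpha
}

protein_altering_consequences <- function() {
  c("splice_acceptor_variant", "splice_donor_variant", "stop_gained",
    "frameshift_variant", "stop_lost", "start_lost", "inframe_insertion",
    "inframe_deletion", "missense_variant", "protein_altering_variant",
    "splice_region_variant")
}

#' Candidate driver mutation selection
#'
#' All four clauses must hold: (i) a protein-altering consequence (the
#' standard transcript-consequence whitelist, see
#' [protein_altering_consequences()]); (ii) CADD PHRED score strictly above
#' 14.1; (iii) tumour VAF >= 0.1; and (iv) unlikely germline — observed in
#' fewer than two control populations AND every population's allele count is
#' consistent with frequency <= 1e-4 under [poisson_af_bound()]. Variants
#' with a missing CADD score are not selectable and are flagged.
#'
#' @param variants Tibble with `consequence`, `cadd_phred`, `tumor_vaf`,
#'   `n_populations_observed` and a list-column `populations` of tibbles with
#'   `ac`, `an` per population (may be empty).
#' @param whitelist Consequence whitelist.
#' @return `variants` with logical `driver_candidate` and `cadd_missing`.
#' @export
candidate_driver_select <- function(variants,
                                    whitelist =
                                      protein_altering_consequences()) {
  v <- as_tibble(variants)
  cons_ok <- map_lgl(v$consequence, function(x) {
    any(unlist(strsplit(x, "[,&]")) %in% whitelist)
  })
  cadd_missing <- is.na(v$cadd_phred)
  cadd_ok <- !cadd_missing & v$cadd_phred > 14.1
  vaf_ok <- v$tumor_vaf >= 0.1
  germ_ok <- map_lgl(seq_len(nrow(v)), function(i) {
    if (v$n_populations_observed[i] >= 2) return(FALSE)
    pops <- v$populations[[i]]
    if (is.null(pops) || nrow(pops) == 0) return(TRUE)
    all(poisson_af_bound(pops$ac, pops$an))
  })
  v$cadd_missing <- cadd_missing
  v$driver_candidate <- cons_ok & cadd_ok & vaf_ok & germ_ok
  v
}

#' Full somatic-variant filter chain
#'
#' Convenience wrapper composing [orientation_bias_filter()] and
#' [quality_vaf_filters()]; the `reasons` column accounts for every dropped
#' variant.
#'
#' @param variants Variant tibble (see the component filters for columns).
#' @return Tibble with `keep` plus the per-clause columns.
#' @export
filter_somatic_variants <- function(variants) {
  v <- orientation_bias_filter(variants)
  v <- quality_vaf_filters(v)
  v$reasons <- ifelse(!v$orientation_keep,
                      paste0("orientation",
                             ifelse(v$reasons == "", "", ","), v$reasons),
                      v$reasons)
  v$keep <- v$orientation_keep & v$qual_keep
  v
}
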