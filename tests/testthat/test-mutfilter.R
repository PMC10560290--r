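variant_row <- function(...) {
  defaults <- list(
    chrom = "chr1", pos = 100, ref = "C", alt = "T", is_indel = FALSE,
    f1r2 = 20, f2r1 = 20, tumor_ref_ad = 70, tumor_alt_ad = 30,
    normal_ref_ad = 60, normal_alt_ad = 0, tumor_alt_bq = 30,
    normal_alt_bq = 30, tumor_ref_bq = 32, normal_ref_bq = 33,
    consequence = "missense_variant", cadd_phred = 20,
    n_populations_observed = 0,
    populations = list(tibble::tibble(ac = 0, an = 10000))
  )
  args <- list(...)
  defaults[names(args)] <- args
  tibble::as_tibble(defaults)
}

test_that("orientation bias uses the ref-base / indel branch rules", {
  # ref G: F1R2 proportion 1/41 < 0.05 -> drop
  v <- orientation_bias_filter(variant_row(ref = "G", f1r2 = 1, f2r1 = 40))
  expect_false(v$orientation_keep)
  expect_equal(v$orientation_prop, 1 / 41)
  # ref A: F2R1 proportion 0.5 -> keep
  expect_true(orientation_bias_filter(
    variant_row(ref = "A", f1r2 = 20, f2r1 = 20))$orientation_keep)
  # indel uses the F1R2 branch regardless of ref base
  expect_false(orientation_bias_filter(
    variant_row(ref = "A", is_indel = TRUE, f1r2 = 97,
                f2r1 = 3))$orientation_keep)
  # zero orientation reads: kept with flag
  z <- orientation_bias_filter(variant_row(f1r2 = 0, f2r1 = 0))
  expect_true(z$orientation_keep)
  expect_true(z$orientation_flag)
})

test_that("quality/VAF clauses fire at their printed boundaries", {
  # VAF exactly 0.02 is not < 0.02
  v <- quality_vaf_filters(variant_row(tumor_ref_ad = 98, tumor_alt_ad = 2))
  expect_true(v$qual_keep)
  expect_equal(v$tumor_vaf, 0.02)
  expect_false(quality_vaf_filters(
    variant_row(tumor_ref_ad = 990, tumor_alt_ad = 10))$qual_keep)
  # tumour/normal weighted ratio 10 >= 4 -> keep
  r <- quality_vaf_filters(variant_row(
    tumor_ref_ad = 80, tumor_alt_ad = 20, normal_ref_ad = 98,
    normal_alt_ad = 2, tumor_alt_bq = 30, normal_alt_bq = 30))
  expect_true(r$qual_keep)
  # ratio 2 < 4 -> drop with reason tn_ratio
  r2 <- quality_vaf_filters(variant_row(
    tumor_ref_ad = 90, tumor_alt_ad = 10, normal_ref_ad = 95,
    normal_alt_ad = 5, tumor_alt_bq = 30, normal_alt_bq = 30))
  expect_false(r2$qual_keep)
  expect_match(r2$reasons, "tn_ratio")
  # the ratio clause is only evaluated with >= 1 normal alt read
  r3 <- quality_vaf_filters(variant_row(
    tumor_ref_ad = 99, tumor_alt_ad = 3, normal_alt_ad = 0))
  expect_true(r3$qual_keep)
  expect_false(quality_vaf_filters(
    variant_row(tumor_ref_bq = 19))$qual_keep)
  expect_false(quality_vaf_filters(
    variant_row(tumor_alt_bq = 24))$qual_keep)
  nc <- quality_vaf_filters(variant_row(tumor_ref_ad = 0, tumor_alt_ad = 0))
  expect_equal(nc$reasons, "no_coverage")
})

test_that("reason codes partition dropped variants (order-independent)", {
  set.seed(31)
  v <- dplyr::bind_rows(lapply(1:50, function(i) {
    variant_row(tumor_alt_bq = sample(c(20, 30), 1),
                tumor_ref_bq = sample(c(18, 30), 1),
                f1r2 = sample(c(1, 20), 1),
                tumor_alt_ad = sample(c(1, 30), 1),
                tumor_ref_ad = 70)
  }))
  out <- filter_somatic_variants(v)
  expect_true(all(out$keep == (out$reasons == "")))
  expect_true(all(nchar(out$reasons[!out$keep]) > 0))
})

test_that("Poisson allele-frequency bound separates germline from somatic", {
  expect_true(poisson_af_bound(0, 1e5))
  expect_false(poisson_af_bound(4, 10000))   # P(X >= 4 | 1) ~ 0.019
  expect_true(poisson_af_bound(2, 10000))    # P(X >= 2 | 1) ~ 0.264
  # planted germline variants at AF 1e-3 with AN >= 50,000 are removed
  set.seed(32)
  germ_ac <- rpois(500, 50000 * 1e-3)
  expect_gte(mean(!poisson_af_bound(germ_ac, 50000)), 0.99)
  expect_true(all(poisson_af_bound(rep(0, 100), 50000)))
})

test_that("candidate driver selection requires all four clauses", {
  expect_true(candidate_driver_select(variant_row(
    tumor_vaf = 0.3))$driver_candidate)
  expect_false(candidate_driver_select(variant_row(
    tumor_vaf = 0.3, consequence = "synonymous_variant"))$driver_candidate)
  expect_false(candidate_driver_select(variant_row(
    tumor_vaf = 0.3, cadd_phred = 14.1))$driver_candidate)  # strict >
  expect_false(candidate_driver_select(variant_row(
    tumor_vaf = 0.09))$driver_candidate)
  expect_true(candidate_driver_select(variant_row(
    tumor_vaf = 0.1))$driver_candidate)                     # >= 0.1
  expect_false(candidate_driver_select(variant_row(
    tumor_vaf = 0.3, n_populations_observed = 2))$driver_candidate)
  expect_false(candidate_driver_select(variant_row(
    tumor_vaf = 0.3,
    populations = list(tibble::tibble(ac = 40, an = 10000))
  ))$driver_candidate)
  flagged <- candidate_driver_select(variant_row(tumor_vaf = 0.3,
                                                 cadd_phred = NA))
  expect_false(flagged$driver_candidate)
  expect_true(flagged$cadd_missing)
})
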