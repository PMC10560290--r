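test_that("BAF site filter applies inclusive blood-evidence bounds", {
  sites <- tibble::tibble(
    chrom = "chr1", pos = 1:5,
    tumor_baf = 0.5, blood_baf = c(1 / 3, 0.5, 0.7, 0.5, 2 / 3),
    tumor_depth = 50, blood_depth = c(8, 7, 50, 50, 8)
  )
  kept <- filter_baf_sites(sites)
  expect_equal(kept$pos, c(1, 4, 5))
})

test_that("devBAF folds around 0.5 before averaging", {
  sites <- tibble::tibble(chrom = "chr1", pos = c(10, 20),
                          tumor_baf = c(0.3, 0.7),
                          blood_baf = 0.5, tumor_depth = 50,
                          blood_depth = 50)
  d <- compute_devbaf(sites, list(chrom = "chr1", start = 1, end = 100))
  expect_equal(d$M_dev, 0.2)
  expect_equal(d$SD_dev, 0)
  empty <- compute_devbaf(sites, list(chrom = "chr1", start = 200,
                                      end = 300))
  expect_false(empty$defined)
  expect_true(is.na(empty$M_dev))
})

test_that("Ansari-Bradley matches exhaustive enumeration and conventions", {
  p <- ansari_bradley_scale_test(c(0.01, 0.25, 0.26), c(0.10, 0.12, 0.14))
  expect_equal(p, ab_enumeration_oracle(c(0.01, 0.25, 0.26),
                                        c(0.10, 0.12, 0.14)))
  # identical multisets carry no scale signal
  expect_gte(ansari_bradley_scale_test(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3)),
             0.5)
  expect_equal(ansari_bradley_scale_test(rep(0.2, 4), rep(0.2, 5)), 1)
  # property: exact path == enumeration for random tied/untied inputs
  set.seed(11)
  for (rep in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- round(runif(n1, 0, 0.5), 2)
    y <- round(runif(n2, 0, 0.5), 2)
    expect_equal(ansari_bradley_scale_test(x, y),
                 ab_enumeration_oracle(x, y))
  }
})

test_that("Ansari-Bradley large-sample path tracks ansari.test and has power", {
  set.seed(12)
  x <- rnorm(40, 0.2, 0.09); y <- rnorm(40, 0.2, 0.03)
  mine <- ansari_bradley_scale_test(abs(x - 0.2) + 0.2, abs(y - 0.2) + 0.2)
  ref <- suppressWarnings(
    stats::ansari.test(abs(x - 0.2) + 0.2, abs(y - 0.2) + 0.2,
                       alternative = "greater")$p.value
  )
  expect_equal(mine, ref, tolerance = 0.02)
  # power: 3x scale difference detected in >= 90% of seeded replicates
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    tu <- 0.2 + rnorm(50, 0, 0.15); bl <- 0.2 + rnorm(50, 0, 0.05)
    ansari_bradley_scale_test(tu, bl) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("devBAF Z test follows the normal reference and conventions", {
  expect_equal(devbaf_z_test(c(0, 0)), 1)              # M_dev = 0, SD = 0
  expect_equal(devbaf_z_test(c(0.1, 0.2, 0.3)),        # Z = 2
               2 * (1 - pnorm(2)))
  expect_equal(devbaf_z_test(c(0.2, 0.2)), 0)          # shifted, SD = 0
  expect_equal(devbaf_z_test(c(0.1, 0.3)),
               devbaf_z_test(c(-0.1, -0.3) + 0.4))     # |Z| only
})

test_that("low-complexity exclusion uses a strict 70% bound", {
  seg <- tibble::tibble(chrom = "chr1", start = 1, end = 100)
  m70 <- tibble::tibble(chrom = "chr1", start = 1, end = 70)
  m71 <- tibble::tibble(chrom = "chr1", start = 1, end = 71)
  expect_true(exclude_low_complexity(seg, m70)$kept)
  expect_false(exclude_low_complexity(seg, m71)$kept)
  expect_true(exclude_low_complexity(seg, m71[0, ])$kept)
})

test_that("BED reader converts coordinates and names malformed lines", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t150\t200"), f)
  b <- read_bed(f)
  expect_equal(b$start, c(1, 151))
  expect_equal(b$end, c(100, 200))
  writeLines(c("chr1\t0\t100", "chr1\tnope"), f)
  expect_error(read_bed(f), "line 2")
})

test_that("segment merging follows the tolerance and few-site rules", {
  sites <- tibble::tibble(
    chrom = "chr1",
    pos = c(seq(10, 90, 10), seq(110, 190, 10)),
    # segment 1: M_dev = 0.20, SD_dev ~ 0.053; segment 2: M_dev = 0.22
    tumor_baf = 0.5 + c(rep(c(-0.15, 0.25), length.out = 9),
                        rep(c(-0.17, 0.27), length.out = 9)),
    blood_baf = 0.5, tumor_depth = 50, blood_depth = 50
  )
  segs <- tibble::tibble(
    chrom = "chr1", start = c(1, 101), end = c(100, 200),
    exomecnv_call = "deletion", logCR = c(-0.52, -0.50), n_T = c(10, 10)
  )
  merged <- merge_segments(segs, sites)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$end, 200)
  expect_equal(merged$n, 18)
  # deletion next to amplification never merges
  segs2 <- dplyr::mutate(segs,
                         exomecnv_call = c("deletion", "amplification"))
  expect_equal(nrow(merge_segments(segs2, sites)), 2)
  # few-site override: neutral segments with n = 2 and n = 1 always merge
  sparse <- sites[c(1, 2, 10), ]
  segs3 <- tibble::tibble(chrom = "chr1", start = c(1, 101),
                          end = c(100, 200), exomecnv_call = "neutral",
                          logCR = c(0.3, -0.3), n_T = c(5, 5))
  expect_equal(nrow(merge_segments(segs3, sparse)), 1)
  # devBAF tolerance blocks merging when means differ beyond half the SD
  segs4 <- segs
  sites4 <- sites
  sites4$tumor_baf[10:18] <- 0.5 + rep(c(-0.45, 0.45), length.out = 9)
  expect_equal(nrow(merge_segments(segs4, sites4)), 2)
  expect_error(merge_segments(segs[2:1, ], sites), "sorted")
})

test_that("classification reproduces the rule tables at their boundaries", {
  row <- function(call, P_ABT = 1, P_dev = 1, M_dev = 0, n = 50, n_T = 50,
                  logCR = 0) {
    tibble::tibble(exomecnv_call = call, P_ABT = P_ABT, P_dev = P_dev,
                   M_dev = M_dev, n = n, n_T = n_T, logCR = logCR)
  }
  cls <- function(...) classify_segment(row(...))$final_call
  expect_equal(cls("deletion", P_ABT = 0.01, P_dev = 0.05, M_dev = 0.12),
               "LOSS")
  expect_equal(cls("deletion", P_ABT = 0.05, P_dev = 0.04, M_dev = 0.15),
               "LOSS")
  expect_equal(cls("deletion", P_ABT = 0.05, P_dev = 0.04, M_dev = 0.149),
               "NEUTRAL")
  expect_equal(cls("deletion", n = 2, n_T = 10, M_dev = 0.17), "LOSS")
  expect_equal(cls("deletion", n = 0, n_T = 10, M_dev = 0.17), "NEUTRAL")
  expect_equal(cls("neutral", P_ABT = 0.10, P_dev = 0.01, M_dev = 0.25),
               "CN-LOH")
  expect_equal(cls("neutral", P_ABT = 0.01, P_dev = 0.09, M_dev = 0.15),
               "CN-LOH")
  expect_equal(cls("neutral", P_ABT = 0.10, P_dev = 0.01, M_dev = 0.19),
               "NEUTRAL")
  expect_equal(cls("amplification", n_T = 120, logCR = log2(1.35)), "GAIN")
  expect_equal(cls("amplification", n_T = 99, logCR = log2(1.35)),
               "NEUTRAL")
  expect_equal(cls("amplification", P_ABT = 0.009, n = 20, logCR = 1.12),
               "GAIN")
  expect_equal(cls("amplification", P_ABT = 0.009, n = 19, logCR = 1.12),
               "NEUTRAL")
  expect_equal(cls("amplification", P_ABT = 0.04, P_dev = 0.09), "GAIN")
  expect_equal(cls("amplification", P_ABT = 0.06, P_dev = 0.04,
                   M_dev = 0.1), "GAIN")
})

test_that("GAIN-filtered rescue and indeterminate handling work", {
  seg <- tibble::tibble(exomecnv_call = "amplification", P_ABT = 0.5,
                        P_dev = 0.5, M_dev = 0.09, n = 30, n_T = 70,
                        logCR = 0.2)
  expect_equal(classify_segment(seg)$final_call, "NEUTRAL")
  expect_equal(classify_segment(seg, gain_filtered = TRUE)$final_call,
               "GAIN-filtered")
  expect_equal(classify_segment(dplyr::mutate(seg, n_T = 59),
                                gain_filtered = TRUE)$final_call, "NEUTRAL")
  # missing statistics never give a silent NEUTRAL
  nas <- tibble::tibble(exomecnv_call = "deletion", P_ABT = NA, P_dev = NA,
                        M_dev = NA, n = 0, n_T = 5, logCR = -1)
  expect_equal(classify_segment(nas)$final_call, "indeterminate")
  # but a clause not needing BAF statistics can still fire
  cov_only <- tibble::tibble(exomecnv_call = "amplification", P_ABT = NA,
                             P_dev = NA, M_dev = NA, n = 0, n_T = 150,
                             logCR = log2(1.4))
  expect_equal(classify_segment(cov_only)$final_call, "GAIN")
})

test_that("classification is total and deterministic over clause grids", {
  grid <- tidyr::expand_grid(
    exomecnv_call = c("deletion", "amplification", "neutral"),
    P_ABT = c(0.009, 0.049, 0.05, 0.5),
    P_dev = c(0.009, 0.049, 0.099, 0.5),
    M_dev = c(0.05, 0.1, 0.15, 0.17, 0.2),
    n = c(1, 2, 20), n_T = c(5, 60, 100), logCR = c(0.1, 1.12)
  )
  r1 <- classify_segment(grid, gain_filtered = TRUE)$final_call
  r2 <- classify_segment(grid, gain_filtered = TRUE)$final_call
  expect_identical(r1, r2)
  expect_true(all(r1 %in% c("LOSS", "GAIN", "GAIN-filtered", "CN-LOH",
                            "NEUTRAL")))
})

test_that("sample QC fires on scatter and fragmentation clauses", {
  seg_ok <- tibble::tibble(n_T = rep(50, 100))
  set.seed(1)
  base <- rnorm(1000, 0, 0.05)
  expect_equal(sample_qc(base * 5, seg_ok)$status, "fail")     # MAD > 0.2
  seg_frag <- tibble::tibble(n_T = c(rep(5, 25), rep(50, 75)))
  expect_equal(sample_qc(base * 3.3, seg_frag)$status, "fail") # clause 2
  expect_equal(sample_qc(base * 2, seg_ok)$status, "pass")
  expect_equal(sample_qc(base * 3.3, seg_ok)$status, "pass")
})

test_that("arm event sizes sum per type and split at the centromere", {
  sp <- genome_spec()   # chr1: p 40 Mb, q 60 Mb
  segs <- tibble::tibble(
    chrom = "chr1",
    start = c(1e6, 10e6, 50e6, 35e6), end = c(6e6, 15e6, 55e6, 45e6),
    final_call = c("LOSS", "LOSS", "GAIN", "LOSS")
  )
  ae <- arm_event_sizes(segs, sp)
  p_loss <- ae$total_length[ae$arm == "p" & ae$type == "LOSS"]
  q_loss <- ae$total_length[ae$arm == "q" & ae$type == "LOSS"]
  q_gain <- ae$total_length[ae$arm == "q" & ae$type == "GAIN"]
  expect_equal(p_loss, (5e6 + 1) * 3)              # centromere split at 40 Mb
  expect_equal(q_loss, 5e6)
  expect_equal(q_gain, 5e6 + 1)
  # same arm, different types: separate events, the small ones not large
  expect_true(ae$is_large[ae$arm == "p" & ae$type == "LOSS"])  # 15 Mb
  expect_false(ae$is_large[ae$arm == "q" & ae$type == "GAIN"])
  expect_false(ae$is_large[ae$arm == "q" & ae$type == "LOSS"])
  big <- tibble::tibble(chrom = "chr1", start = c(41e6, 60e6),
                        end = c(46e6, 65e6), final_call = "LOSS")
  expect_true(arm_event_sizes(big, sp)$is_large)    # 2 x 5 Mb + 2 bp > 9 Mb
  exact9 <- tibble::tibble(chrom = "chr1", start = 41e6, end = 41e6 + 9e6 - 1,
                           final_call = "LOSS")
  expect_false(arm_event_sizes(exact9, sp)$is_large)  # strict >
})

test_that("whole-chromosome categorization follows the 50%/80% rules", {
  sp <- genome_spec()
  ae <- tibble::tibble(chrom = "chr1", arm = c("p", "q"), type = "GAIN",
                       total_length = c(24e6, 33e6),
                       frac_arm = c(0.6, 0.55), is_large = TRUE)
  cat1 <- categorize_whole_chromosome(ae, sp)
  expect_equal(cat1$category, "1-GAIN")
  expect_true(cat1$whole_chromosome)
  expect_false(cat1$covers_80pct)    # 57 of 100 Mb
  only_q <- tibble::tibble(chrom = "chr1", arm = "q", type = "GAIN",
                           total_length = 54e6, frac_arm = 0.9,
                           is_large = TRUE)
  expect_equal(categorize_whole_chromosome(only_q, sp)$category, "1q-GAIN")
  acro <- tibble::tibble(chrom = "chr3", arm = "q", type = "GAIN",
                         total_length = 42.5e6, frac_arm = 0.85,
                         is_large = TRUE)
  cat3 <- categorize_whole_chromosome(acro, sp)
  expect_equal(cat3$category, "3-GAIN")
  expect_true(cat3$covers_80pct)
})

test_that("shared neutral interval is the cross-sample intersection", {
  iv <- tibble::tibble(
    sample = c("a", "b"), chrom = "chr2",
    start = c(219800000, 219825716), end = c(219950000, 220000000)
  )
  region <- list(chrom = "chr2", start = 219650000, end = 220150000)
  res <- shared_neutral_interval(iv, region)
  expect_equal(res$start, 219825716)
  expect_equal(res$end, 219950000)
  # one sample deleted across the region empties the intersection
  iv2 <- dplyr::bind_rows(iv, tibble::tibble(sample = "c", chrom = "chr2",
                                             start = 1, end = 2))
  expect_equal(nrow(shared_neutral_interval(iv2, region)), 0)
})

test_that("planted LOSS/GAIN/CN-LOH profiles are recovered end to end", {
  b <- simulate_scna_benchmark(101)
  calls <- call_scna(segments_from_truth(b), b$baf)
  m <- scna_recovery_metrics(calls, b$truth)
  expect_gte(m$sensitivity, 0.8)
  expect_gte(m$precision, 0.8)
  # merging preserves covered bases and never crosses chromosomes
  segs <- segments_from_truth(b)
  sites <- filter_baf_sites(b$baf)
  merged <- merge_segments(segs, sites)
  expect_equal(sum(merged$end - merged$start + 1),
               sum(segs$end - segs$start + 1))
  expect_identical(merge_segments(merged[names(segs)], sites)[names(segs)],
                   merged[names(segs)])
})

test_that("naive segmentation finds planted mean shifts for demos", {
  sp <- genome_spec()
  ev <- tibble::tibble(chrom = "chr1", start = 10e6, end = 40e6,
                       type = "LOSS", purity = 0.9, extra_copies = 1)
  p <- simulate_scna_profile(sp, ev, noise_sd = 0.1, seed = 13)
  segs <- naive_segment(p$coverage)
  del <- segs[segs$exomecnv_call == "deletion", ]
  expect_equal(nrow(del), 1)
  expect_lt(abs(del$start - 10e6), 5e5)
  expect_lt(abs(del$end - 40e6), 5e5)
  # total covered targets preserved
  expect_equal(sum(segs$n_T), nrow(p$coverage))
})
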