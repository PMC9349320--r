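# small hand-built patient: 2 samples, pure diploid genome, so that
# CCF equals 2 * VAF and thresholds can be steered via read counts
toy_patient <- function(rows) {
  samples <- data.frame(sample_id = c("S1", "S2"), patient_id = "P1",
                        site_class = c("iliac_crest_left",
                                       "iliac_crest_right"),
                        anatomical_label = "", timepoint = 0,
                        purity = 1)
  variants <- data.frame(variant_id = rows$id, chrom = rows$chrom,
                         pos = rows$pos, ref = "C", alt = "A",
                         gene = "", context96 = 0L,
                         in_ig_locus = rows$ig)
  observations <- rbind(
    data.frame(variant_id = rows$id, sample_id = "S1",
               alt_reads = rows$a1, depth = rows$d1,
               qc_pass = rows$qc1),
    data.frame(variant_id = rows$id, sample_id = "S2",
               alt_reads = rows$a2, depth = rows$d2, qc_pass = TRUE))
  list(variants = variants, observations = observations,
       samples = samples, segments = diploid_segments(c("S1", "S2")))
}

test_that("inclusion filters apply the printed thresholds in order", {
  rows <- data.frame(
    id = c("ok", "lowdep", "depth20", "badqc", "ig", "lowccf",
           "edgeccf"),
    chrom = "1", pos = 1000 + seq_len(7), ig = FALSE,
    a1 = c(30, 30, 30, 30, 30, 5, 10),   # depth 100 -> ccf = 2*vaf
    d1 = c(100, 100, 100, 100, 100, 100, 100),
    a2 = c(30, 30, 30, 30, 30, 5, 2),
    d2 = c(100, 19, 20, 100, 100, 100, 100),
    qc1 = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  rows$ig[rows$id == "ig"] <- TRUE
  p <- toy_patient(rows)
  f <- apply_inclusion_filters(p$variants, p$observations, p$samples,
                               p$segments)
  out <- setNames(f$report$outcome, f$report$variant_id)
  expect_equal(out[["ok"]], "retained")
  expect_equal(out[["lowdep"]], "fail_coverage")   # 19 < 20
  expect_equal(out[["depth20"]], "fail_coverage")  # exceeding 20 is strict
  expect_equal(out[["badqc"]], "fail_quality")
  expect_equal(out[["ig"]], "fail_ig_locus")
  expect_equal(out[["lowccf"]], "fail_ccf_floor")  # max ccf 0.10
  expect_equal(out[["edgeccf"]], "retained")       # max ccf 0.20 exactly
  expect_equal(sum(f$counts), nrow(p$variants))
})

test_that("a variant above the CCF floor in one sample only is kept", {
  # ccf 0.25 in S1, 0.05 in S2
  rows <- data.frame(id = "v", chrom = "1", pos = 500, ig = FALSE,
                     a1 = 25, d1 = 200, a2 = 5, d2 = 200, qc1 = TRUE)
  p <- toy_patient(rows)
  f <- apply_inclusion_filters(p$variants, p$observations, p$samples,
                               p$segments)
  expect_equal(f$retained, "v")
})

test_that("empty sample set is a configuration error", {
  rows <- data.frame(id = "v", chrom = "1", pos = 500, ig = FALSE,
                     a1 = 25, d1 = 100, a2 = 5, d2 = 100, qc1 = TRUE)
  p <- toy_patient(rows)
  expect_error(apply_inclusion_filters(p$variants, p$observations,
                                       p$samples[0, ], p$segments),
               class = "mmclone_config_error")
})

test_that("filtering is monotone in its thresholds", {
  set.seed(11)
  n <- 60
  rows <- data.frame(id = paste0("v", 1:n), chrom = "1",
                     pos = 1:n * 10, ig = FALSE,
                     a1 = rbinom(n, 60, runif(n, 0.02, 0.5)),
                     d1 = sample(15:90, n, TRUE),
                     a2 = rbinom(n, 60, runif(n, 0.02, 0.5)),
                     d2 = sample(15:90, n, TRUE), qc1 = TRUE)
  rows$a1 <- pmin(rows$a1, rows$d1); rows$a2 <- pmin(rows$a2, rows$d2)
  p <- toy_patient(rows)
  strict <- apply_inclusion_filters(p$variants, p$observations,
                                    p$samples, p$segments, mm_config())
  relaxed <- apply_inclusion_filters(
    p$variants, p$observations, p$samples, p$segments,
    mm_config(min_depth_exclusive = 10, ccf_floor = 0.05))
  expect_true(all(strict$retained %in% relaxed$retained))
})

test_that("detection needs at least two variant reads", {
  expect_equal(detection_status(c(0, 1, 2, 5)),
               c("undetected", "undetected", "detected", "detected"))
})

test_that("CNA size gates follow the 5 Mb and 1 Mb thresholds", {
  seg <- data.frame(sample = "S1", chrom = c("1", "1", "17", "17"),
                    start = 1L,
                    end = c(4900000L, 5000000L, 1200000L, 1200000L),
                    total_cn = c(3L, 3L, 1L, 3L),
                    minor_cn = c(1L, 1L, 0L, 1L))
  seg$length_bp <- seg$end - seg$start + 1L
  glob <- filter_cna(seg, "global")
  expect_equal(glob$end, 5000000L)  # 4.9 Mb dropped, 5.0 Mb kept
  drivers <- data.frame(chrom = "17", start = 1000000L,
                        end = 1100000L)
  drv <- filter_cna(seg, "driver", drivers)
  expect_equal(nrow(drv), 1)
  expect_equal(drv$total_cn, 1L)    # the 1.2 Mb gain is not a deletion
  expect_error(filter_cna(seg, "driver"),
               class = "mmclone_config_error")
})
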