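mk_fu_samples <- function(site_tp) {
  # site_tp: data.frame(sample_id, site_class, timepoint)
  data.frame(sample_id = site_tp$sample_id, patient_id = "P1",
             site_class = site_tp$site_class, anatomical_label = "",
             timepoint = site_tp$timepoint, purity = 0.9)
}

test_that("relapse branches are the root children seen at follow-up", {
  cen <- rbind(R = c(1, 1, 1), A = c(0.2, 0.9, 0.9),
               B = c(0.6, 0.0, 0.15))
  colnames(cen) <- c("t0", "t1a", "t1b")
  tr <- build_clone_tree(cen)
  samples <- mk_fu_samples(data.frame(
    sample_id = c("t0", "t1a", "t1b"),
    site_class = c("iliac_crest_left", "iliac_crest_left",
                   "focal_lesion"),
    timepoint = c(0, 1, 1)))
  br <- count_relapse_branches(tr, samples)
  expect_equal(br, "A")   # B only 0.15 at follow-up: below threshold

  expect_error(count_relapse_branches(tr, samples[1, ]),
               class = "mmclone_domain_error")
})

test_that("a trunk-only relapse counts as one branch", {
  cen <- rbind(R = c(1, 1), A = c(0.6, 0.1))
  colnames(cen) <- c("t0", "t1")
  tr <- build_clone_tree(cen)
  samples <- mk_fu_samples(data.frame(
    sample_id = c("t0", "t1"),
    site_class = "iliac_crest_left", timepoint = c(0, 1)))
  expect_equal(count_relapse_branches(tr, samples), "R")
})

test_that("the three patterns are assigned by branch count and co-detection", {
  samples2 <- mk_fu_samples(data.frame(
    sample_id = c("t0", "fu1", "fu2"),
    site_class = c("iliac_crest_left", "iliac_crest_left",
                   "iliac_crest_left"),
    timepoint = c(0, 1, 2)))

  # one relapse branch -> single-cell expansion
  cen1 <- rbind(R = c(1, 1, 1), A = c(0.1, 0.9, 1.0),
                B = c(0.6, 0.0, 0.0))
  colnames(cen1) <- samples2$sample_id
  p1 <- classify_pattern(build_clone_tree(cen1), samples2)
  expect_equal(p1$pattern, "single_cell_expansion")
  expect_equal(p1$n_relapse_branches, 1)

  # two branches co-detected in one sample -> coexisting
  cen2 <- rbind(R = c(1, 1, 1), A = c(0.3, 0.6, 0.25),
                B = c(0.1, 0.3, 0.7))
  colnames(cen2) <- samples2$sample_id
  p2 <- classify_pattern(build_clone_tree(cen2), samples2)
  expect_equal(p2$pattern, "coexisting_subclones")
  expect_true(p2$mixed_features$co_located)

  # two branches at disjoint sites -> alternating spatial dominance
  samples3 <- mk_fu_samples(data.frame(
    sample_id = c("t0", "ic1", "fl1"),
    site_class = c("iliac_crest_left", "iliac_crest_left",
                   "focal_lesion"),
    timepoint = c(0, 1, 1)))
  cen3 <- rbind(R = c(1, 1, 1), A = c(0.15, 0.9, 0.0),
                B = c(0.1, 0.0, 0.85))
  colnames(cen3) <- samples3$sample_id
  p3 <- classify_pattern(build_clone_tree(cen3), samples3)
  expect_equal(p3$pattern, "alternating_spatial_dominance")
  expect_setequal(p3$mixed_features$solo_branches, c("A", "B"))
})

test_that("pattern labels are exhaustive and mutually exclusive", {
  set.seed(23)
  samples <- mk_fu_samples(data.frame(
    sample_id = c("t0", "fu1", "fu2"),
    site_class = c("iliac_crest_left", "iliac_crest_left",
                   "focal_lesion"),
    timepoint = c(0, 1, 1)))
  for (i in 1:40) {
    a <- round(runif(3, 0, 0.6), 2); b <- round(runif(3, 0, 0.35), 2)
    cen <- rbind(R = c(1, 1, 1), A = a, B = b)
    colnames(cen) <- samples$sample_id
    p <- classify_pattern(build_clone_tree(cen), samples)
    expect_true(p$pattern %in% c("single_cell_expansion",
                                 "coexisting_subclones",
                                 "alternating_spatial_dominance"))
    expect_equal(p$pattern == "single_cell_expansion",
                 p$n_relapse_branches == 1)
  }
})

test_that("patient summaries keep consistent subclone bookkeeping", {
  sim <- simulate_patient(sim_config(), seed = 30, patient_id = "P9",
                          scenario = "coexisting")
  an <- analyze_patient(sim$variants, sim$observations, sim$samples,
                        sim$segments)
  rep_ <- an$report
  expect_equal(rep_$patient_id, "P9")
  per_tp <- attr(rep_, "per_timepoint")
  expect_gte(rep_$subclones_total, max(per_tp))
  expect_equal(rep_$subclones_max_timepoint, max(per_tp))
  expect_equal(rep_$pattern, an$pattern$pattern)
  expect_equal(rep_$n_sweeps, nrow(an$sweeps))
})

test_that("cohort reports produce one row per patient", {
  cfg <- sim_config(n_patients = 3, scenario = "mixed")
  coh <- simulate_cohort(cfg, seed = 3)
  reports <- do.call(rbind, lapply(names(coh$patients), function(pid) {
    s <- coh$patients[[pid]]
    analyze_patient(s$variants, s$observations, s$samples,
                    s$segments)$report
  }))
  expect_equal(nrow(reports), 3)
  expect_setequal(reports$patient_id, names(coh$patients))
})
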