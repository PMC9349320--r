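test_that("context binning is pyrimidine-normalized and conservative", {
  expect_equal(context96_index("C", "A", "A", "A"), 0L)
  # G>T with T flanks is the reverse complement of A[C>A]A
  expect_equal(context96_index("G", "T", "T", "T"), 0L)
  expect_equal(context96_index("T", "C", "G", "C"),
               match("G[T>C]C", sbs96_contexts()) - 1L)

  cnt <- count_contexts(data.frame(ref = "C", alt = "A", p5 = "A",
                                   p3 = "A"))
  expect_equal(sum(cnt), 1)
  expect_equal(unname(cnt[["A[C>A]A"]]), 1)

  df <- data.frame(ref = c("C", "G", "N"), alt = c("A", "T", "A"),
                   p5 = c("A", "T", "A"), p3 = c("A", "T", "A"))
  expect_warning(cnt2 <- count_contexts(df), "skipped")
  expect_equal(sum(cnt2), 2)
  expect_equal(unname(cnt2[["A[C>A]A"]]), 2)

  set.seed(6)
  idx <- sample(0:95, 100, TRUE)
  expect_equal(sum(count_contexts(idx)), 100)
})

test_that("a pure signature is recovered with exposure one", {
  cat_ <- default_signature_catalog()
  for (j in c(1, 3, 8)) {
    f <- fit_exposures(960 * cat_$profiles[, j], cat_)
    expect_lt(abs(f$exposures[[cat_$names[j]]] - 1), 1e-6)
  }
  cat1 <- sig_catalog(cat_$profiles[, 1, drop = FALSE], "only")
  expect_equal(fit_exposures(rep(1, 96), cat1)$exposures,
               c(only = 1))
})

test_that("two-signature mixtures match the grid-search oracle", {
  cat2 <- two_sig_catalog()
  mix <- 0.7 * cat2$profiles[, 1] + 0.3 * cat2$profiles[, 2]
  f <- fit_exposures(10000 * mix, cat2)
  orc <- grid_fit_two(10000 * mix, cat2)
  expect_lt(max(abs(f$exposures - c(0.7, 0.3))), 0.01)
  expect_lt(max(abs(f$exposures - orc)), 0.0015)

  # stochastic draws: the fit equals the oracle on every draw, and the
  # recovery error sits inside the sampling tolerance on average
  errs <- vapply(1:10, function(s) {
    cnt <- with_seed(s, as.numeric(rmultinom(1, 500, mix)))
    f2 <- fit_exposures(cnt, cat2)
    expect_lt(max(abs(f2$exposures - grid_fit_two(cnt, cat2))), 0.0015)
    max(abs(f2$exposures - c(0.7, 0.3)))
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
})

test_that("exposure fits are invariant to count scaling", {
  cat_ <- default_signature_catalog()
  cnt <- with_seed(12, as.numeric(rmultinom(
    1, 300, cat_$profiles %*% rep(1 / 8, 8))))
  f1 <- fit_exposures(cnt, cat_)
  f3 <- fit_exposures(3 * cnt, cat_)
  expect_lt(max(abs(f1$exposures - f3$exposures)), 1e-6)
})

test_that("the presence test detects a planted treatment signature", {
  cat_ <- default_signature_catalog()
  bg <- as.numeric(cat_$profiles[, 1:7] %*%
                     c(.25, .10, .35, .10, .10, .05, .05))
  mix <- 0.7 * bg + 0.3 * cat_$profiles[, "SBS-MM1-like"]
  cnt <- with_seed(5, as.numeric(rmultinom(1, 100, mix)))
  pt <- presence_test(cnt, cat_, "SBS-MM1-like", B = 400, seed = 5)
  expect_lt(pt$p, 0.05)
  expect_gt(pt$lr, 0)

  # counts exactly on the background mixture: the full fit gains
  # nothing from the target, LR ~ 0, p ~ 1
  cnt0 <- 400 * bg
  pt0 <- presence_test(cnt0, cat_, "SBS-MM1-like", B = 100, seed = 2)
  expect_lt(pt0$lr, 1e-4)
  expect_gt(pt0$p, 0.9)

  expect_error(presence_test(cnt, cat_, "nope"),
               class = "mmclone_domain_error")
})

test_that("single-cell-expansion flagging honors the 25-mutation gate", {
  cat_ <- default_signature_catalog()
  bg <- as.numeric(cat_$profiles[, 1:7] %*%
                     c(.25, .10, .35, .10, .10, .05, .05))
  mix <- 0.67 * bg + 0.33 * cat_$profiles[, "SBS-MM1-like"]
  cfg <- mm_config(bootstrap_B = 300)

  small <- with_seed(9, as.numeric(rmultinom(1, 24, mix)))
  expect_equal(flag_single_cell_expansion(small, cat_, "SBS-MM1-like",
                                          cfg)$status,
               "not_evaluable")

  big <- with_seed(9, as.numeric(rmultinom(1, 120, mix)))
  f <- flag_single_cell_expansion(big, cat_, "SBS-MM1-like", cfg)
  expect_equal(f$status, "flagged")
  expect_lt(f$presence_p, 0.05)

  null_ <- with_seed(10, as.numeric(rmultinom(1, 120, bg)))
  f0 <- flag_single_cell_expansion(null_, cat_, "SBS-MM1-like", cfg)
  expect_true(f0$status %in% c("flagged", "not_flagged"))
  expect_equal(f0$n, 120)
})

test_that("presence p-values fall (stochastically) with planted exposure", {
  cat_ <- default_signature_catalog()
  bg <- as.numeric(cat_$profiles[, 1:7] %*%
                     c(.25, .10, .35, .10, .10, .05, .05))
  med_p <- vapply(c(0, 0.2, 0.4), function(w) {
    mix <- (1 - w) * bg + w * cat_$profiles[, "SBS-MM1-like"]
    ps <- vapply(1:15, function(s) {
      cnt <- with_seed(100 + s, as.numeric(rmultinom(1, 200, mix)))
      presence_test(cnt, cat_, "SBS-MM1-like", B = 150,
                    seed = s)$p
    }, numeric(1))
    median(ps)
  }, numeric(1))
  expect_true(med_p[2] < med_p[1])
  expect_true(med_p[3] <= med_p[2])
  expect_lt(med_p[3], 0.05)
})
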