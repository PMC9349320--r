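test_that("pair classification follows the 3x and 60% rules", {
  expect_equal(classify_pair(0.50, 0.45, TRUE, TRUE), "shared")
  expect_equal(classify_pair(0.60, 0.15, TRUE, TRUE),
               "shared_diff_clonal")    # ratio 4, max >= 0.60
  expect_equal(classify_pair(0.45, 0.15, TRUE, TRUE),
               "shared_diff_subclonal") # ratio exactly 3, max < 0.60
  expect_equal(classify_pair(0.60, 0.20, TRUE, TRUE),
               "shared_diff_clonal")    # boundary ratio exactly 3
  expect_equal(classify_pair(0.70, 0, TRUE, FALSE), "unshared_major")
  expect_equal(classify_pair(0.59, 0, TRUE, FALSE), "unshared_minor")
  expect_equal(classify_pair(0, 0.60, FALSE, TRUE), "unshared_major")
  expect_error(classify_pair(0.1, 0.1, FALSE, FALSE),
               class = "mmclone_domain_error")
})

test_that("classification is symmetric up to the detecting sample", {
  set.seed(7)
  for (i in 1:200) {
    ca <- round(runif(1), 2); cb <- round(runif(1), 2)
    da <- runif(1) < 0.8; db <- runif(1) < 0.8
    if (!da && !db) da <- TRUE
    expect_identical(classify_pair(ca, cb, da, db),
                     classify_pair(cb, ca, db, da))
  }
})

test_that("pair summaries partition classifiable mutations exactly", {
  sim <- simulate_patient(sim_config(), seed = 5, patient_id = "P1",
                          scenario = "alternating")
  m <- build_ccf_matrix(sim$variants, sim$observations, sim$samples,
                        sim$segments)
  s <- sim$samples$sample_id[1:2]
  ps <- pair_summary(s[1], s[2], m)
  expect_equal(sum(ps$counts), ps$n)
  expect_equal(sum(ps$proportions), 1, tolerance = 1e-9)
  expect_equal(nrow(ps$classifications), ps$n)
  # rational arithmetic on counts: proportions derived exactly
  expect_equal(unname(ps$proportions),
               unname(ps$counts / sum(ps$counts)))
})

test_that("an empty pair yields the empty-summary sentinel", {
  m <- data.frame(variant_id = "v1", sample_id = c("S1", "S2"),
                  f_s = 0, n_mut = 0, n_chr = 1L, ccf = 0,
                  capped = FALSE, evaluable = TRUE, detected = FALSE,
                  alt_reads = 0L, depth = 50L, purity = 1,
                  total_cn = 2L)
  ps <- pair_summary("S1", "S2", m)
  expect_equal(ps$n, 0L)
  expect_true(is.na(ps$proportion_shared))
})

test_that("toy proportions come out as count ratios", {
  # 8 shared + 2 unshared-minor out of 10
  m <- data.frame(
    variant_id = rep(paste0("v", 1:10), 2),
    sample_id = rep(c("S1", "S2"), each = 10),
    ccf = c(rep(0.5, 10), c(rep(0.5, 8), 0, 0)),
    evaluable = TRUE,
    detected = c(rep(TRUE, 10), rep(TRUE, 8), FALSE, FALSE))
  ps <- pair_summary("S1", "S2", m)
  expect_equal(ps$proportion_shared, 0.8)
  m$detected <- TRUE
  m$ccf[19:20] <- 0.5
  expect_equal(pair_summary("S1", "S2", m)$proportion_shared, 1.0)
})

test_that("group comparison reproduces exact Mann-Whitney p-values", {
  expect_equal(compare_pair_groups(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(compare_pair_groups(c(0.9, 0.8), c(0.9, 0.8)), 1.0)
  g1 <- lapply(c(0.98, 0.97), function(x)
    list(proportion_shared = x))
  g2 <- lapply(c(0.70, 0.65), function(x)
    list(proportion_shared = x))
  expect_equal(compare_pair_groups(g1, g2),
               mw_oracle(c(0.98, 0.97), c(0.70, 0.65)))
  expect_error(compare_pair_groups(numeric(0), 1),
               class = "mmclone_domain_error")
})

test_that("a planted site-private branch depresses sharing accordingly", {
  # 80 shared mutations at CCF 0.5 plus a 20% site-private branch at
  # CCF 0.5: expected shared proportion 0.8
  set.seed(21)
  props <- replicate(60, {
    n <- 100; priv <- 81:100
    phi_a <- rep(0.5, n); phi_b <- rep(0.5, n); phi_b[priv] <- 0
    draw <- function(phi) {
      depth <- pmax(1, rnbinom(n, mu = 121, size = 10))
      alt <- rbinom(n, depth, phi * 0.5 * 2 / 2)  # purity 1, cn 2
      list(alt = alt, depth = depth)
    }
    a <- draw(phi_a); b <- draw(phi_b)
    m <- data.frame(
      variant_id = rep(paste0("v", 1:n), 2),
      sample_id = rep(c("A", "B"), each = n),
      ccf = c(pmin(1, 2 * a$alt / a$depth), pmin(1, 2 * b$alt / b$depth)),
      evaluable = TRUE,
      detected = c(a$alt >= 2, b$alt >= 2))
    pair_summary("A", "B", m)$proportion_shared
  })
  expect_lt(abs(mean(props) - 0.8), 0.05)
})

test_that("sharing approaches one at high depth without private branches", {
  set.seed(31)
  n <- 150
  depth <- 500
  alt_a <- rbinom(n, depth, 0.25); alt_b <- rbinom(n, depth, 0.25)
  m <- data.frame(variant_id = rep(paste0("v", 1:n), 2),
                  sample_id = rep(c("A", "B"), each = n),
                  ccf = c(pmin(1, 2 * alt_a / depth),
                          pmin(1, 2 * alt_b / depth)),
                  evaluable = TRUE, detected = TRUE)
  expect_gte(pair_summary("A", "B", m)$proportion_shared, 0.95)
})

test_that("same-treatment-line pairing groups samples by timepoint", {
  samples <- data.frame(sample_id = c("a", "b", "c", "d"),
                        timepoint = c(0, 0, 1, 2))
  pr <- same_line_pairs(samples)
  expect_equal(nrow(pr), 1)
  expect_setequal(unlist(pr[1, c("sample_a", "sample_b")]), c("a", "b"))
})
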