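# shared fixtures and independent oracles, built in code at test time

write_toy_sample_sheet <- function(dir, samples = c("S1", "S2"),
                                   purity = 1) {
  path <- file.path(dir, "samples.tsv")
  df <- data.frame(sample_id = samples, patient_id = "P1",
                   site_class = rep(c("iliac_crest_left",
                                      "iliac_crest_right",
                                      "focal_lesion"),
                                    length.out = length(samples)),
                   anatomical_label = "x",
                   timepoint = seq_along(samples) - 1,
                   purity = purity)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_toy_mutation_file <- function(dir, rows) {
  path <- file.path(dir, "muts.tsv")
  writeLines(rows, path)
  path
}

# segments giving every sample diploid coverage of chromosomes 1..22
diploid_segments <- function(samples) {
  do.call(rbind, lapply(samples, function(s)
    data.frame(sample = s, chrom = as.character(1:22), start = 1L,
               end = 250000000L, total_cn = 2L, minor_cn = 1L,
               length_bp = 250000000L)))
}

# two near-orthogonal synthetic signatures on disjoint context halves
two_sig_catalog <- function() {
  p1 <- c(rep(1 / 48, 48), rep(0, 48))
  p2 <- c(rep(0, 48), rep(1 / 48, 48))
  sig_catalog(cbind(sigA = p1, sigB = p2))
}

# exposure fit by grid search over the 1-simplex (step 0.001); the
# independent oracle for two-signature mixtures
grid_fit_two <- function(counts, catalog, step = 0.001) {
  P <- catalog$profiles
  es <- seq(0, 1, by = step)
  ll <- vapply(es, function(e) {
    p <- pmax(e * P[, 1] + (1 - e) * P[, 2], 1e-300)
    sum(counts * log(p))
  }, numeric(1))
  e1 <- es[which.max(ll)]
  c(e1, 1 - e1)
}

# two-sided Fisher p by direct enumeration with choose() arithmetic
fisher_oracle <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  pr <- vapply(lo:hi, function(a)
    choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1),
    numeric(1))
  p_obs <- pr[m[1, 1] - lo + 1]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# two-sided Mann-Whitney p by enumeration of group assignments, using
# rank sums (not pair counting) as an independent route
mw_oracle <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  pooled <- c(g1, g2)
  rk <- rank(pooled)
  u_of <- function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  obs <- abs(u_of(seq_len(n1)) - mu)
  idx <- utils::combn(n1 + n2, n1)
  mean(apply(idx, 2, function(i) abs(u_of(i) - mu)) >= obs - 1e-9)
}

# brute-force multiplicity oracle: exhaustive likelihood enumeration
# (expected fractions clamped below one exactly as documented)
brute_multiplicity <- function(alt, depth, p, cn) {
  ll <- sapply(seq_len(cn), function(c_)
    dbinom(alt, depth,
           min(1 - 0.02, c_ * p / (p * cn + 2 * (1 - p))),
           log = TRUE))
  which.max(ll)
}

# simulate read counts for one mutation set at a fixed true CCF; the
# recovered quantity is the uncapped mutation-copy ratio n_mut / n_chr
# (the capped ccf is a reporting convention, not the estimator)
draw_ccf_entries <- function(n, phi, p, cn, mult = 1, depth = 121) {
  vaf <- phi * mult * p / (p * cn + 2 * (1 - p))
  alt <- rbinom(n, depth, vaf)
  vapply(seq_len(n), function(i) {
    e <- compute_ccf(alt[i], depth, p, cn)
    e$n_mut / e$n_chr
  }, numeric(1))
}
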