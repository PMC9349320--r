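#' Expected variant allele fraction for a given multiplicity
#'
#' In a sample of tumor purity \code{p} at a locus of tumor copy number
#' \code{total_cn}, a fully clonal mutation present on \code{c}
#' chromosome copies is expected at allele fraction
#' \deqn{f = c p / (p \cdot total\_cn + 2 (1 - p)),}
#' the tumor contributing \code{p * total_cn} and the diploid normal
#' \code{2 (1 - p)} chromosome copies per cell.
#'
#' @param c Multiplicity, integer 1..max(total_cn, 1).
#' @param p Tumor purity in (0, 1].
#' @param total_cn Locus total copy number in the tumor.
#' @return Expected allele fraction.
#' @export
#' @examples
#' expected_vaf(1, 1, 2)    # 0.5, pure diploid heterozygous
#' expected_vaf(1, 0.8, 3)  # 0.2857...
expected_vaf <- function(c, p, total_cn) {
  if (any(p <= 0 | p > 1))
    stop_mmclone("purity must be in (0, 1]", class = "mmclone_domain_error")
  c * p / (p * total_cn + 2 * (1 - p))
}

#' Maximum-likelihood mutation multiplicity
#'
#' Compares the observed allele counts to the allele fractions expected
#' for a mutation on 1, 2, ..., \code{total_cn} chromosome copies and
#' returns the multiplicity with the largest binomial likelihood
#' \eqn{Binom(alt | depth, f(c))}. Ties break toward the smaller
#' multiplicity.
#'
#' In the likelihood the expected fraction is clamped at
#' \code{1 - 0.02}: a saturated site never yields every read as
#' variant in practice (sequencing error at the base-quality-20 level,
#' residual reference bias), and without the clamp the fully mutated
#' state would have probability zero for any non-variant read.
#'
#' @param alt_reads,depth Variant and total read counts.
#' @param p Tumor purity in (0, 1].
#' @param total_cn Locus total copy number (>= 1).
#' @return Integer multiplicity in 1..total_cn.
#' @export
assign_multiplicity <- function(alt_reads, depth, p, total_cn) {
  if (depth < 1)
    stop_mmclone("depth must be >= 1", class = "mmclone_domain_error")
  if (alt_reads > depth)
    stop_mmclone("alt_reads must not exceed depth",
                 class = "mmclone_domain_error")
  if (total_cn < 1)
    stop_mmclone("total_cn must be >= 1 to assign a multiplicity",
                 class = "mmclone_domain_error")
  cs <- seq_len(total_cn)
  f <- pmin(expected_vaf(cs, p, total_cn), MAX_LIK_VAF)
  ll <- dbinom(alt_reads, depth, f, log = TRUE)
  cs[which.max(ll)]  # which.max takes the first (smallest c) on ties
}

#' Cancer clonal fraction of one observation
#'
#' Computes the mutation copy number
#' \deqn{n_{mut} = f_s \frac{1}{p} [p \; n_{locus} + 2 (1 - p)],}
#' assigns the multiplicity \code{n_chr} by binomial maximum likelihood
#' ([assign_multiplicity()]), and returns the cancer clonal fraction
#' \code{ccf = n_mut / n_chr}, capped at 1 (with \code{capped = TRUE}
#' recorded when the raw ratio exceeded 1).
#'
#' @param alt_reads,depth Variant and total read counts (qc-passing).
#' @param purity Tumor purity in (0, 1].
#' @param total_cn Locus total copy number. \code{total_cn = 0}
#'   (mutation inside a homozygous deletion call) or a missing segment
#'   (\code{NA}) yields an unevaluable entry.
#' @return One-row data.frame: \code{f_s}, \code{n_mut}, \code{n_chr},
#'   \code{ccf}, \code{capped}, \code{evaluable}.
#' @export
#' @examples
#' compute_ccf(30, 60, purity = 1, total_cn = 2)   # clonal heterozygous
compute_ccf <- function(alt_reads, depth, purity, total_cn) {
  if (is.na(total_cn) || total_cn < 1 || is.na(depth) || depth < 1) {
    return(data.frame(f_s = NA_real_, n_mut = NA_real_,
                      n_chr = NA_integer_, ccf = NA_real_,
                      capped = NA, evaluable = FALSE))
  }
  f_s <- alt_reads / depth
  n_mut <- f_s * (purity * total_cn + 2 * (1 - purity)) / purity
  n_chr <- if (alt_reads == 0) 1L else
    assign_multiplicity(alt_reads, depth, purity, total_cn)
  raw <- n_mut / n_chr
  data.frame(f_s = f_s, n_mut = n_mut, n_chr = as.integer(n_chr),
             ccf = min(1, raw), capped = raw > 1, evaluable = TRUE)
}

# expected allele fractions are clamped below one in likelihood
# evaluations: saturated sites retain a small non-variant read
# probability (sequencing error at BQ >= 20, reference bias)
MAX_LIK_VAF <- 1 - 0.02

# vectorized CCF computation over aligned vectors; entries with missing
# copy number / depth, or qc failure (encoded as NA alt) are unevaluable
ccf_vectorized <- function(alt, depth, purity, cn) {
  n <- length(alt)
  purity <- rep_len(purity, n)
  evaluable <- !is.na(alt) & !is.na(depth) & depth >= 1 &
    !is.na(cn) & cn >= 1
  f_s <- ifelse(evaluable, alt / depth, NA_real_)
  n_mut <- ifelse(evaluable,
                  f_s * (purity * cn + 2 * (1 - purity)) / purity,
                  NA_real_)
  n_chr <- ifelse(evaluable, 1L, NA_integer_)
  for (cnv in unique(cn[evaluable & cn >= 2 & alt > 0])) {
    idx <- which(evaluable & cn == cnv & alt > 0)
    ll <- vapply(seq_len(cnv), function(cc)
      dbinom(alt[idx], depth[idx],
             pmin(cc * purity[idx] /
                    (purity[idx] * cnv + 2 * (1 - purity[idx])),
                  MAX_LIK_VAF),
             log = TRUE), numeric(length(idx)))
    ll <- matrix(ll, nrow = length(idx))
    n_chr[idx] <- max.col(ll, ties.method = "first")
  }
  raw <- n_mut / n_chr
  data.frame(f_s = f_s, n_mut = n_mut, n_chr = as.integer(n_chr),
             ccf = pmin(1, raw), capped = !is.na(raw) & raw > 1,
             evaluable = evaluable)
}

# locus total copy number per (variant, sample) from the segment table;
# NA where no covering segment exists
locus_total_cn <- function(variants, sample_id, segments) {
  seg <- segments[segments$sample == sample_id, , drop = FALSE]
  vchrom <- as.character(variants$chrom)
  out <- rep(NA_integer_, nrow(variants))
  for (i in seq_len(nrow(seg))) {
    hit <- vchrom == seg$chrom[i] & variants$pos >= seg$start[i] &
      variants$pos <= seg$end[i]
    out[hit] <- seg$total_cn[i]
  }
  out
}

#' Per-patient CCF matrix
#'
#' Applies [compute_ccf()] to every (variant, sample) pair of one
#' patient, joining purity from the sample sheet and locus copy number
#' from the segment table. Entries without a covering segment (or with
#' total copy number 0) are flagged unevaluable rather than silently
#' defaulted, and are excluded from downstream clustering. A
#' \code{detected} flag (alt reads >= \code{min_detect_alt_reads})
#' accompanies every entry.
#'
#' @param variants,observations Mutation data as from
#'   [read_mutation_table()].
#' @param samples Sample sheet rows for this patient.
#' @param segments Segment table from [read_segments()].
#' @param min_detect_alt_reads Detection rule threshold (default 2
#'   variant reads).
#' @return Long data.frame, one row per (variant, sample):
#'   \code{variant_id}, \code{sample_id}, \code{f_s}, \code{n_mut},
#'   \code{n_chr}, \code{ccf}, \code{capped}, \code{evaluable},
#'   \code{detected}, \code{alt_reads}, \code{depth}, \code{purity},
#'   \code{total_cn}.
#' @export
build_ccf_matrix <- function(variants, observations, samples, segments,
                             min_detect_alt_reads = 2) {
  out <- vector("list", nrow(samples))
  for (j in seq_len(nrow(samples))) {
    sid <- samples$sample_id[j]
    p <- samples$purity[j]
    obs <- observations[observations$sample_id == sid, , drop = FALSE]
    obs <- obs[match(variants$variant_id, obs$variant_id), , drop = FALSE]
    cn <- locus_total_cn(variants, sid, segments)
    a <- ifelse(!is.na(obs$qc_pass) & obs$qc_pass, obs$alt_reads, NA)
    d <- ifelse(!is.na(obs$qc_pass) & obs$qc_pass, obs$depth, NA)
    ent <- ccf_vectorized(a, d, p, cn)
    ent$variant_id <- variants$variant_id
    ent$sample_id <- sid
    ent$alt_reads <- obs$alt_reads
    ent$depth <- obs$depth
    ent$purity <- p
    ent$total_cn <- cn
    ent$detected <- !is.na(obs$alt_reads) &
      obs$alt_reads >= min_detect_alt_reads
    out[[j]] <- ent
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[c("variant_id", "sample_id", "f_s", "n_mut", "n_chr", "ccf",
        "capped", "evaluable", "detected", "alt_reads", "depth",
        "purity", "total_cn")]
}

# wide variant x sample matrix of one ccf-matrix column
ccf_wide <- function(ccf_matrix, value = "ccf") {
  vids <- unique(ccf_matrix$variant_id)
  sids <- unique(ccf_matrix$sample_id)
  m <- matrix(NA_real_, length(vids), length(sids),
              dimnames = list(vids, sids))
  m[cbind(match(ccf_matrix$variant_id, vids),
          match(ccf_matrix$sample_id, sids))] <- ccf_matrix[[value]]
  m
}
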