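#' Analysis configuration defaults
#'
#' Central place for the tunable thresholds of the pipeline. Values can
#' be overridden per call; the defaults follow the published analysis:
#' coverage strictly exceeding 20x in every sample of the patient, a
#' 2-variant-read detection rule, a CCF floor of 0.20 in at least one
#' sample, 5 Mb / 1 Mb copy-number size gates, a minimum clustering
#' depth of 50, a 0.60 clonal/dominance cutoff, and a 0.20 minor-clone
#' / detection-proportion threshold.
#'
#' @param ... Named overrides of any default.
#' @return Named list of configuration values.
#' @export
mm_config <- function(...) {
  cfg <- list(
    min_depth_exclusive = 20,    # coverage must exceed this in all samples
    min_detect_alt_reads = 2,    # reads needed to call a site detected
    ccf_floor = 0.20,            # max CCF across samples must reach this
    cna_global_mb = 5,           # global CNA size gate (Mb)
    cna_driver_mb = 1,           # driver-deletion size gate (Mb)
    cluster_min_depth = 50,      # depth needed in all samples to cluster
    kmax = 8,                    # max mixture components for BIC scan
    em_seed = 1,                 # EM initialization seed
    em_restarts = 2,
    em_maxit = 200,
    em_tol = 1e-6,
    tree_tol = 0.10,             # pigeonhole / sibling-sum CCF tolerance
    dominance = 0.60,            # clone proportion counting as dominant
    minor_threshold = 0.20,      # minor-clone / detection proportion
    shared_diff_ratio = 3,       # CCF fold-change for shared-differential
    clonal_ccf = 0.60,           # clonal vs subclonal CCF cutoff
    min_signature_mutations = 25,
    presence_alpha = 0.05,
    bootstrap_B = 1000,
    bootstrap_seed = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop_mmclone("unknown config key(s): ", paste(bad, collapse = ", "),
                 class = "mmclone_config_error")
  cfg[names(over)] <- over
  cfg
}

#' Detection status of one observation
#'
#' A variant is called detected in a sample when at least
#' \code{min_alt_reads} (default 2) qc-passing variant reads support it.
#'
#' @param alt_reads Variant read count.
#' @param min_alt_reads Detection threshold.
#' @return \code{"detected"} or \code{"undetected"} (vectorized).
#' @export
detection_status <- function(alt_reads, min_alt_reads = 2) {
  ifelse(alt_reads >= min_alt_reads, "detected", "undetected")
}

#' Apply the per-patient inclusion filters
#'
#' Produces the analysis-ready mutation set of one patient. A variant is
#' retained when (i) its depth strictly exceeds
#' \code{min_depth_exclusive} in every sample of the patient, (ii) it
#' passes base/mapping quality in every sample, (iii) it lies outside
#' the immunoglobulin loci, and (iv) its provisional CCF reaches
#' \code{ccf_floor} in at least one sample. Filtering is a single
#' two-pass sweep: provisional CCFs are computed on the full candidate
#' set first, then the rules are applied once. When a variant fails
#' several rules the first failing rule in the order coverage, quality,
#' Ig locus, CCF floor is recorded.
#'
#' @param variants,observations Candidate mutations as from
#'   [read_mutation_table()].
#' @param samples Sample sheet rows of this patient (all its samples).
#' @param segments Segment table.
#' @param config List from [mm_config()].
#' @return List with \code{retained} (variant ids), \code{ccf_matrix}
#'   (provisional CCF matrix of all candidates), \code{report}
#'   (per-variant outcome) and \code{counts} (outcomes tabulated; sums
#'   to the number of candidates).
#' @export
apply_inclusion_filters <- function(variants, observations, samples,
                                    segments, config = mm_config()) {
  if (nrow(samples) == 0)
    stop_mmclone("empty sample set", class = "mmclone_config_error")
  ccf_matrix <- build_ccf_matrix(variants, observations, samples,
                                 segments,
                                 config$min_detect_alt_reads)
  dep <- ccf_wide(ccf_matrix, "depth")
  ccf <- ccf_wide(ccf_matrix, "ccf")

  # qc per (variant, sample) from the observations table
  qcw <- matrix(TRUE, nrow(variants), nrow(samples),
                dimnames = dimnames(dep))
  for (s in samples$sample_id) {
    o <- observations[observations$sample_id == s, ]
    qcw[match(o$variant_id, rownames(qcw)), s] <- o$qc_pass
  }

  cover_ok <- apply(dep, 1, function(d)
    all(!is.na(d) & d > config$min_depth_exclusive))
  qual_ok <- apply(qcw, 1, all)
  ig_ok <- !variants$in_ig_locus
  max_ccf <- apply(ccf, 1, function(x)
    if (all(is.na(x))) -Inf else max(x, na.rm = TRUE))
  ccf_ok <- max_ccf >= config$ccf_floor

  outcome <- rep("retained", nrow(variants))
  outcome[!ccf_ok] <- "fail_ccf_floor"
  outcome[!ig_ok] <- "fail_ig_locus"
  outcome[!qual_ok] <- "fail_quality"
  outcome[!cover_ok] <- "fail_coverage"

  report <- data.frame(variant_id = variants$variant_id,
                       outcome = outcome, stringsAsFactors = FALSE)
  counts <- table(factor(outcome,
                         levels = c("retained", "fail_coverage",
                                    "fail_quality", "fail_ig_locus",
                                    "fail_ccf_floor")))
  list(retained = variants$variant_id[outcome == "retained"],
       ccf_matrix = ccf_matrix, report = report, counts = counts)
}

#' Size- and class-gate copy-number segments
#'
#' Global mode keeps segments of at least \code{cna_global_mb}
#' megabases. Driver mode keeps deletions (total copy number below 2)
#' of at least \code{cna_driver_mb} megabases that overlap a supplied
#' driver-gene interval.
#'
#' @param segments Segment table from [read_segments()].
#' @param mode \code{"global"} or \code{"driver"}.
#' @param driver_intervals data.frame \code{chrom start end} (BED-like,
#'   here 1-based inclusive); required in driver mode.
#' @param config List from [mm_config()].
#' @return The retained segment rows.
#' @export
filter_cna <- function(segments, mode = c("global", "driver"),
                       driver_intervals = NULL, config = mm_config()) {
  mode <- match.arg(mode)
  if (mode == "global")
    return(segments[segments$length_bp >= config$cna_global_mb * 1e6, ,
                    drop = FALSE])
  if (is.null(driver_intervals) || nrow(driver_intervals) == 0)
    stop_mmclone("driver mode requires driver intervals",
                 class = "mmclone_config_error")
  keep <- segments$total_cn < 2 &
    segments$length_bp >= config$cna_driver_mb * 1e6
  chrom <- sub("^chr", "", segments$chrom)
  dchrom <- sub("^chr", "", driver_intervals$chrom)
  ov <- logical(nrow(segments))
  for (i in seq_len(nrow(driver_intervals))) {
    ov <- ov | (chrom == dchrom[i] &
                  segments$start <= driver_intervals$end[i] &
                  segments$end >= driver_intervals$start[i])
  }
  segments[keep & ov, , drop = FALSE]
}
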