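PAIR_CATEGORIES <- c("shared", "shared_diff_subclonal",
                     "shared_diff_clonal", "unshared_minor",
                     "unshared_major")

#' Classify a mutation across a sample pair
#'
#' A mutation detected in only one of the two samples is unshared
#' (minor when its CCF in the detecting sample is below
#' \code{clonal_ccf}, major otherwise). A mutation detected in both is
#' shared-differential when the larger CCF is at least
#' \code{shared_diff_ratio} times the smaller (subclonal or clonal by
#' whether the larger CCF reaches \code{clonal_ccf}), and shared
#' otherwise. The defaults implement the published thresholds: a
#' threefold CCF difference and a 60\% clonal cutoff.
#'
#' @param ccf_a,ccf_b CCF of the mutation in the two samples.
#' @param detected_a,detected_b Detection flags (>= 2 variant reads).
#' @param shared_diff_ratio,clonal_ccf Thresholds (defaults 3 and 0.60).
#' @return One of \code{"shared"}, \code{"shared_diff_subclonal"},
#'   \code{"shared_diff_clonal"}, \code{"unshared_minor"},
#'   \code{"unshared_major"}; vectorized over its inputs.
#' @export
#' @examples
#' classify_pair(0.60, 0.15, TRUE, TRUE)   # shared_diff_clonal
#' classify_pair(0.70, 0.00, TRUE, FALSE)  # unshared_major
classify_pair <- function(ccf_a, ccf_b, detected_a, detected_b,
                          shared_diff_ratio = 3, clonal_ccf = 0.60) {
  n <- max(length(ccf_a), length(ccf_b))
  ccf_a <- rep_len(ccf_a, n); ccf_b <- rep_len(ccf_b, n)
  detected_a <- rep_len(detected_a, n)
  detected_b <- rep_len(detected_b, n)
  out <- character(n)
  for (i in seq_len(n)) {
    if (!detected_a[i] && !detected_b[i])
      stop_mmclone("mutation undetected in both samples is not ",
                   "classifiable", class = "mmclone_domain_error")
    if (xor(detected_a[i], detected_b[i])) {
      own <- if (detected_a[i]) ccf_a[i] else ccf_b[i]
      out[i] <- if (own < clonal_ccf) "unshared_minor" else
        "unshared_major"
    } else {
      hi <- max(ccf_a[i], ccf_b[i]); lo <- min(ccf_a[i], ccf_b[i])
      # small relative slack so an exact threefold ratio (e.g.
      # 0.60/0.20) is not lost to floating-point rounding
      diff3 <- if (lo > 0)
        hi / lo >= shared_diff_ratio * (1 - 1e-9) else hi > 0
      out[i] <- if (!diff3) "shared" else if (hi >= clonal_ccf)
        "shared_diff_clonal" else "shared_diff_subclonal"
    }
  }
  out
}

#' Heterogeneity summary of a sample pair
#'
#' Classifies every evaluable mutation of a patient across one sample
#' pair and tabulates category counts and proportions. Mutations
#' undetected in both samples, or unevaluable in either, are excluded.
#'
#' @param sample_a,sample_b Sample ids of the pair.
#' @param ccf_matrix CCF matrix from [build_ccf_matrix()] (filtered).
#' @param config List from [mm_config()].
#' @return List with \code{pair}, per-category \code{counts} and
#'   \code{proportions} (summing to 1), \code{n} classifiable
#'   mutations, \code{proportion_shared}, and \code{classifications}
#'   (per-variant categories). With zero classifiable mutations an
#'   empty-summary sentinel (\code{n = 0}, \code{NA} proportions) is
#'   returned.
#' @export
pair_summary <- function(sample_a, sample_b, ccf_matrix,
                         config = mm_config()) {
  a <- ccf_matrix[ccf_matrix$sample_id == sample_a, ]
  b <- ccf_matrix[ccf_matrix$sample_id == sample_b, ]
  b <- b[match(a$variant_id, b$variant_id), ]
  ok <- a$evaluable & b$evaluable & (a$detected | b$detected) &
    !is.na(b$variant_id)
  a <- a[ok, ]; b <- b[ok, ]
  if (nrow(a) == 0) {
    return(list(pair = c(sample_a, sample_b), n = 0L,
                counts = setNames(integer(5), PAIR_CATEGORIES),
                proportions = setNames(rep(NA_real_, 5),
                                       PAIR_CATEGORIES),
                proportion_shared = NA_real_,
                classifications = data.frame()))
  }
  cat <- classify_pair(a$ccf, b$ccf, a$detected, b$detected,
                       config$shared_diff_ratio, config$clonal_ccf)
  counts <- table(factor(cat, levels = PAIR_CATEGORIES))
  props <- as.numeric(counts) / sum(counts)
  names(props) <- PAIR_CATEGORIES
  list(pair = c(sample_a, sample_b), n = nrow(a),
       counts = setNames(as.integer(counts), PAIR_CATEGORIES),
       proportions = props,
       proportion_shared = props[["shared"]],
       classifications = data.frame(variant_id = a$variant_id,
                                    category = cat,
                                    stringsAsFactors = FALSE))
}

#' Compare shared-mutation proportions between two groups of pairs
#'
#' Two-sided Mann-Whitney test on the \code{proportion_shared} values
#' of two groups of pair summaries (e.g. paired left/right iliac crest
#' versus paired iliac crest/focal lesion).
#'
#' @param group1,group2 Lists of summaries from [pair_summary()], or
#'   numeric vectors of shared proportions.
#' @return Two-sided p-value.
#' @export
compare_pair_groups <- function(group1, group2) {
  pull <- function(g) {
    if (is.numeric(g)) return(g)
    vapply(g, function(s) s$proportion_shared, numeric(1))
  }
  g1 <- pull(group1); g2 <- pull(group2)
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  if (length(g1) == 0 || length(g2) == 0)
    stop_mmclone("both groups must be nonempty",
                 class = "mmclone_domain_error")
  mann_whitney(g1, g2)
}

#' Form same-treatment-line sample pairs
#'
#' Pairs of samples from one patient sharing a treatment-line index
#' (timepoint), the pairing policy used for within-timepoint spatial
#' comparisons.
#'
#' @param samples Sample sheet rows of one patient.
#' @return data.frame with \code{sample_a}, \code{sample_b},
#'   \code{timepoint}.
#' @export
same_line_pairs <- function(samples) {
  out <- list()
  for (tp in unique(samples$timepoint)) {
    s <- samples$sample_id[samples$timepoint == tp]
    if (length(s) >= 2) {
      cmb <- combn(s, 2)
      out[[length(out) + 1]] <- data.frame(sample_a = cmb[1, ],
                                           sample_b = cmb[2, ],
                                           timepoint = tp,
                                           stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample_a = character(0),
                      sample_b = character(0),
                      timepoint = numeric(0)))
  do.call(rbind, out)
}
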