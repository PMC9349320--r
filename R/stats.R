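#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computes the two-sided p-value by the point-probability method: with
#' the table margins fixed, the hypergeometric probability of every
#' feasible table is evaluated and all tables whose probability does not
#' exceed that of the observed table (within a small relative slack for
#' floating-point ties) are summed.
#'
#' @param table 2x2 matrix (or object coercible to one) of nonnegative
#'   integer counts.
#' @return Two-sided p-value.
#' @export
#' @examples
#' fisher_exact(matrix(c(0, 7, 11, 3), 2))  # ~1.03e-3
fisher_exact <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2)))
    stop_mmclone("need a 2x2 table", class = "mmclone_domain_error")
  if (any(is.na(m)) || any(m < 0) || any(m != floor(m)))
    stop_mmclone("counts must be nonnegative integers",
                 class = "mmclone_domain_error")
  if (sum(m) < 1)
    stop_mmclone("table total must be >= 1", class = "mmclone_domain_error")
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  support <- lo:hi
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Mann-Whitney U statistic of group1 against group2 (ties count 1/2)
mw_u <- function(g1, g2) {
  sum(vapply(g1, function(x) sum(x > g2) + 0.5 * sum(x == g2),
             numeric(1)))
}

#' Two-sided Mann-Whitney-Wilcoxon test for independent groups
#'
#' For a combined sample size of at most \code{exact_n} the p-value is
#' computed by exact enumeration of all assignments of the pooled
#' values to the two groups: the proportion of assignments whose U
#' statistic deviates from its null mean n1*n2/2 at least as much as
#' the observed U (ties handled by mid-counting). Larger samples use
#' the tie-corrected normal approximation with continuity correction.
#'
#' @param group1,group2 Numeric vectors, both nonempty.
#' @param exact_n Combined-size limit for exhaustive enumeration.
#' @return Two-sided p-value.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # 0.1 by enumeration
mann_whitney <- function(group1, group2, exact_n = 12) {
  if (length(group1) == 0 || length(group2) == 0)
    stop_mmclone("both groups must be nonempty",
                 class = "mmclone_domain_error")
  n1 <- length(group1); n2 <- length(group2)
  pooled <- c(group1, group2)
  u_obs <- mw_u(group1, group2)
  mu <- n1 * n2 / 2
  if (n1 + n2 <= exact_n) {
    idx <- combn(n1 + n2, n1)
    dev <- apply(idx, 2, function(i)
      abs(mw_u(pooled[i], pooled[-i]) - mu))
    return(mean(dev >= abs(u_obs - mu) - 1e-9))
  }
  # tie-corrected normal approximation
  n <- n1 + n2
  ties <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-max(z, 0)))
}

#' GEP70 risk score
#'
#' The GEP70 score is the average log2 expression of the 51 upregulated
#' genes minus the average log2 expression of the 19 downregulated
#' genes; scores of at least 0.66 indicate high risk. Gene lists are
#' supplied by the caller (the probe-set ids are configuration, not
#' package constants). Up to \code{max_missing_frac} of either set may
#' be absent from the expression vector (means are then taken over the
#' available genes); beyond that the score is refused with a
#' missing-gene report.
#'
#' @param expression Named numeric vector of normalized log2 expression.
#' @param up_set,down_set Character vectors of gene/probe ids (disjoint).
#' @param threshold High-risk cutoff (default 0.66).
#' @param max_missing_frac Tolerated fraction of missing genes per set.
#' @return List with \code{score}, \code{risk} ("high"/"low") and
#'   \code{missing} (ids absent from \code{expression}).
#' @export
gep70_score <- function(expression, up_set, down_set, threshold = 0.66,
                        max_missing_frac = 0.20) {
  if (length(intersect(up_set, down_set)))
    stop_mmclone("up and down gene sets must be disjoint",
                 class = "mmclone_domain_error")
  miss_up <- setdiff(up_set, names(expression))
  miss_dn <- setdiff(down_set, names(expression))
  if (length(miss_up) > max_missing_frac * length(up_set) ||
      length(miss_dn) > max_missing_frac * length(down_set))
    stop_mmclone("too many genes missing from the expression vector: ",
                 paste(c(miss_up, miss_dn), collapse = ", "),
                 class = "mmclone_missing_gene_error")
  score <- mean(expression[intersect(up_set, names(expression))]) -
    mean(expression[intersect(down_set, names(expression))])
  list(score = score,
       risk = if (score >= threshold) "high" else "low",
       missing = c(miss_up, miss_dn))
}

#' Associate evolutionary patterns with clinical features
#'
#' Joins per-patient evolution reports ([summarize_patient()]) to a
#' clinical table and computes two Fisher's exact tests: PET-positive
#' focal-lesion burden (>= \code{fl_cut} vs fewer) against relapse
#' seeding (single branch vs multiple), and best response (CR vs
#' non-CR) against the same grouping.
#'
#' @param reports data.frame with at least \code{patient_id} and
#'   \code{n_relapse_branches} (one row per patient).
#' @param clinical data.frame from [read_clinical_table()].
#' @param fl_cut Focal-lesion count defining high burden (default 3).
#' @return List with the two 2x2 tables, their p-values, and
#'   \code{unmatched} patient ids present in only one input. With an
#'   empty clinical table an explicit empty result (\code{NULL} tables
#'   and p-values) is returned.
#' @export
associate_pattern_features <- function(reports, clinical, fl_cut = 3) {
  if (is.null(clinical) || nrow(clinical) == 0) {
    return(list(fl_table = NULL, fl_p = NULL, cr_table = NULL,
                cr_p = NULL,
                unmatched = reports$patient_id %||% character(0)))
  }
  unmatched <- union(setdiff(reports$patient_id, clinical$patient_id),
                     setdiff(clinical$patient_id, reports$patient_id))
  j <- merge(reports, clinical, by = "patient_id")
  single <- factor(j$n_relapse_branches == 1, levels = c(TRUE, FALSE),
                   labels = c("single", "multi"))
  fl_table <- NULL; fl_p <- NULL
  if (any(!is.na(j$pet_fl_count))) {
    hi <- factor(j$pet_fl_count >= fl_cut, levels = c(FALSE, TRUE),
                 labels = c("fl_lt", "fl_ge"))
    fl_table <- table(single, hi)
    fl_p <- fisher_exact(fl_table)
  }
  cr_table <- NULL; cr_p <- NULL
  if (any(!is.na(j$best_response))) {
    cr <- factor(j$best_response == "CR", levels = c(TRUE, FALSE),
                 labels = c("CR", "non_CR"))
    cr_table <- table(single, cr)
    cr_p <- fisher_exact(cr_table)
  }
  list(fl_table = fl_table, fl_p = fl_p, cr_table = cr_table,
       cr_p = cr_p, unmatched = unmatched)
}
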