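PATTERNS <- c("single_cell_expansion", "coexisting_subclones",
              "alternating_spatial_dominance")

# fraction of tumor cells belonging to a branch (the subtree rooted at
# a node) in each sample: the node's own CCF centroid
branch_fraction <- function(tree, id) tree$centroids[id, ]

#' Branches seeding relapse
#'
#' Returns the minimal set of clone-tree branches (subtrees rooted at
#' children of the root) whose cells reach the detection proportion in
#' at least one follow-up sample. When no child branch is detected at
#' follow-up but the trunk persists, relapse is seeded by the single
#' trunk clone and the root id is returned.
#'
#' @param tree A \code{clone_tree}.
#' @param samples Sample-sheet rows of the patient; rows with
#'   \code{timepoint > 0} count as follow-up.
#' @param config List from [mm_config()] (uses
#'   \code{minor_threshold} as the detection proportion).
#' @return Character vector of branch-defining node ids (length >= 1).
#' @export
count_relapse_branches <- function(tree, samples,
                                   config = mm_config()) {
  fu <- samples$sample_id[samples$timepoint > 0]
  fu <- intersect(fu, colnames(tree$centroids))
  if (!length(fu))
    stop_mmclone("no follow-up samples", class = "mmclone_domain_error")
  branches <- tree_children(tree, tree$root)
  detected <- branches[vapply(branches, function(b)
    any(branch_fraction(tree, b)[fu] >= config$minor_threshold),
    logical(1))]
  if (!length(detected)) tree$root else detected
}

#' Classify a patient's evolutionary pattern
#'
#' Applies the three-pattern taxonomy of relapse: a single relapse
#' branch is a single-cell expansion; two or more branches co-detected
#' (both at or above the detection proportion) in at least one
#' follow-up sample are coexisting subclones; two or more branches
#' never co-detected in any sample constitute alternating spatial
#' clonal dominance. Mixed features (e.g. site-unique extra branches
#' alongside co-located ones) are recorded as evidence; co-location
#' dominates the label.
#'
#' @param tree A \code{clone_tree}.
#' @param samples Sample-sheet rows of the patient.
#' @param config List from [mm_config()].
#' @param patient_id Optional label.
#' @param signature_flags Optional named character vector of
#'   single-cell-expansion signature statuses per branch (from
#'   [flag_single_cell_expansion()]), recorded as corroborating
#'   evidence only.
#' @return A \code{pattern_call}: list with \code{patient},
#'   \code{pattern}, \code{n_relapse_branches}, \code{branches},
#'   \code{evidence}, \code{mixed_features}.
#' @export
classify_pattern <- function(tree, samples, config = mm_config(),
                             patient_id = NA_character_,
                             signature_flags = NULL) {
  branches <- count_relapse_branches(tree, samples, config)
  fu <- intersect(samples$sample_id[samples$timepoint > 0],
                  colnames(tree$centroids))
  occ <- vapply(branches, function(b)
    branch_fraction(tree, b)[fu] >= config$minor_threshold,
    logical(length(fu)))
  occ <- matrix(occ, nrow = length(fu),
                dimnames = list(fu, branches))
  co_detected <- length(branches) >= 2 &&
    any(rowSums(occ) >= 2)
  pattern <- if (length(branches) == 1) {
    "single_cell_expansion"
  } else if (co_detected) {
    "coexisting_subclones"
  } else {
    "alternating_spatial_dominance"
  }
  # branches seen somewhere as the only detected branch of a sample
  solo <- branches[apply(occ, 2, function(col)
    any(col & rowSums(occ) == 1))]
  structure(list(
    patient = patient_id, pattern = pattern,
    n_relapse_branches = length(branches), branches = branches,
    evidence = list(occupancy = occ,
                    signature_flags = signature_flags),
    mixed_features = list(
      co_located = co_detected,
      solo_branches = solo,
      flagged_branches = names(signature_flags)[
        signature_flags == "flagged"] %||% character(0))),
    class = "pattern_call")
}

#' @export
print.pattern_call <- function(x, ...) {
  cat("Pattern:", x$pattern, "(", x$n_relapse_branches,
      "relapse branch(es):", paste(x$branches, collapse = ", "), ")\n")
  invisible(x)
}

#' Per-patient evolution report
#'
#' Assembles one record per patient from the fitted stages: the
#' evolutionary pattern, the clonal sweep count, signature-flagged
#' branches, parallel-evolution genes, and subclone counts per
#' timepoint and in total (a clone counts as observed at a timepoint
#' when its terminal proportion reaches the detection threshold in any
#' sample of that timepoint).
#'
#' @param patient_id Patient label.
#' @param tree A \code{clone_tree}.
#' @param samples Sample-sheet rows of the patient.
#' @param pattern A \code{pattern_call} from [classify_pattern()].
#' @param sweeps data.frame from [detect_sweeps()].
#' @param parallel_genes Character vector from
#'   [detect_parallel_evolution()].
#' @param config List from [mm_config()].
#' @return One-row data.frame: \code{patient_id}, \code{pattern},
#'   \code{n_relapse_branches}, \code{n_sweeps},
#'   \code{flagged_branches}, \code{parallel_genes},
#'   \code{subclones_total}, \code{subclones_max_timepoint}, plus a
#'   \code{per_timepoint} attribute with the per-timepoint counts.
#' @export
summarize_patient <- function(patient_id, tree, samples, pattern,
                              sweeps = NULL, parallel_genes = character(0),
                              config = mm_config()) {
  P <- clone_proportions(tree)
  tps <- sort(unique(samples$timepoint))
  per_tp <- vapply(tps, function(tp) {
    s <- intersect(samples$sample_id[samples$timepoint == tp],
                   colnames(P))
    if (!length(s)) return(0L)
    sum(apply(P[, s, drop = FALSE], 1, max) >= config$minor_threshold)
  }, integer(1))
  names(per_tp) <- tps
  total <- sum(apply(P, 1, max) >= config$minor_threshold)
  out <- data.frame(
    patient_id = patient_id, pattern = pattern$pattern,
    n_relapse_branches = pattern$n_relapse_branches,
    n_sweeps = if (is.null(sweeps)) NA_integer_ else nrow(sweeps),
    flagged_branches = paste(pattern$mixed_features$flagged_branches,
                             collapse = ","),
    parallel_genes = paste(parallel_genes, collapse = ","),
    subclones_total = total,
    subclones_max_timepoint = max(per_tp),
    stringsAsFactors = FALSE)
  attr(out, "per_timepoint") <- per_tp
  out
}
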