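#' Run the full per-patient analysis
#'
#' End-to-end pipeline for one patient: inclusion filters (coverage,
#' quality, immunoglobulin loci, CCF floor), CCF matrix, subclone
#' mixture fit, clone tree, per-sample clone proportions, clonal-sweep
#' detection on the iliac-crest series, optional per-branch signature
#' fitting with the treatment-signature presence test, parallel
#' evolution flagging, evolutionary-pattern classification, and the
#' per-patient summary record.
#'
#' @param variants,observations,samples,segments Patient data as read
#'   by the io layer (or a [simulate_patient()] bundle's components).
#' @param config List from [mm_config()].
#' @param signature_catalog Optional \code{sig_catalog}; when supplied
#'   (together with \code{target}) branch-defining mutations are
#'   fitted and tested for the target signature. \code{NULL} skips the
#'   signature stage.
#' @param target Name of the treatment signature in the catalog.
#' @param patient_id Label; defaults to the sample sheet's patient id.
#' @return Object of class \code{mm_analysis}: list with
#'   \code{filter}, \code{ccf_matrix}, \code{fit} (subclone_fit),
#'   \code{tree}, \code{proportions}, \code{sweeps},
#'   \code{signature_fits}, \code{pattern}, \code{parallel_genes},
#'   \code{report}.
#' @export
analyze_patient <- function(variants, observations, samples, segments,
                            config = mm_config(),
                            signature_catalog = NULL,
                            target = "SBS-MM1-like",
                            patient_id = samples$patient_id[1]) {
  filt <- apply_inclusion_filters(variants, observations, samples,
                                  segments, config)
  ccf_f <- filt$ccf_matrix[filt$ccf_matrix$variant_id %in%
                             filt$retained, , drop = FALSE]
  fit <- cluster_mutations(ccf_f, config)
  tree <- build_clone_tree(fit, config)
  proportions <- clone_proportions(tree)

  ic <- samples[startsWith(samples$site_class, "iliac_crest"), ,
                drop = FALSE]
  sweeps <- detect_sweeps(tree, ic, config)

  # per-branch gene lists and context counts
  asg <- fit$assignments
  cluster_ids <- rownames(fit$centroids)
  branch_genes <- lapply(seq_along(cluster_ids), function(j) {
    v <- asg$variant_id[asg$cluster == j]
    unique(variants$gene[variants$variant_id %in% v])
  })
  names(branch_genes) <- cluster_ids

  signature_fits <- NULL
  flags <- NULL
  if (!is.null(signature_catalog)) {
    signature_fits <- lapply(seq_along(cluster_ids), function(j) {
      v <- asg$variant_id[asg$cluster == j]
      ctx <- variants$context96[variants$variant_id %in% v]
      cnt <- count_contexts(ctx[!is.na(ctx)])
      flag_single_cell_expansion(cnt, signature_catalog, target,
                                 config)
    })
    names(signature_fits) <- cluster_ids
    flags <- vapply(signature_fits, function(f) f$status,
                    character(1))
  }

  pattern <- classify_pattern(tree, samples, config, patient_id,
                              signature_flags = flags)
  parallel_genes <- detect_parallel_evolution(
    tree, branch_genes,
    families = list(KDM_KMT = c("KDM", "KMT")))
  report <- summarize_patient(patient_id, tree, samples, pattern,
                              sweeps, parallel_genes, config)
  structure(list(patient_id = patient_id, filter = filt,
                 ccf_matrix = ccf_f, fit = fit, tree = tree,
                 proportions = proportions, sweeps = sweeps,
                 branch_genes = branch_genes,
                 signature_fits = signature_fits, pattern = pattern,
                 parallel_genes = parallel_genes, report = report,
                 samples = samples, config = config),
            class = "mm_analysis")
}

#' @export
print.mm_analysis <- function(x, ...) {
  cat("mm_analysis for patient", x$patient_id, "\n")
  cat("  retained mutations:", length(x$filter$retained), "of",
      nrow(x$filter$report), "\n")
  cat("  subclones:", x$fit$k, " pattern:", x$pattern$pattern,
      " sweeps:", nrow(x$sweeps), "\n")
  invisible(x)
}

# greedy bijective matching of recovered clusters to true clones by
# centroid distance; returns named map cluster id -> clone id
match_clusters_to_truth <- function(centroids, true_ccf) {
  d <- outer(seq_len(nrow(centroids)), seq_len(nrow(true_ccf)),
             Vectorize(function(i, j)
               sqrt(mean((centroids[i, colnames(true_ccf)] -
                            true_ccf[j, ])^2))))
  map <- setNames(rep(NA_character_, nrow(centroids)),
                  rownames(centroids))
  while (any(is.finite(d))) {
    ij <- arrayInd(which.min(d), dim(d))
    map[rownames(centroids)[ij[1]]] <- rownames(true_ccf)[ij[2]]
    d[ij[1], ] <- Inf; d[, ij[2]] <- Inf
  }
  map
}

#' Score a recovered analysis against simulator truth
#'
#' Compares the subclone count, the tree topology (parent relation
#' after matching recovered clusters to planted clones by centroid
#' distance), the pattern label and the sweep count of an analysis to
#' the ground truth of the simulated patient it was run on.
#'
#' @param analysis An \code{mm_analysis}.
#' @param truth The \code{truth} element of a [simulate_patient()]
#'   bundle.
#' @return List of logicals/counts: \code{k_true}, \code{k_hat},
#'   \code{k_correct}, \code{topology_correct},
#'   \code{pattern_correct}, \code{sweeps_hat}, \code{sweeps_true}.
#' @export
evaluate_recovery <- function(analysis, truth) {
  true_ccf <- truth$clone_ccf
  k_true <- nrow(true_ccf)
  k_hat <- analysis$fit$k
  k_correct <- k_hat == k_true
  topology_correct <- FALSE
  if (k_correct) {
    tree <- analysis$tree
    ids <- setdiff(rownames(tree$centroids), "MRCA")
    if (identical(sort(ids), sort(rownames(analysis$fit$centroids))) &&
        !("MRCA" %in% rownames(tree$centroids))) {
      map <- match_clusters_to_truth(tree$centroids, true_ccf)
      if (!anyDuplicated(map) && !anyNA(map)) {
        topology_correct <- all(vapply(rownames(tree$centroids),
          function(id) {
            par <- tree$nodes$parent[match(id, tree$nodes$id)]
            true_par <- truth$parents[[map[[id]]]]
            if (is.na(par)) is.na(true_par) else
              !is.na(true_par) && identical(map[[par]], true_par)
          }, logical(1)))
      }
    }
  }
  pattern_correct <- !is.na(truth$pattern) &&
    identical(analysis$pattern$pattern, truth$pattern)
  list(k_true = k_true, k_hat = k_hat, k_correct = k_correct,
       topology_correct = topology_correct,
       pattern_correct = pattern_correct,
       sweeps_hat = nrow(analysis$sweeps),
       sweeps_true = truth$true_sweeps)
}
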