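#' Arrange subclones into a clone tree
#'
#' Builds a rooted phylogeny over the fitted subclones using the
#' pigeonhole ("sum") rules on per-sample CCF centroids: a cluster may
#' be the parent of another only if its centroid is at least the
#' child's centroid minus \code{tree_tol} in every sample, and the
#' centroids of siblings may not sum to more than their parent's plus
#' \code{tree_tol} in any sample. Clusters whose CCF vectors cross
#' (each exceeding the other in some sample) therefore end up on
#' separate branches. All rooted trees over the clusters are scored
#' (exhaustively for up to five non-root nodes, greedily beyond), the
#' tree with the smallest total rule violation wins, and ties prefer
#' fewer branching points (linear over branched, mirroring parsimony).
#' The root is the cluster that pigeonhole-dominates all others; when
#' no cluster does, a mutation-free most-recent-common-ancestor node is
#' synthesized. If no tree fits within tolerance the best-scoring tree
#' is returned together with an explicit violation report.
#'
#' @param fit A \code{subclone_fit}, or a centroid matrix (clusters x
#'   samples).
#' @param config List from [mm_config()] (uses \code{tree_tol}).
#' @param n_mutations Per-cluster mutation counts (taken from
#'   \code{fit} when available).
#' @return An object of class \code{clone_tree}: list with
#'   \code{nodes} (data.frame id, parent, n_mutations), \code{centroids}
#'   (including the root), \code{root} (node id), \code{violation}
#'   (total score, 0 when the tree is consistent), \code{violations}
#'   (data.frame describing each violated rule), \code{samples}.
#' @export
build_clone_tree <- function(fit, config = mm_config(),
                             n_mutations = NULL) {
  if (inherits(fit, "subclone_fit")) {
    cen <- fit$centroids
    if (is.null(n_mutations)) n_mutations <- fit$sizes
  } else {
    cen <- as.matrix(fit)
    if (is.null(rownames(cen)))
      rownames(cen) <- paste0("C", seq_len(nrow(cen)))
    if (is.null(n_mutations)) n_mutations <- rep(0L, nrow(cen))
  }
  tol <- config$tree_tol
  S <- ncol(cen); m <- nrow(cen)
  ids <- rownames(cen)

  # root: the cluster dominating all others in every sample, else a
  # synthesized mutation-free MRCA
  dominates <- vapply(seq_len(m), function(j)
    all(vapply(seq_len(m)[-j], function(o)
      all(cen[j, ] >= cen[o, ] - tol), logical(1))), logical(1))
  if (m == 1) dominates <- TRUE
  if (any(dominates)) {
    root_i <- which(dominates)[which.max(rowSums(cen)[dominates])]
    node_cen <- cen
    node_mut <- n_mutations
  } else {
    root_i <- m + 1L
    node_cen <- rbind(cen, pmin(1, apply(cen, 2, max)))
    rownames(node_cen) <- c(ids, "MRCA")
    node_mut <- c(n_mutations, 0L)
  }
  ids <- rownames(node_cen)
  nn <- nrow(node_cen)
  free <- setdiff(seq_len(nn), root_i)

  score_tree <- function(parent) {
    # parent: full-length vector, parent[root_i] = 0
    viol <- 0
    for (j in free) {
      viol <- viol +
        sum(pmax(0, node_cen[j, ] - node_cen[parent[j], ] - tol))
    }
    for (p in seq_len(nn)) {
      ch <- which(parent == p)
      if (length(ch) > 1)
        viol <- viol +
          sum(pmax(0, colSums(node_cen[ch, , drop = FALSE]) -
                     node_cen[p, ] - tol))
    }
    viol
  }
  branchiness <- function(parent)
    sum(tabulate(parent[free], nbins = nn) > 1)

  best_parent <- rep(0L, nn)
  if (length(free) == 0) {
    parent <- rep(0L, nn)
  } else if (length(free) <= 5) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(nn)), length(free))))
    best <- NULL
    for (g in seq_len(nrow(grid))) {
      parent <- rep(0L, nn)
      parent[free] <- grid[g, ]
      if (any(parent[free] == free)) next
      # acyclicity: walk each node to the root
      ok <- TRUE
      for (j in free) {
        cur <- j; steps <- 0
        while (cur != root_i && steps <= nn) {
          cur <- parent[cur]; steps <- steps + 1
        }
        if (cur != root_i) { ok <- FALSE; break }
      }
      if (!ok) next
      sc <- score_tree(parent)
      br <- branchiness(parent)
      if (is.null(best) || sc < best$sc - 1e-12 ||
          (abs(sc - best$sc) <= 1e-12 && br < best$br)) {
        best <- list(parent = parent, sc = sc, br = br)
      }
    }
    parent <- best$parent
  } else {
    # greedy: attach nodes in decreasing total centroid to the placed
    # node that adds the least violation
    ord <- free[order(-rowSums(node_cen[free, , drop = FALSE]))]
    parent <- rep(NA_integer_, nn); parent[root_i] <- 0L
    placed <- root_i
    for (j in ord) {
      scs <- vapply(placed, function(p) {
        tmp <- parent; tmp[j] <- p
        tmp[is.na(tmp)] <- root_i
        score_tree(tmp)
      }, numeric(1))
      parent[j] <- placed[which.min(scs)]
      placed <- c(placed, j)
    }
  }

  viol <- score_tree(parent)
  vreport <- data.frame(rule = character(0), node = character(0),
                        sample = character(0), excess = numeric(0))
  if (viol > 1e-12) {
    for (j in free) {
      ex <- node_cen[j, ] - node_cen[parent[j], ] - tol
      for (s in which(ex > 1e-12))
        vreport <- rbind(vreport, data.frame(
          rule = "pigeonhole", node = ids[j],
          sample = colnames(node_cen)[s], excess = ex[s]))
    }
    for (p in seq_len(nn)) {
      ch <- which(parent == p)
      if (length(ch) > 1) {
        ex <- colSums(node_cen[ch, , drop = FALSE]) - node_cen[p, ] -
          tol
        for (s in which(ex > 1e-12))
          vreport <- rbind(vreport, data.frame(
            rule = "sibling_sum", node = ids[p],
            sample = colnames(node_cen)[s], excess = ex[s]))
      }
    }
  }

  parent_chr <- rep(NA_character_, nn)
  parent_chr[parent != 0L] <- ids[parent[parent != 0L]]
  nodes <- data.frame(
    id = ids, parent = parent_chr,
    n_mutations = as.integer(node_mut), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, centroids = node_cen,
                 root = ids[root_i], violation = viol,
                 violations = vreport,
                 samples = colnames(node_cen)),
            class = "clone_tree")
}

tree_children <- function(tree, id)
  tree$nodes$id[!is.na(tree$nodes$parent) & tree$nodes$parent == id]

tree_ancestors <- function(tree, id) {
  out <- character(0)
  cur <- tree$nodes$parent[match(id, tree$nodes$id)]
  while (!is.na(cur)) {
    if (cur %in% out || length(out) > nrow(tree$nodes))
      stop_mmclone("cyclic parent links in clone tree",
                   class = "mmclone_integrity_error")
    out <- c(out, cur)
    cur <- tree$nodes$parent[match(cur, tree$nodes$id)]
  }
  out
}

tree_descendants <- function(tree, id) {
  out <- character(0)
  todo <- tree_children(tree, id)
  while (length(todo)) {
    out <- c(out, todo)
    todo <- unlist(lapply(todo, tree_children, tree = tree))
  }
  out
}

#' Per-sample clone proportions from a clone tree
#'
#' The terminal proportion of a clone in a sample is its CCF centroid
#' minus the centroids of its children (cells carrying the clone's
#' mutations but none of its descendants'), floored at zero. The
#' proportions sum to the root centroid up to the tree tolerance.
#'
#' @param tree A \code{clone_tree}.
#' @param sample Sample id; \code{NULL} returns the full node x sample
#'   matrix.
#' @return Named numeric vector (or matrix) of clone proportions.
#' @export
clone_proportions <- function(tree, sample = NULL) {
  cen <- tree$centroids
  P <- cen
  for (id in tree$nodes$id) {
    ch <- tree_children(tree, id)
    i <- match(id, rownames(cen))
    childsum <- if (length(ch))
      colSums(cen[match(ch, rownames(cen)), , drop = FALSE]) else 0
    P[i, ] <- pmax(0, cen[i, ] - childsum)
  }
  if (is.null(sample)) P else P[, sample]
}

#' Detect clonal sweeps along a timepoint series
#'
#' Scans consecutive timepoints of one site class for dominance
#' turnover: an event is emitted when a clone that was below the minor
#' threshold becomes dominant (proportion >= \code{dominance}) while a
#' previously dominant clone falls below the detection proportion.
#'
#' @param tree A \code{clone_tree}.
#' @param samples Sample-sheet rows of the comparable site class,
#'   spanning >= 2 timepoints. Proportions of samples sharing a
#'   timepoint are averaged.
#' @param config List from [mm_config()] (uses \code{dominance} and
#'   \code{minor_threshold}).
#' @return data.frame of sweep events: \code{timepoint_from},
#'   \code{timepoint_to}, \code{rising}, \code{displaced}; empty with
#'   fewer than two timepoints.
#' @export
detect_sweeps <- function(tree, samples, config = mm_config()) {
  empty <- data.frame(timepoint_from = numeric(0),
                      timepoint_to = numeric(0),
                      rising = character(0),
                      displaced = character(0))
  tps <- sort(unique(samples$timepoint))
  if (length(tps) < 2) return(empty)
  P <- clone_proportions(tree)
  prop_at <- function(tp) {
    s <- samples$sample_id[samples$timepoint == tp]
    s <- intersect(s, colnames(P))
    if (!length(s)) return(NULL)
    rowMeans(P[, s, drop = FALSE])
  }
  events <- empty
  for (i in seq_len(length(tps) - 1)) {
    p0 <- prop_at(tps[i]); p1 <- prop_at(tps[i + 1])
    if (is.null(p0) || is.null(p1)) next
    rising <- names(p0)[p0 < config$minor_threshold &
                          p1 >= config$dominance]
    displaced <- names(p0)[p0 >= config$dominance &
                             p1 < config$minor_threshold]
    if (length(rising) && length(displaced)) {
      events <- rbind(events, data.frame(
        timepoint_from = tps[i], timepoint_to = tps[i + 1],
        rising = paste(rising, collapse = ","),
        displaced = paste(displaced, collapse = ",")))
    }
  }
  events
}

#' Flag genes hit independently on separate branches
#'
#' A gene (or configured gene family, e.g. the KDM/KMT epigenetic
#' modifiers) shows parallel evolution when it is mutated on at least
#' two branches neither of which is ancestral to the other, with no
#' shared ancestral event in that gene.
#'
#' @param tree A \code{clone_tree}.
#' @param branch_genes Named list: node id -> character vector of gene
#'   symbols mutated on that branch.
#' @param families Optional named list: family name -> character vector
#'   of gene-symbol prefixes (e.g. \code{list(KDM_KMT = c("KDM",
#'   "KMT"))}); family members on different branches then also flag
#'   the family.
#' @return Character vector of flagged genes/families.
#' @export
detect_parallel_evolution <- function(tree, branch_genes,
                                      families = NULL) {
  flag_symbol <- function(nodes_with) {
    if (length(nodes_with) < 2) return(FALSE)
    for (a in seq_along(nodes_with)) {
      anc_a <- tree_ancestors(tree, nodes_with[a])
      if (any(anc_a %in% nodes_with)) next
      for (b in seq_along(nodes_with)) {
        if (b == a) next
        if (!(nodes_with[b] %in% anc_a) &&
            !(nodes_with[a] %in% tree_ancestors(tree, nodes_with[b])))
          return(TRUE)
      }
    }
    FALSE
  }
  all_genes <- unique(unlist(branch_genes))
  flagged <- character(0)
  for (g in all_genes) {
    nodes_with <- names(branch_genes)[vapply(branch_genes,
                                             function(x) g %in% x,
                                             logical(1))]
    if (flag_symbol(nodes_with)) flagged <- c(flagged, g)
  }
  for (fam in names(families)) {
    pref <- families[[fam]]
    nodes_with <- names(branch_genes)[vapply(branch_genes, function(x)
      any(vapply(pref, function(p) any(startsWith(x, p)),
                 logical(1))), logical(1))]
    if (flag_symbol(nodes_with)) flagged <- c(flagged, fam)
  }
  unique(flagged)
}

#' Export a clone tree as Newick text
#'
#' One labelled node per subclone (internal clone nodes are retained as
#' singleton nodes where needed); branch lengths carry the per-branch
#' mutation counts.
#'
#' @param tree A \code{clone_tree}.
#' @return Newick string terminated by \code{";"}.
#' @export
export_tree_newick <- function(tree) {
  nodes <- tree$nodes
  # integrity: every non-root node must reach the root
  for (id in nodes$id) {
    seen <- character(0); cur <- id
    while (!is.na(nodes$parent[match(cur, nodes$id)])) {
      cur <- nodes$parent[match(cur, nodes$id)]
      if (cur %in% seen)
        stop_mmclone("cyclic parent links in clone tree",
                     class = "mmclone_integrity_error")
      seen <- c(seen, cur)
    }
  }
  rec <- function(id) {
    ch <- tree_children(tree, id)
    lab <- id
    len <- nodes$n_mutations[match(id, nodes$id)]
    inner <- if (length(ch))
      paste0("(", paste(vapply(ch, rec, character(1)),
                        collapse = ","), ")") else ""
    if (id == tree$root) paste0(inner, lab)
    else paste0(inner, lab, ":", len)
  }
  paste0(rec(tree$root), ";")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("Clone tree (", nrow(x$nodes), " nodes, root ", x$root, ")\n",
      sep = "")
  cat(" ", export_tree_newick(x), "\n")
  if (x$violation > 1e-12)
    cat("  NOTE: no fully consistent tree; total rule violation ",
        signif(x$violation, 3), " (see $violations)\n", sep = "")
  invisible(x)
}

#' @export
plot.clone_tree <- function(x, ...) {
  P <- clone_proportions(x)
  barplot(P, beside = FALSE, col = seq_len(nrow(P)),
          ylab = "clone proportion", las = 2,
          legend.text = rownames(P), ...)
  invisible(x)
}
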