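# independent exhaustive-enumeration oracle over rooted trees on a
# centroid matrix: returns the minimal total pigeonhole/sibling-sum
# violation and all parent vectors achieving it
tree_oracle <- function(cen, root, tol = 0.10) {
  n <- nrow(cen)
  free <- setdiff(seq_len(n), root)
  viol_of <- function(parent) {
    v <- 0
    for (j in free)
      v <- v + sum(pmax(0, cen[j, ] - cen[parent[j], ] - tol))
    for (p in seq_len(n)) {
      ch <- which(parent == p)
      if (length(ch) > 1)
        v <- v + sum(pmax(0, colSums(cen[ch, , drop = FALSE]) -
                            cen[p, ] - tol))
    }
    v
  }
  acyclic <- function(parent) {
    for (j in free) {
      cur <- j; st <- 0
      while (cur != root && st <= n) { cur <- parent[cur]; st <- st + 1 }
      if (cur != root) return(FALSE)
    }
    TRUE
  }
  grid <- expand.grid(rep(list(seq_len(n)), length(free)))
  best <- Inf; winners <- list()
  for (g in seq_len(nrow(grid))) {
    parent <- rep(0L, n); parent[free] <- as.integer(grid[g, ])
    if (any(parent[free] == free) || !acyclic(parent)) next
    v <- viol_of(parent)
    if (v < best - 1e-12) { best <- v; winners <- list(parent) }
    else if (v <= best + 1e-12) winners <- c(winners, list(parent))
  }
  list(best = best, winners = winners)
}

tree_parent_vec <- function(tree) {
  ids <- tree$nodes$id
  vapply(seq_along(ids), function(i) {
    p <- tree$nodes$parent[i]
    if (is.na(p)) 0L else match(p, ids)
  }, integer(1))
}

test_that("nested centroids produce a chain", {
  cen <- rbind(C1 = c(1, 1), C2 = c(0.4, 0.3))
  colnames(cen) <- c("s1", "s2")
  tr <- build_clone_tree(cen, n_mutations = c(10, 5))
  expect_equal(tr$root, "C1")
  expect_equal(tr$nodes$parent, c(NA, "C1"))
  expect_equal(tr$violation, 0)
})

test_that("crossing CCF vectors are placed on separate branches", {
  cen <- rbind(R = c(1, 1), A = c(0.6, 0.1), B = c(0.3, 0.8))
  colnames(cen) <- c("s1", "s2")
  tr <- build_clone_tree(cen)
  expect_equal(tr$nodes$parent, c(NA, "R", "R"))
  # exhaustive-enumeration oracle agrees this is the best tree
  orc <- tree_oracle(cen, root = 1)
  expect_equal(tr$violation, orc$best)
  expect_true(any(vapply(orc$winners, identical,
                         logical(1), y = tree_parent_vec(tr))))
})

test_that("sibling-sum violations are minimized over all trees", {
  # children cannot both hang off the root without exceeding it
  cen <- rbind(R = c(1, 1), A = c(0.65, 0.6), B = c(0.5, 0.55))
  colnames(cen) <- c("s1", "s2")
  tr <- build_clone_tree(cen)
  orc <- tree_oracle(cen, root = 1)
  expect_equal(tr$violation, orc$best)
  expect_true(any(vapply(orc$winners, identical,
                         logical(1), y = tree_parent_vec(tr))))
  # and when no tree fits, the violation report is explicit:
  # A and B cross by more than the tolerance yet together exceed the
  # root, so neither nesting nor branching is consistent
  cen2 <- rbind(R = c(1, 1), A = c(0.7, 0.3), B = c(0.5, 0.9))
  colnames(cen2) <- c("s1", "s2")
  tr2 <- build_clone_tree(cen2)
  orc2 <- tree_oracle(cen2, root = 1)
  expect_gt(orc2$best, 0)
  expect_equal(tr2$violation, orc2$best)
  expect_gt(nrow(tr2$violations), 0)
})

test_that("a mutation-free MRCA root is synthesized when needed", {
  cen <- rbind(A = c(0.7, 0.1), B = c(0.1, 0.7))
  colnames(cen) <- c("s1", "s2")
  tr <- build_clone_tree(cen)
  expect_equal(tr$root, "MRCA")
  expect_equal(sort(tr$nodes$id[!is.na(tr$nodes$parent) &
                                  tr$nodes$parent == "MRCA"]),
               c("A", "B"))
})

mk_tree <- function(cen, parents) {
  structure(list(
    nodes = data.frame(id = rownames(cen), parent = parents,
                       n_mutations = 0L, stringsAsFactors = FALSE),
    centroids = cen, root = rownames(cen)[is.na(parents)],
    violation = 0,
    violations = data.frame(), samples = colnames(cen)),
    class = "clone_tree")
}

test_that("clone proportions subtract children and floor at zero", {
  cen <- rbind(R = c(1, 1), A = c(0.4, 0.6), B = c(0.3, 0.3))
  colnames(cen) <- c("s1", "s2")
  tr <- mk_tree(cen, c(NA, "R", "R"))
  P <- clone_proportions(tr)
  expect_equal(unname(P["R", ]), c(1 - 0.4 - 0.3, 1 - 0.6 - 0.3))
  expect_equal(unname(P["A", ]), c(0.4, 0.6))
  expect_equal(unname(colSums(P)), unname(cen["R", ]))

  # a chain subtracts only the direct child
  tr_chain <- mk_tree(cen, c(NA, "R", "A"))
  Pc <- clone_proportions(tr_chain)
  expect_equal(unname(Pc["A", ]), c(0.1, 0.3))
  expect_equal(unname(Pc["R", ]), c(0.6, 0.4))

  # child exceeding the parent within tolerance never goes negative
  cen2 <- rbind(R = c(0.9, 0.9), A = c(0.95, 0.85))
  colnames(cen2) <- c("s1", "s2")
  P2 <- clone_proportions(build_clone_tree(cen2))
  expect_true(all(P2 >= 0))
  expect_equal(unname(P2["R", 1]), 0)
})

test_that("sweeps are dominance turnovers between timepoints", {
  mk_samples <- function(n) data.frame(
    sample_id = paste0("t", seq_len(n)), patient_id = "P1",
    site_class = "iliac_crest_left", anatomical_label = "",
    timepoint = seq_len(n) - 1, purity = 0.9)

  cen <- rbind(R = c(1, 1), A = c(0.7, 0.0), B = c(0.1, 0.8))
  colnames(cen) <- c("t1", "t2")
  sw <- detect_sweeps(build_clone_tree(cen), mk_samples(2))
  expect_equal(nrow(sw), 1)
  expect_equal(sw$rising, "B")
  expect_equal(sw$displaced, "A")

  cen_stable <- rbind(R = c(1, 1), A = c(0.7, 0.7))
  colnames(cen_stable) <- c("t1", "t2")
  expect_equal(nrow(detect_sweeps(build_clone_tree(cen_stable),
                                  mk_samples(2))), 0)

  cen3 <- rbind(R = c(1, 1, 1), A = c(0.75, 0.05, 0.0),
                B = c(0.10, 0.80, 0.05), C = c(0.0, 0.10, 0.85))
  colnames(cen3) <- c("t1", "t2", "t3")
  sw3 <- detect_sweeps(build_clone_tree(cen3), mk_samples(3))
  expect_equal(nrow(sw3), 2)
  expect_equal(sw3$rising, c("B", "C"))

  expect_equal(nrow(detect_sweeps(build_clone_tree(cen),
                                  mk_samples(2)[1, ])), 0)
})

test_that("parallel evolution flags independent hits on branches", {
  cen <- rbind(R = c(1, 1), A = c(0.6, 0.1), B = c(0.3, 0.8))
  colnames(cen) <- c("s1", "s2")
  tr <- build_clone_tree(cen)
  expect_equal(detect_parallel_evolution(
    tr, list(R = c("NRAS"), A = c("TP53"), B = c("TP53"))), "TP53")
  expect_equal(detect_parallel_evolution(
    tr, list(R = c("TP53"), A = character(0), B = character(0))),
    character(0))
  # ancestral shared event suppresses the flag
  expect_equal(detect_parallel_evolution(
    tr, list(R = c("TP53"), A = c("TP53"), B = character(0))),
    character(0))
  # gene-family mode
  expect_equal(detect_parallel_evolution(
    tr, list(R = character(0), A = c("KDM4B"), B = c("KMT2D")),
    families = list(KDM_KMT = c("KDM", "KMT"))), "KDM_KMT")
})

test_that("Newick export round-trips through a standard reader", {
  skip_if_not_installed("ape")
  single <- build_clone_tree(matrix(1, 1, 2,
                                    dimnames = list("C1",
                                                    c("s1", "s2"))))
  expect_equal(export_tree_newick(single), "C1;")

  cen <- rbind(R = c(1, 1), A = c(0.6, 0.6), B = c(0.3, 0.3))
  colnames(cen) <- c("s1", "s2")
  chain <- build_clone_tree(cen, n_mutations = c(8, 5, 3))
  nwk <- export_tree_newick(chain)
  expect_equal(nwk, "((B:3)A:5)R;")
  ph <- ape::read.tree(text = nwk)
  expect_equal(ph$tip.label, "B")
  expect_true(all(c("A", "R") %in% ph$node.label))

  cen2 <- rbind(R = c(1, 1), A = c(0.6, 0.1), B = c(0.3, 0.8))
  colnames(cen2) <- c("s1", "s2")
  tr2 <- build_clone_tree(cen2, n_mutations = c(8, 5, 3))
  ph2 <- ape::read.tree(text = export_tree_newick(tr2))
  expect_setequal(ph2$tip.label, c("A", "B"))

  bad <- tr2
  bad$nodes$parent <- c("B", "R", "A")
  expect_error(export_tree_newick(bad),
               class = "mmclone_integrity_error")
})
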