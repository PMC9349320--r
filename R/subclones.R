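#' Cluster mutations into subclones (binomial mixture over CCF vectors)
#'
#' Fits a finite mixture model to the multi-sample CCF profiles of a
#' patient's mutations. Each cluster k has a per-sample CCF centroid
#' \eqn{\phi_{ks}}; the likelihood of mutation i in sample s is
#' binomial, \eqn{alt_{is} \sim Binom(depth_{is}, \phi_{ks} c_{is})},
#' where \eqn{c_{is}} is the allele fraction a fully clonal mutation
#' would show given the sample's purity, the locus copy number and the
#' assigned multiplicity (see [expected_vaf()]). The model is fitted by
#' EM, the number of clusters is selected by BIC over k = 1..kmax, and
#' mutations below the minimum clustering depth (50 in every sample by
#' default) are assigned post hoc to the best-fitting cluster. Clusters
#' violating the subclone evidence rule (at least two member mutations
#' or one member copy-number aberration) are marked invalid and merged
#' into the nearest valid cluster.
#'
#' @param ccf_matrix CCF matrix from [build_ccf_matrix()] (after
#'   filtering).
#' @param config List from [mm_config()]; uses
#'   \code{cluster_min_depth}, \code{kmax}, \code{em_seed},
#'   \code{em_restarts}, \code{em_maxit}, \code{em_tol}.
#' @param cna_ccf Optional matrix (one row per copy-number aberration,
#'   one column per sample) of aberration cancer-cell fractions; each
#'   CNA is attached to the nearest cluster and counts toward the
#'   evidence rule.
#' @return An object of class \code{subclone_fit}: list with
#'   \code{assignments} (variant_id, cluster, eligible),
#'   \code{centroids} (k x samples matrix), \code{pi} (mixing
#'   weights), \code{sizes}, \code{valid}, \code{cna_support},
#'   \code{loglik}, \code{bic} (per-k table), \code{k},
#'   \code{samples}.
#' @export
cluster_mutations <- function(ccf_matrix, config = mm_config(),
                              cna_ccf = NULL) {
  ev <- ccf_matrix[ccf_matrix$evaluable, , drop = FALSE]
  sids <- unique(ccf_matrix$sample_id)
  vids <- unique(ccf_matrix$variant_id)
  S <- length(sids)

  wide <- function(col) {
    m <- matrix(NA_real_, length(vids), S,
                dimnames = list(vids, sids))
    m[cbind(match(ev$variant_id, vids), match(ev$sample_id, sids))] <-
      ev[[col]]
    m
  }
  A <- wide("alt_reads"); D <- wide("depth"); CCF <- wide("ccf")
  # clonal allele fraction per entry: n_chr * p / (p * cn + 2 (1 - p))
  CC <- wide("n_chr") * wide("purity") /
    (wide("purity") * wide("total_cn") + 2 * (1 - wide("purity")))

  complete <- rowSums(is.na(D)) == 0
  eligible <- complete & apply(D, 1, function(d)
    all(d >= config$cluster_min_depth))
  if (sum(eligible) < 2) {
    warning("fewer than 2 clusterable mutations; single-cluster fallback")
    cen <- matrix(pmin(1, colMeans(CCF, na.rm = TRUE)), 1, S,
                  dimnames = list("C1", sids))
    fit <- list(assignments = data.frame(variant_id = vids,
                                         cluster = 1L,
                                         eligible = eligible,
                                         stringsAsFactors = FALSE),
                centroids = cen, pi = 1,
                sizes = length(vids), valid = TRUE,
                cna_support = 0L, loglik = NA_real_,
                bic = data.frame(k = 1L, bic = NA_real_), k = 1L,
                samples = sids, config = config)
    class(fit) <- "subclone_fit"
    return(fit)
  }

  Ae <- A[eligible, , drop = FALSE]; De <- D[eligible, , drop = FALSE]
  Ce <- CC[eligible, , drop = FALSE]
  CCFe <- CCF[eligible, , drop = FALSE]
  n <- nrow(Ae)

  # binomial coefficients are constant across clusters and iterations;
  # the compiled EM omits them and they are added back here
  lc_const <- sum(lchoose(De, Ae))

  em_fit <- function(k, phi0) {
    f <- binom_mix_em_cpp(Ae, De, Ce, phi0, config$em_tol,
                          as.integer(config$em_maxit))
    list(phi = f$phi, pi = as.numeric(f$pi),
         loglik = f$loglik + lc_const)
  }

  # deterministic Ward-linkage initialization (robust to the local
  # optima random kmeans starts can fall into on elongated clusters)
  hc_sub <- if (n > 1500) with_seed(config$em_seed,
                                    sample.int(n, 1500)) else
    seq_len(n)
  hc <- stats::hclust(stats::dist(CCFe[hc_sub, , drop = FALSE]),
                      method = "ward.D2")
  hc_centers <- function(k) {
    grp <- stats::cutree(hc, k = k)
    t(vapply(seq_len(k), function(g)
      colMeans(CCFe[hc_sub, , drop = FALSE][grp == g, ,
                    drop = FALSE]), numeric(S)))
  }

  run_k <- function(k) {
    best <- NULL
    for (r in seq_len(max(1, config$em_restarts))) {
      phi0 <- with_seed(config$em_seed + 1000L * r + k, {
        if (k == 1) {
          matrix(pmin(1, colMeans(CCFe)), 1, S)
        } else if (r == 1) {
          hc_centers(min(k, n))
        } else {
          km <- suppressWarnings(
            kmeans(CCFe, centers = min(k, n - 1), nstart = 5,
                   iter.max = 30))
          cen <- km$centers
          if (nrow(cen) < k)
            cen <- rbind(cen, matrix(runif(S * (k - nrow(cen))),
                                     ncol = S))
          pmin(pmax(cen + if (r > 2)
            matrix(runif(k * S, -0.05, 0.05), k, S) else 0, 0), 1)
        }
      })
      f <- em_fit(k, matrix(pmin(pmax(phi0, 0), 1), ncol = S))
      if (is.null(best) || f$loglik > best$loglik) best <- f
    }
    best
  }

  fits <- list(); bics <- numeric(0)
  for (k in seq_len(config$kmax)) {
    if (k > n) break
    fits[[k]] <- run_k(k)
    bics[k] <- -2 * fits[[k]]$loglik + (k * S + k - 1) * log(n)
    # stop scanning once BIC has deteriorated twice in a row
    if (k >= 3 && bics[k] > bics[k - 1] && bics[k - 1] > bics[k - 2])
      break
  }
  k_best <- which.min(bics)
  fit <- fits[[k_best]]
  phi <- fit$phi

  # assign every variant (eligible by posterior, others post hoc by
  # maximum likelihood over its evaluable entries)
  assign_one <- function(i) {
    ok <- !is.na(D[i, ])
    if (!any(ok)) return(NA_integer_)
    ll <- vapply(seq_len(k_best), function(j) {
      q <- pmin(pmax(phi[j, ok] * CC[i, ok], 1e-6), 1 - 1e-6)
      sum(dbinom(A[i, ok], D[i, ok], q, log = TRUE)) + log(fit$pi[j])
    }, numeric(1))
    which.max(ll)
  }
  cl <- vapply(seq_along(vids), assign_one, integer(1))

  # evidence rule: >= 2 mutations or >= 1 attached CNA
  sizes <- tabulate(cl, nbins = k_best)
  cna_support <- integer(k_best)
  if (!is.null(cna_ccf) && nrow(cna_ccf) > 0) {
    for (i in seq_len(nrow(cna_ccf))) {
      d <- vapply(seq_len(k_best), function(j)
        sum((cna_ccf[i, ] - phi[j, ])^2), numeric(1))
      jj <- which.min(d)
      cna_support[jj] <- cna_support[jj] + 1L
    }
  }
  valid <- sizes >= 2 | cna_support >= 1
  if (!any(valid)) valid[which.max(sizes)] <- TRUE
  if (any(!valid)) {
    for (j in which(!valid)) {
      d <- vapply(which(valid), function(v)
        sum((phi[j, ] - phi[v, ])^2), numeric(1))
      cl[cl == j] <- which(valid)[which.min(d)]
    }
  }
  keep <- sort(unique(cl[!is.na(cl)]))
  remap <- match(cl, keep)
  phi <- phi[keep, , drop = FALSE]
  rownames(phi) <- paste0("C", seq_along(keep))
  colnames(phi) <- sids

  res <- list(
    assignments = data.frame(variant_id = vids, cluster = remap,
                             eligible = eligible,
                             stringsAsFactors = FALSE),
    centroids = pmin(pmax(phi, 0), 1),
    pi = fit$pi[keep] / sum(fit$pi[keep]),
    sizes = tabulate(remap, nbins = length(keep)),
    valid = rep(TRUE, length(keep)),
    cna_support = cna_support[keep],
    loglik = fit$loglik,
    bic = data.frame(k = seq_along(bics), bic = bics),
    k = length(keep), samples = sids, config = config)
  class(res) <- "subclone_fit"
  res
}

#' @export
print.subclone_fit <- function(x, ...) {
  cat("Subclone mixture fit:", x$k, "cluster(s) over",
      length(x$samples), "sample(s),",
      nrow(x$assignments), "mutations\n")
  print(round(x$centroids, 3))
  invisible(x)
}

#' @export
summary.subclone_fit <- function(object, ...) {
  cat("Subclone mixture fit\n")
  cat("  samples:   ", paste(object$samples, collapse = ", "), "\n")
  cat("  mutations: ", nrow(object$assignments), " (",
      sum(object$assignments$eligible), " used for clustering)\n",
      sep = "")
  cat("  clusters:  ", object$k, " (BIC-selected; log-likelihood ",
      round(object$loglik, 2), ")\n", sep = "")
  df <- data.frame(cluster = rownames(object$centroids),
                   n_mutations = object$sizes,
                   cna_support = object$cna_support,
                   round(object$centroids, 3))
  print(df, row.names = FALSE)
  invisible(df)
}

#' @export
coef.subclone_fit <- function(object, ...) object$centroids

#' @export
plot.subclone_fit <- function(x, ccf_matrix = NULL, samples = NULL,
                              ...) {
  s <- samples %||% x$samples[seq_len(min(2, length(x$samples)))]
  if (length(s) < 2 || is.null(ccf_matrix)) {
    barplot(t(x$centroids), beside = TRUE,
            ylab = "cluster CCF", xlab = "subclone", ylim = c(0, 1),
            legend.text = x$samples, ...)
    return(invisible(x))
  }
  w <- ccf_wide(ccf_matrix, "ccf")
  cl <- x$assignments$cluster[match(rownames(w),
                                    x$assignments$variant_id)]
  plot(w[, s[1]], w[, s[2]], col = cl, pch = 16,
       xlab = paste("CCF", s[1]), ylab = paste("CCF", s[2]),
       xlim = c(0, 1), ylim = c(0, 1), ...)
  points(x$centroids[, s[1]], x$centroids[, s[2]], pch = 3, cex = 2,
         col = seq_len(x$k))
  invisible(x)
}
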