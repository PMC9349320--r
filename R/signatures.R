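#' Tabulate mutations into the 96 substitution contexts
#'
#' Accepts either a data.frame of mutations with a \code{context96}
#' column (0-based class indices, e.g. from the mutation table) or with
#' \code{ref}, \code{alt}, \code{p5}, \code{p3} columns (flanking
#' bases), in which case purine-reference substitutions are
#' strand-normalized via [context96_index()]. Mutations with an
#' ambiguous base or missing context are skipped with a warning.
#'
#' @param mutations data.frame as described, or an integer vector of
#'   0-based context indices.
#' @return Named integer vector of length 96 (names the context
#'   strings); sums to the number of usable mutations.
#' @export
count_contexts <- function(mutations) {
  if (is.data.frame(mutations)) {
    idx <- if (!is.null(mutations$context96) &&
               !all(is.na(mutations$context96))) {
      as.integer(mutations$context96)
    } else {
      context96_index(mutations$ref, mutations$alt, mutations$p5,
                      mutations$p3)
    }
  } else idx <- as.integer(mutations)
  bad <- is.na(idx) | idx < 0 | idx > 95
  if (any(bad)) {
    warning(sum(bad), " mutation(s) with ambiguous or missing context ",
            "skipped")
    idx <- idx[!bad]
  }
  counts <- tabulate(idx + 1L, nbins = 96)
  names(counts) <- sbs96_contexts()
  counts
}

#' Fit signature exposures by maximum likelihood
#'
#' Maximizes the multinomial log-likelihood of a 96-context count
#' vector under the mixture \eqn{\sum_k e_k \cdot profile_k} over the
#' probability simplex, by expectation-maximization with closed-form
#' updates. Iteration stops when the log-likelihood improves by less
#' than \code{tol}.
#'
#' @param counts96 Numeric vector of 96 context counts (sum >= 1).
#' @param catalog A \code{sig_catalog}.
#' @param tol Convergence threshold on the log-likelihood improvement.
#' @param maxit Iteration cap.
#' @param init Optional starting exposure vector (defaults to
#'   uniform); a warm start accelerates repeated fits on related data.
#' @return List with \code{exposures} (named, nonnegative, summing to
#'   1), \code{loglik} and \code{iterations}.
#' @export
fit_exposures <- function(counts96, catalog, tol = 1e-10,
                          maxit = 100000, init = NULL) {
  if (length(counts96) != 96)
    stop_mmclone("counts96 must have length 96",
                 class = "mmclone_domain_error")
  if (sum(counts96) < 1)
    stop_mmclone("need at least one mutation",
                 class = "mmclone_domain_error")
  K <- length(catalog$names)
  if (K == 1) {
    ll <- sum(counts96 * log(pmax(catalog$profiles[, 1], 1e-300)))
    return(list(exposures = setNames(1, catalog$names),
                loglik = ll, iterations = 0L))
  }
  e0 <- if (is.null(init)) rep(1 / K, K) else rep_len(init, K)
  fit <- em_exposures_cpp(as.numeric(counts96), catalog$profiles,
                          e0, tol, as.integer(maxit))
  names(fit$exposures) <- catalog$names
  fit
}

#' Likelihood-ratio presence test for a target signature
#'
#' Tests whether a target signature contributes to the observed
#' 96-context counts: the multinomial mixture is fitted with and
#' without the target, and the likelihood-ratio statistic
#' \eqn{2 (\ell_{full} - \ell_{constrained})} is compared to its null
#' distribution obtained by parametric bootstrap from the constrained
#' fit (resampling count vectors of the same total). The p-value uses
#' the (r + 1) / (B + 1) continuity correction.
#'
#' @param counts96 96-context counts (sum >= 1).
#' @param catalog A \code{sig_catalog} containing the target.
#' @param target Name of the target signature.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap resampling.
#' @return List with \code{p}, \code{lr} (observed statistic),
#'   \code{exposure} (fitted target exposure), \code{B}.
#' @export
presence_test <- function(counts96, catalog, target, B = 1000,
                          seed = 1) {
  if (!(target %in% catalog$names))
    stop_mmclone("target signature '", target, "' not in catalog",
                 class = "mmclone_domain_error")
  keep <- setdiff(catalog$names, target)
  if (!length(keep))
    stop_mmclone("catalog must contain background signatures",
                 class = "mmclone_domain_error")
  reduced <- sig_catalog(catalog$profiles[, keep, drop = FALSE], keep)
  lr_stat <- function(cnt, init_full = NULL, init_red = NULL) {
    full <- fit_exposures(cnt, catalog, init = init_full)
    constr <- fit_exposures(cnt, reduced, init = init_red)
    list(lr = max(0, 2 * (full$loglik - constr$loglik)),
         exposure = full$exposures[[target]],
         full = full$exposures, red = constr$exposures,
         null_probs = as.numeric(reduced$profiles %*%
                                   constr$exposures))
  }
  obs <- lr_stat(counts96)
  n <- sum(counts96)
  # bootstrap replicates use the same (uniform) initialization as the
  # observed fits so that optimizer behaviour is identical under the
  # null and in the resamples
  r <- with_seed(seed, {
    hits <- 0L
    cnt_b <- rmultinom(B, n, obs$null_probs)
    for (b in seq_len(B)) {
      lr_b <- lr_stat(as.numeric(cnt_b[, b]))$lr
      if (lr_b >= obs$lr - 1e-12) hits <- hits + 1L
    }
    hits
  })
  list(p = (r + 1) / (B + 1), lr = obs$lr, exposure = obs$exposure,
       B = B)
}

#' Flag a subclone as a single-cell expansion candidate
#'
#' Fits the branch-private (subclone-defining) mutations of a subclone
#' against the signature catalog and tests for the presence of the
#' treatment (melphalan-like) target signature. A subclone is flagged
#' when it carries at least \code{min_mutations} defining mutations
#' (default 25), the presence test rejects at \code{alpha} (default
#' 0.05), and the fitted target exposure is positive. Subclones below
#' the mutation cut-off are reported as not evaluable, never as
#' negative.
#'
#' @param context_counts 96-context counts of the subclone-defining
#'   mutations (from [count_contexts()]).
#' @param catalog A \code{sig_catalog} containing the target.
#' @param target Name of the target signature.
#' @param config List from [mm_config()] (uses
#'   \code{min_signature_mutations}, \code{presence_alpha},
#'   \code{bootstrap_B}, \code{bootstrap_seed}).
#' @return List (a signature-fit record) with \code{n},
#'   \code{status} in \code{"flagged"}, \code{"not_flagged"},
#'   \code{"not_evaluable"}, \code{exposures}, \code{loglik},
#'   \code{presence_p}.
#' @export
flag_single_cell_expansion <- function(context_counts, catalog, target,
                                       config = mm_config()) {
  n <- sum(context_counts)
  if (n < config$min_signature_mutations) {
    return(list(n = n, status = "not_evaluable", exposures = NULL,
                loglik = NA_real_, presence_p = NA_real_))
  }
  fit <- fit_exposures(context_counts, catalog)
  pt <- presence_test(context_counts, catalog, target,
                      B = config$bootstrap_B,
                      seed = config$bootstrap_seed)
  flagged <- pt$p < config$presence_alpha && pt$exposure > 0
  list(n = n, status = if (flagged) "flagged" else "not_flagged",
       exposures = fit$exposures, loglik = fit$loglik,
       presence_p = pt$p)
}

#' Packaged synthetic signature catalog
#'
#' A deterministic synthetic stand-in catalog for tests and simulation:
#' seven smooth background profiles (labelled after the COSMIC
#' signatures commonly refitted in myeloma: SBS1, SBS2, SBS5, SBS8,
#' SBS9, SBS13, SBS18) plus a sparse treatment-exposure signature
#' (\code{"SBS-MM1-like"}) concentrated on eight contexts. The profiles
#' are synthetic: they are NOT the COSMIC profiles nor the real
#' SBS-MM1, whose catalog can be supplied at runtime via
#' [read_signature_catalog()].
#'
#' @return A \code{sig_catalog} with 8 signatures.
#' @export
default_signature_catalog <- function() {
  bg_names <- c("SBS1", "SBS2", "SBS5", "SBS8", "SBS9", "SBS13",
                "SBS18")
  profiles <- with_seed(20260101, {
    m <- matrix(0, 96, 8)
    for (k in seq_along(bg_names)) {
      # smooth positive profile with signature-specific peaks
      base <- runif(96, 0.2, 1)
      peaks <- sample.int(96, 12)
      base[peaks] <- base[peaks] + runif(12, 2, 6)
      m[, k] <- base
    }
    m
  })
  # sparse treatment signature: eight contexts, spread over the classes
  treat <- numeric(96)
  treat[c(3, 17, 29, 41, 55, 67, 81, 93)] <- 1 / 8
  profiles[, 8] <- treat
  sig_catalog(profiles, c(bg_names, "SBS-MM1-like"))
}
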