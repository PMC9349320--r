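#' Simulation configuration
#'
#' Defines the study conditions emulated by the synthetic-cohort
#' generator: multi-site multi-timepoint sampling of a planted subclone
#' phylogeny with scenario-scripted clone trajectories, purities drawn
#' from \code{purity_range}, negative-binomial sequencing depth around
#' a median-matched mean of 121x, binomial allele counts at the allele
#' fraction implied by the clone fractions, purity, multiplicity and
#' locus copy number, and branch-specific signature mixtures in which
#' post-treatment branches receive the treatment (melphalan-like)
#' signature.
#'
#' @param scenario One of \code{"single_cell_expansion"},
#'   \code{"coexisting"}, \code{"alternating"}, \code{"mixed"},
#'   \code{"null"}.
#' @param n_patients Cohort size for [simulate_cohort()].
#' @param n_followups Number of follow-up timepoints (default 2).
#' @param trunk_mutations Mutations on the trunk (default 100).
#' @param branch_mutations Range of per-branch mutation counts
#'   (default 25--400).
#' @param mean_depth Mean sequencing depth (default 121).
#' @param depth_dispersion Negative-binomial size parameter.
#' @param purity_range Sample purity range (default 0.5--0.95).
#' @param target_weight Treatment-signature exposure planted on
#'   post-treatment branches (default 0.3).
#' @param catalog Signature catalog used for context sampling.
#' @param target Name of the treatment signature in \code{catalog}.
#' @param clinical_association Couple the clinical record to the
#'   pattern (as observed in patients) or draw it independently.
#' @param ig_variants Number of immunoglobulin-locus decoy variants
#'   added per patient (exercise the exclusion filter; default 2).
#' @return Named list of class \code{sim_config}.
#' @export
sim_config <- function(scenario = "mixed", n_patients = 24,
                       n_followups = 2, trunk_mutations = 100,
                       branch_mutations = c(25, 400),
                       mean_depth = 121, depth_dispersion = 10,
                       purity_range = c(0.5, 0.95),
                       target_weight = 0.3,
                       catalog = default_signature_catalog(),
                       target = "SBS-MM1-like",
                       clinical_association = TRUE,
                       ig_variants = 2) {
  scenario <- match.arg(scenario,
                        c("mixed", "single_cell_expansion",
                          "coexisting", "alternating", "null"))
  structure(list(scenario = scenario, n_patients = n_patients,
                 n_followups = n_followups,
                 trunk_mutations = trunk_mutations,
                 branch_mutations = branch_mutations,
                 mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion,
                 purity_range = purity_range,
                 target_weight = target_weight, catalog = catalog,
                 target = target,
                 clinical_association = clinical_association,
                 ig_variants = ig_variants),
            class = "sim_config")
}

# background signature mixture over the seven background profiles
BG_EXPOSURES <- c(SBS1 = 0.25, SBS2 = 0.10, SBS5 = 0.35, SBS8 = 0.10,
                  SBS9 = 0.10, SBS13 = 0.05, SBS18 = 0.05)

# scenario scripts: clone tree and cumulative clone CCFs per sample.
# Rows are clones, columns samples; entries are the fraction of tumor
# cells carrying the clone's mutations (parent >= child everywhere).
scenario_script <- function(scenario, n_followups) {
  fu_ids <- function(site, n) paste0(site, "_t", seq_len(n))
  if (scenario == "null") {
    samp <- data.frame(
      sample_id = c("ICL_t0", "ICR_t0", fu_ids("ICL", n_followups)),
      site_class = c("iliac_crest_left", "iliac_crest_right",
                     rep("iliac_crest_left", n_followups)),
      timepoint = c(0, 0, seq_len(n_followups)),
      stringsAsFactors = FALSE)
    ccf <- matrix(1, 1, nrow(samp),
                  dimnames = list("R", samp$sample_id))
    return(list(samples = samp, ccf = ccf,
                parents = c(R = NA_character_),
                post_treatment = character(0),
                pattern = NA_character_, true_sweeps = 0L))
  }
  if (scenario == "single_cell_expansion") {
    stopifnot(n_followups >= 2)
    samp <- data.frame(
      sample_id = c("ICL_t0", "ICR_t0", fu_ids("ICL", n_followups)),
      site_class = c("iliac_crest_left", "iliac_crest_right",
                     rep("iliac_crest_left", n_followups)),
      timepoint = c(0, 0, seq_len(n_followups)),
      stringsAsFactors = FALSE)
    ccf <- rbind(
      R   = rep(1, nrow(samp)),
      B1  = c(0.10, 0.10, 0.90, rep(1.00, n_followups - 1)),
      B1a = c(0.00, 0.00, 0.00, rep(0.55, n_followups - 1)),
      B2  = c(0.65, 0.65, rep(0.00, n_followups)))
    colnames(ccf) <- samp$sample_id
    return(list(samples = samp, ccf = ccf,
                parents = c(R = NA, B1 = "R", B1a = "B1", B2 = "R"),
                post_treatment = c("B1", "B1a"),
                pattern = "single_cell_expansion", true_sweeps = 1L))
  }
  if (scenario == "coexisting") {
    stopifnot(n_followups >= 2)
    samp <- data.frame(
      sample_id = c("ICL_t0", "ICR_t0", fu_ids("ICL", n_followups)),
      site_class = c("iliac_crest_left", "iliac_crest_right",
                     rep("iliac_crest_left", n_followups)),
      timepoint = c(0, 0, seq_len(n_followups)),
      stringsAsFactors = FALSE)
    b1 <- c(0.30, 0.30, 0.60, rep(0.25, n_followups - 1))
    b2 <- c(0.10, 0.10, 0.30, rep(0.70, n_followups - 1))
    ccf <- rbind(R = rep(1, nrow(samp)), B1 = b1, B2 = b2)
    colnames(ccf) <- samp$sample_id
    return(list(samples = samp, ccf = ccf,
                parents = c(R = NA, B1 = "R", B2 = "R"),
                post_treatment = c("B1", "B2"),
                pattern = "coexisting_subclones", true_sweeps = 0L))
  }
  # alternating spatial dominance: follow-ups sampled at the iliac
  # crest and a focal lesion, each dominated by its own branch
  samp <- data.frame(
    sample_id = c("ICL_t0", "ICR_t0",
                  as.vector(rbind(fu_ids("ICL", n_followups),
                                  fu_ids("FL", n_followups)))),
    site_class = c("iliac_crest_left", "iliac_crest_right",
                   rep(c("iliac_crest_left", "focal_lesion"),
                       n_followups)),
    timepoint = c(0, 0, rep(seq_len(n_followups), each = 2)),
    stringsAsFactors = FALSE)
  nfu <- n_followups
  b1 <- c(0.15, 0.15, rep(c(0.90, 0.00), nfu))
  b2 <- c(0.10, 0.10, rep(c(0.00, 0.85), nfu))
  ccf <- rbind(R = rep(1, nrow(samp)), B1 = b1, B2 = b2)
  colnames(ccf) <- samp$sample_id
  list(samples = samp, ccf = ccf,
       parents = c(R = NA, B1 = "R", B2 = "R"),
       post_treatment = c("B1", "B2"),
       pattern = "alternating_spatial_dominance", true_sweeps = 1L)
}

#' Simulate one synthetic patient
#'
#' Generates a fully specified patient — planted clone phylogeny,
#' site/timepoint occupancy, purity, copy number, read counts and
#' trinucleotide contexts — together with its ground truth, in the
#' exact table dialects consumed by the readers. Deterministic given
#' \code{(config, seed)}.
#'
#' @param config A \code{sim_config}.
#' @param seed Integer seed.
#' @param patient_id Patient label.
#' @param scenario Override of \code{config$scenario} (used by
#'   [simulate_cohort()] for mixed cohorts).
#' @return List with \code{truth} (tree, per-variant branch, planted
#'   CCFs and exposures, pattern label, sweep count), \code{variants},
#'   \code{observations}, \code{samples}, \code{segments},
#'   \code{clinical}.
#' @export
simulate_patient <- function(config, seed, patient_id = "P1",
                             scenario = config$scenario) {
  if (scenario == "mixed")
    stop_mmclone("simulate_patient needs a concrete scenario; ",
                 "'mixed' applies to cohorts",
                 class = "mmclone_config_error")
  with_seed(seed, {
    sc <- scenario_script(scenario, config$n_followups)
    # feasibility: children may not sum above their parent anywhere
    for (cl in rownames(sc$ccf)) {
      ch <- names(sc$parents)[!is.na(sc$parents) & sc$parents == cl]
      if (length(ch)) {
        bad <- colSums(sc$ccf[ch, , drop = FALSE]) >
          sc$ccf[cl, ] + 1e-9
        if (any(bad))
          stop_mmclone("infeasible clone proportions in sample ",
                       sc$samples$sample_id[which(bad)[1]],
                       class = "mmclone_generation_error")
      }
    }
    samp <- sc$samples
    samp$patient_id <- patient_id
    samp$anatomical_label <- samp$site_class
    samp$purity <- runif(nrow(samp), config$purity_range[1],
                         config$purity_range[2])
    samp$sample_id <- paste0(patient_id, "_", samp$sample_id)
    colnames(sc$ccf) <- samp$sample_id
    samp <- samp[c("sample_id", "patient_id", "site_class",
                   "anatomical_label", "timepoint", "purity")]

    clones <- rownames(sc$ccf)
    n_mut <- setNames(integer(length(clones)), clones)
    n_mut["R"] <- config$trunk_mutations
    for (cl in setdiff(clones, "R"))
      n_mut[cl] <- sample(config$branch_mutations[1]:
                            config$branch_mutations[2], 1)

    # genome layout: chr1 trunk gain (cn 3), chr13 deletion (cn 1),
    # chr3..chr12 diploid; identical segments in every sample
    diploid <- as.character(3:12)
    seg1 <- data.frame(chrom = c("1", "13", diploid),
                       start = 1L, end = 240000000L,
                       total_cn = c(3L, 1L, rep(2L, length(diploid))),
                       minor_cn = c(1L, 0L, rep(1L, length(diploid))))
    segments <- do.call(rbind, lapply(samp$sample_id, function(s)
      cbind(sample = s, seg1)))
    segments$length_bp <- segments$end - segments$start + 1L

    # place mutations
    total <- sum(n_mut)
    branch <- rep(clones, n_mut)
    chrom <- sample(c("1", "13", diploid), total, replace = TRUE,
                    prob = c(0.10, 0.05, rep(0.85 / length(diploid),
                                             length(diploid))))
    pos <- sample.int(239000000L, total, replace = TRUE)
    cn <- ifelse(chrom == "1", 3L, ifelse(chrom == "13", 1L, 2L))
    # multiplicity: trunk mutations on the gained chromosome may sit on
    # either one or both gained copies
    mult <- rep(1L, total)
    on_gain_trunk <- chrom == "1" & branch == "R"
    mult[on_gain_trunk] <- sample(1:2, sum(on_gain_trunk),
                                  replace = TRUE)

    # trinucleotide contexts from the branch signature mixture
    K <- length(config$catalog$names)
    expo <- matrix(0, length(clones), K,
                   dimnames = list(clones, config$catalog$names))
    for (cl in clones) {
      e <- setNames(numeric(K), config$catalog$names)
      e[names(BG_EXPOSURES)] <- BG_EXPOSURES
      if (cl %in% sc$post_treatment) {
        e <- e * (1 - config$target_weight)
        e[config$target] <- config$target_weight
      }
      expo[cl, ] <- e
    }
    p96 <- config$catalog$profiles %*% t(expo)  # 96 x clones
    ctx <- integer(total)
    for (cl in clones) {
      i <- which(branch == cl)
      ctx[i] <- sample.int(96, length(i), replace = TRUE,
                           prob = p96[, cl]) - 1L
    }
    type <- sbs96_contexts()[ctx + 1L]
    ref <- sub(".*\\[([A-T])>.*", "\\1", type)
    alt <- sub(".*>([A-T])\\].*", "\\1", type)
    gene <- sprintf("G%04d", sample.int(5000, total, replace = TRUE))

    variants <- data.frame(
      variant_id = sprintf("%s_v%04d", patient_id, seq_len(total)),
      chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
      context96 = ctx, in_ig_locus = FALSE, stringsAsFactors = FALSE)

    # immunoglobulin-locus decoys (filtered out downstream)
    if (config$ig_variants > 0) {
      nig <- config$ig_variants
      igv <- data.frame(
        variant_id = sprintf("%s_ig%02d", patient_id, seq_len(nig)),
        chrom = "14", pos = 106032614L + seq_len(nig) * 1000L,
        ref = "C", alt = "T", gene = "IGH",
        context96 = 38L, in_ig_locus = TRUE, stringsAsFactors = FALSE)
      variants <- rbind(variants, igv)
      segments <- rbind(segments, do.call(rbind, lapply(
        samp$sample_id, function(s)
          data.frame(sample = s, chrom = "14", start = 1L,
                     end = 240000000L, total_cn = 2L, minor_cn = 1L,
                     length_bp = 240000000L))))
      branch <- c(branch, rep("R", nig))
      cn <- c(cn, rep(2L, nig))
      mult <- c(mult, rep(1L, nig))
    }

    # read counts: depth ~ NegBin(mean_depth), alt ~ Binom(depth, vaf)
    obs <- list()
    for (j in seq_len(nrow(samp))) {
      p <- samp$purity[j]
      phi <- sc$ccf[branch, j]
      vaf <- phi * mult * p / (p * cn + 2 * (1 - p))
      depth <- pmax(1L, rnbinom(nrow(variants),
                                size = config$depth_dispersion,
                                mu = config$mean_depth))
      altr <- rbinom(nrow(variants), depth, pmin(vaf, 1))
      obs[[j]] <- data.frame(variant_id = variants$variant_id,
                             sample_id = samp$sample_id[j],
                             alt_reads = altr, depth = depth,
                             qc_pass = TRUE, stringsAsFactors = FALSE)
    }
    observations <- do.call(rbind, obs)
    rownames(observations) <- NULL
    segments <- segments[order(segments$sample, segments$chrom,
                               segments$start), ]
    rownames(segments) <- NULL

    multi <- !is.na(sc$pattern) &&
      sc$pattern != "single_cell_expansion"
    clinical <- data.frame(
      patient_id = patient_id,
      pet_fl_count = if (!config$clinical_association)
        sample(0:10, 1) else if (multi) sample(3:10, 1) else
          sample(0:2, 1),
      best_response = if (!config$clinical_association)
        sample(RESPONSES, 1) else if (!is.na(sc$pattern) &&
          sc$pattern == "coexisting_subclones")
        sample(c("PR", "VGPR", "CR"), 1) else "CR",
      gep70_score = round(runif(1, -0.5, 1.5), 3),
      stringsAsFactors = FALSE)
    clinical$gep70_risk <- ifelse(clinical$gep70_score >= 0.66,
                                  "high", "low")

    truth <- list(
      scenario = scenario, parents = sc$parents,
      clone_ccf = sc$ccf, branch = setNames(branch,
                                            variants$variant_id),
      multiplicity = setNames(mult, variants$variant_id),
      exposures = expo, pattern = sc$pattern,
      true_sweeps = sc$true_sweeps,
      n_relapse_branches = if (is.na(sc$pattern)) 0L else
        if (sc$pattern == "single_cell_expansion") 1L else 2L)
    list(truth = truth, variants = variants,
         observations = observations, samples = samp,
         segments = segments, clinical = clinical)
  })
}

#' Simulate a cohort of synthetic patients
#'
#' Independent patients with per-patient seeds derived from the master
#' seed; in the \code{"mixed"} scenario the three evolutionary-pattern
#' scenarios are cycled across patients.
#'
#' @param config A \code{sim_config}.
#' @param seed Master seed.
#' @return List with \code{patients} (named list of
#'   [simulate_patient()] bundles) and \code{truth} (registry keyed by
#'   patient id).
#' @export
simulate_cohort <- function(config, seed = 1) {
  scenarios <- if (config$scenario == "mixed") {
    rep(c("single_cell_expansion", "coexisting", "alternating"),
        length.out = config$n_patients)
  } else rep(config$scenario, config$n_patients)
  patients <- list()
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", i)
    pseed <- (seed + 7919L * i) %% 2147483647L
    patients[[pid]] <- simulate_patient(config, pseed, pid,
                                        scenario = scenarios[i])
  }
  list(patients = patients,
       truth = lapply(patients, function(p) p$truth))
}

#' Write a simulated patient to disk in the reader dialects
#'
#' @param sim A bundle from [simulate_patient()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written file paths.
#' @export
write_patient_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pid <- sim$samples$patient_id[1]
  paths <- c(
    mutations = file.path(dir, paste0(pid, "_mutations.tsv")),
    segments = file.path(dir, paste0(pid, "_segments.tsv")),
    samples = file.path(dir, paste0(pid, "_samples.tsv")),
    clinical = file.path(dir, paste0(pid, "_clinical.tsv")))
  write_mutation_table(sim$variants, sim$observations,
                       paths["mutations"])
  write.table(sim$segments[c("sample", "chrom", "start", "end",
                             "total_cn", "minor_cn")],
              paths["segments"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$samples, paths["samples"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$clinical[c("patient_id", "pet_fl_count",
                             "best_response", "gep70_score")],
              paths["clinical"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}
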