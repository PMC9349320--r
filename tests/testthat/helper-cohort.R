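# the simulated-cohort recovery run is shared by several test files;
# computed once per session and cached
.cohort_cache <- new.env(parent = emptyenv())

cohort_recovery <- function(n_seeds = 50) {
  key <- paste0("recovery_", n_seeds)
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  cfg <- sim_config()
  out <- list()
  for (sc in c("single_cell_expansion", "coexisting", "alternating")) {
    evs <- vector("list", n_seeds)
    for (seed in seq_len(n_seeds)) {
      sim <- simulate_patient(cfg, seed = seed, patient_id = "P1",
                              scenario = sc)
      an <- analyze_patient(sim$variants, sim$observations,
                            sim$samples, sim$segments)
      evs[[seed]] <- evaluate_recovery(an, sim$truth)
    }
    out[[sc]] <- evs
  }
  .cohort_cache[[key]] <- out
  out
}
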