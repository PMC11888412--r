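# Shared fixtures: everything is generated in code, nothing is stored.

tiny_panel <- function(P = 30) founder_panel(chromosomes = c(`2` = P))

tiny_cfg <- function(seed = 11, ...) {
  sim_config(n_rils = 20, flies_per_vial = c(15, 40), n_replicates = 2,
             seed = seed, ...)
}

# a small complete study: haplotypes, fly outcomes, acuity, counts
tiny_study <- function(seed = 11, P = 30, effects = list(), ...) {
  cfg <- tiny_cfg(seed = seed, ...)
  haps <- simulate_ril_haplotypes(tiny_panel(P), cfg)
  sim <- simulate_fly_outcomes(haps, effects, cfg)
  acu <- simulate_acuity_and_preference(haps, cfg)
  list(cfg = cfg, haps = haps, sim = sim, acu = acu,
       counts = rbind(aggregate_fly_records(sim$flies), acu$counts))
}

# hand-built haplotype map from a hard founder-state matrix
# (RILs x positions, integer states 1..8), for exact design control
hap_map_from_states <- function(states, founders = paste0("A", 1:8),
                                chrom = "2") {
  R <- nrow(states); P <- ncol(states)
  prob <- array(0, dim = c(R, P, 8), dimnames = list(NULL, NULL, founders))
  prob[cbind(rep(seq_len(R), P), rep(seq_len(P), each = R),
             as.vector(states))] <- 1
  structure(list(founders = founders,
                 ril_ids = sprintf("RIL_%03d", seq_len(R)),
                 positions = data.frame(chrom = chrom, index = seq_len(P),
                                        map_pos = seq_len(P) - 1,
                                        stringsAsFactors = FALSE),
                 prob = prob),
            class = "ril_hap_map")
}

# minimal learning-counts table for given per-RIL successes/trials
counts_from_scores <- function(ril_ids, successes, trials,
                               odor = "OCT", assay = "learning") {
  chamber_counts(ril_ids, paste0(ril_ids, "_", odor, "_R1"), odor, assay,
                 n_plus = successes, n_minus = trials - successes,
                 n_nc = 0)
}
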