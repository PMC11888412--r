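# Synthetic DSPR-like study generator.
#
# Emulates the data a group-tested olfactory conditioning study produces:
# an 8-founder RIL haplotype-probability map (the output format of the
# DSPR ancestry HMM, which is consumed, not re-implemented) and fly-level
# two-decision outcomes with RIL and vial random effects on the logit
# scale, with optional planted founder effects as ground truth.

#' Describe an 8-founder mapping panel
#'
#' @param founder_ids Exactly 8 founder labels (default `A1`..`A8`, the
#'   DSPR population-A naming).
#' @param chromosomes Named integer vector: positions per chromosome.
#' @param position_spacing Map-distance units between adjacent positions
#'   (cM-like; only recorded, recombination is governed per interval by
#'   the simulation config).
#' @return An object of class `founder_panel`.
#' @export
founder_panel <- function(founder_ids = paste0("A", 1:8),
                          chromosomes = c(X = 60, `2` = 110, `3` = 110),
                          position_spacing = 1) {
  if (length(founder_ids) != 8 || anyDuplicated(founder_ids))
    stop("a founder panel has exactly 8 distinct founders")
  if (is.null(names(chromosomes)) || any(chromosomes < 1))
    stop("chromosomes must be a named vector of positive position counts")
  structure(list(founder_ids = as.character(founder_ids),
                 chromosomes = chromosomes,
                 position_spacing = position_spacing),
            class = "founder_panel")
}

#' Simulation study configuration
#'
#' Defaults emulate the scale of a 50-line group-tested study: three
#' replicate vials per line and trained odor with 20-100 flies each gives
#' per-line starting samples of roughly 60-600 flies, and random-intercept
#' SDs of 0.3 (RIL) and 0.2 (vial) on the logit scale give line-level
#' performance spreads of about 0.4-0.65 around a neutral baseline.
#'
#' @param n_rils Number of recombinant inbred lines.
#' @param flies_per_vial Integer range `c(min, max)`; vial sizes are drawn
#'   uniformly over it.
#' @param n_replicates Replicate vials per RIL per trained odor.
#' @param sd_ril Logit-scale SD of RIL random intercepts.
#' @param sd_replicate Logit-scale SD of vial (replicate) intercepts.
#' @param baseline_correct_logit Grand intercept of the correctness
#'   decision (0 = unbiased choice).
#' @param baseline_climb_logit Grand intercept of the climbing decision.
#' @param recomb_prob Per-interval founder-switch probability of the
#'   mosaic Markov chain, in `[0, 1]`. The 0.05 default gives a
#'   ~100-position chromosome about five ancestry breakpoints per line,
#'   the order observed in multiparent RIL panels.
#' @param soft_prob_noise Dirichlet concentration used to soften hard
#'   founder calls; 0 (default) keeps hard 0/1 probabilities. Positive
#'   values draw each row from Dirichlet(1 + c * onehot), so larger c
#'   means more certain calls.
#' @param seed Integer seed; every stochastic draw flows from it
#'   (haplotypes use `seed`, fly outcomes `seed + 1`, acuity and
#'   preference tables `seed + 2`).
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_rils = 50, flies_per_vial = c(20, 100),
                       n_replicates = 3, sd_ril = 0.3, sd_replicate = 0.2,
                       baseline_correct_logit = 0,
                       baseline_climb_logit = 0,
                       recomb_prob = 0.05, soft_prob_noise = 0,
                       seed = 1) {
  if (n_rils < 1) stop("n_rils must be at least 1")
  if (length(flies_per_vial) != 2 || flies_per_vial[1] < 1 ||
      flies_per_vial[2] < flies_per_vial[1])
    stop("flies_per_vial must be c(min, max) with min >= 1")
  if (sd_ril < 0 || sd_replicate < 0) stop("random-effect SDs must be >= 0")
  if (recomb_prob < 0 || recomb_prob > 1)
    stop("recomb_prob must lie in [0, 1]")
  if (soft_prob_noise < 0) stop("soft_prob_noise must be >= 0")
  structure(list(n_rils = as.integer(n_rils),
                 flies_per_vial = as.integer(flies_per_vial),
                 n_replicates = as.integer(n_replicates),
                 sd_ril = sd_ril, sd_replicate = sd_replicate,
                 baseline_correct_logit = baseline_correct_logit,
                 baseline_climb_logit = baseline_climb_logit,
                 recomb_prob = recomb_prob,
                 soft_prob_noise = soft_prob_noise,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

#' Specify a planted founder-haplotype effect
#'
#' @param chromosome Chromosome name.
#' @param position_index Position index within the chromosome (1-based).
#' @param effects Named numeric vector of logit-scale additive effects;
#'   founders not named get 0.
#' @param odor_scope Apply to both trained-odor groups or only one
#'   (`"both"`, `"OCT_only"`, `"MCH_only"`).
#' @param phenotype_scope Outcome the effect acts on: correctness in the
#'   `"learning"` or `"memory"` assay, or the `"climbing"` decision.
#' @param founder_ids Full founder label set used for validation.
#' @return An object of class `qtl_effect`.
#' @export
qtl_effect <- function(chromosome, position_index, effects,
                       odor_scope = c("both", "OCT_only", "MCH_only"),
                       phenotype_scope = c("learning", "memory", "climbing"),
                       founder_ids = paste0("A", 1:8)) {
  odor_scope <- match.arg(odor_scope)
  phenotype_scope <- match.arg(phenotype_scope)
  if (is.null(names(effects)) || any(!nzchar(names(effects))))
    stop("effects must be a named vector of founder effects")
  unknown <- setdiff(names(effects), founder_ids)
  if (length(unknown))
    stop("unknown founder labels in effects: ",
         paste(unknown, collapse = ", "))
  full <- stats::setNames(numeric(length(founder_ids)), founder_ids)
  full[names(effects)] <- effects
  structure(list(chromosome = as.character(chromosome),
                 position_index = as.integer(position_index),
                 effects = full, odor_scope = odor_scope,
                 phenotype_scope = phenotype_scope),
            class = "qtl_effect")
}

#' Simulate a RIL haplotype-probability map
#'
#' Generates each RIL's genome as a first-order symmetric Markov founder
#' mosaic: the founder at the first position of a chromosome is uniform
#' over the 8 founders, and at each interval the founder switches with
#' probability `recomb_prob` to one of the other 7, uniformly. With
#' `soft_prob_noise = 0` the returned probabilities are hard one-hot rows;
#' otherwise each row is drawn from Dirichlet(1 + c * onehot), emulating
#' the near-certain but soft probabilities an ancestry HMM reports.
#'
#' RNG stream (from `config$seed`): per chromosome, first-position states,
#' then interval switches, then switch targets, then softening draws.
#'
#' @param panel A [founder_panel()].
#' @param config A [sim_config()].
#' @return An object of class `ril_hap_map`: list with `founders`,
#'   `ril_ids`, `positions` (data.frame `chrom`, `index`, `map_pos`), and
#'   `prob`, an `n_rils x n_positions x 8` array whose rows sum to 1.
#' @export
simulate_ril_haplotypes <- function(panel, config) {
  stopifnot(inherits(panel, "founder_panel"), inherits(config, "sim_config"))
  set.seed(.derive_seed(config$seed, 0))
  R <- config$n_rils
  founders <- panel$founder_ids
  pos_list <- list()
  state_cols <- list()
  for (ci in seq_along(panel$chromosomes)) {
    chrom <- names(panel$chromosomes)[ci]
    P <- panel$chromosomes[[ci]]
    states <- matrix(0L, R, P)
    states[, 1] <- sample.int(8L, R, replace = TRUE)
    if (P > 1) {
      for (p in 2:P) {
        s <- states[, p - 1]
        sw <- stats::runif(R) < config$recomb_prob
        ns <- s
        if (any(sw)) {
          alt <- sample.int(7L, sum(sw), replace = TRUE)
          cur <- s[sw]
          ns[sw] <- ifelse(alt >= cur, alt + 1L, alt)
        }
        states[, p] <- ns
      }
    }
    state_cols[[ci]] <- states
    pos_list[[ci]] <- data.frame(chrom = chrom, index = seq_len(P),
                                 map_pos = (seq_len(P) - 1) *
                                   panel$position_spacing,
                                 stringsAsFactors = FALSE)
  }
  states <- do.call(cbind, state_cols)
  positions <- do.call(rbind, pos_list)
  Ptot <- nrow(positions)
  prob <- array(0, dim = c(R, Ptot, 8),
                dimnames = list(NULL, NULL, founders))
  idx <- cbind(rep(seq_len(R), Ptot), rep(seq_len(Ptot), each = R),
               as.vector(states))
  prob[idx] <- 1
  if (config$soft_prob_noise > 0) {
    c0 <- config$soft_prob_noise
    alpha <- 1 + c0 * prob
    g <- array(stats::rgamma(length(alpha), shape = alpha), dim = dim(alpha))
    tot <- apply(g, c(1, 2), sum)
    prob <- g / array(tot, dim = dim(g))
  }
  structure(list(founders = founders,
                 ril_ids = sprintf("RIL_%03d", seq_len(R)),
                 positions = positions, prob = prob),
            class = "ril_hap_map")
}

#' @export
print.ril_hap_map <- function(x, ...) {
  cat("RIL haplotype map:", length(x$ril_ids), "RILs,",
      nrow(x$positions), "positions,",
      length(unique(x$positions$chrom)), "chromosome(s),",
      length(x$founders), "founders\n")
  invisible(x)
}

#' Extract the founder-probability matrix at one position
#'
#' @param haps A `ril_hap_map`.
#' @param chromosome Chromosome name.
#' @param index Position index within the chromosome.
#' @return An `n_rils x 8` matrix (rows named by RIL, columns by founder).
#' @export
hap_at <- function(haps, chromosome, index) {
  stopifnot(inherits(haps, "ril_hap_map"))
  j <- which(haps$positions$chrom == as.character(chromosome) &
             haps$positions$index == index)
  if (length(j) != 1)
    stop("position ", chromosome, ":", index, " not in haplotype map")
  g <- haps$prob[, j, , drop = TRUE]
  g <- matrix(g, nrow = length(haps$ril_ids), ncol = 8,
              dimnames = list(haps$ril_ids, haps$founders))
  g
}

#' Simulate fly-level two-decision outcomes
#'
#' Each fly first decides whether to climb
#' (`Bernoulli(plogis(baseline_climb + a_RIL + b_vial))`) and, if it
#' climbed, whether to choose the CS+ arm
#' (`Bernoulli(plogis(baseline_correct + a'_RIL + b'_vial + sum_j g_ij *
#' effect_j))`), where `g_ij` is the RIL's founder probability at each
#' planted effect's position and the effect contributes only within its
#' odor and phenotype scope. Flies choosing CS+ in the learning assay are
#' re-tested for memory in a fresh maze run (new vial intercepts, same
#' replicate label). RIL intercepts are drawn once per RIL, vial
#' intercepts once per maze run.
#'
#' RNG stream (from `config$seed + 1`): RIL intercepts (climb then
#' correct), then per-vial intercepts, vial sizes, and fly draws in
#' RIL-within-odor-within-replicate order, learning before memory.
#'
#' @param haps A `ril_hap_map`.
#' @param effects List of [qtl_effect()] objects (may be empty).
#' @param config A [sim_config()].
#' @return A list of class `fly_sim`: `flies` (per-fly records with
#'   `ril_id`, `replicate_id`, `trained_odor`, `assay`, `climbed`,
#'   `correct`), `truth` (RIL intercepts and the planted-effect table).
#' @export
simulate_fly_outcomes <- function(haps, effects = list(), config) {
  stopifnot(inherits(haps, "ril_hap_map"), inherits(config, "sim_config"))
  if (inherits(effects, "qtl_effect")) effects <- list(effects)
  for (e in effects) {
    stopifnot(inherits(e, "qtl_effect"))
    if (!all(names(e$effects) == haps$founders))
      stop("effect founder labels do not match the haplotype map")
    hap_at(haps, e$chromosome, e$position_index)  # errors if absent
  }
  set.seed(.derive_seed(config$seed, 1))
  R <- length(haps$ril_ids)
  a_climb <- stats::rnorm(R, 0, config$sd_ril)
  a_corr <- stats::rnorm(R, 0, config$sd_ril)

  # per-RIL planted contribution, by odor and phenotype scope
  contrib <- function(scope_phen, odor) {
    out <- numeric(R)
    for (e in effects) {
      if (e$phenotype_scope != scope_phen) next
      if (e$odor_scope == "OCT_only" && odor != "OCT") next
      if (e$odor_scope == "MCH_only" && odor != "MCH") next
      g <- hap_at(haps, e$chromosome, e$position_index)
      out <- out + as.numeric(g %*% e$effects)
    }
    out
  }

  rows <- vector("list", R * 2L * config$n_replicates)
  k <- 0L
  for (i in seq_len(R)) {
    for (odor in c("OCT", "MCH")) {
      eff_learn <- contrib("learning", odor)[i]
      eff_mem <- contrib("memory", odor)[i]
      eff_climb <- contrib("climbing", odor)[i]
      for (r in seq_len(config$n_replicates)) {
        rep_id <- sprintf("%s_%s_R%d", haps$ril_ids[i], odor, r)
        b_climb <- stats::rnorm(1, 0, config$sd_replicate)
        b_corr <- stats::rnorm(1, 0, config$sd_replicate)
        n <- sample(seq(config$flies_per_vial[1], config$flies_per_vial[2]),
                    1L)
        p_climb <- stats::plogis(config$baseline_climb_logit +
                                 a_climb[i] + b_climb + eff_climb)
        climbed <- stats::rbinom(n, 1L, p_climb)
        correct <- rep(NA_integer_, n)
        nc <- sum(climbed)
        if (nc > 0) {
          p_corr <- stats::plogis(config$baseline_correct_logit +
                                  a_corr[i] + b_corr + eff_learn)
          correct[climbed == 1L] <- stats::rbinom(nc, 1L, p_corr)
        }
        learn <- data.frame(ril_id = haps$ril_ids[i], replicate_id = rep_id,
                            trained_odor = odor, assay = "learning",
                            climbed = climbed, correct = correct,
                            stringsAsFactors = FALSE)
        # memory: CS+ choosers re-run in a fresh maze
        n_mem <- sum(!is.na(correct) & correct == 1L)
        mem <- NULL
        if (n_mem > 0) {
          b2_climb <- stats::rnorm(1, 0, config$sd_replicate)
          b2_corr <- stats::rnorm(1, 0, config$sd_replicate)
          p2_climb <- stats::plogis(config$baseline_climb_logit +
                                    a_climb[i] + b2_climb + eff_climb)
          climbed2 <- stats::rbinom(n_mem, 1L, p2_climb)
          correct2 <- rep(NA_integer_, n_mem)
          nc2 <- sum(climbed2)
          if (nc2 > 0) {
            p2_corr <- stats::plogis(config$baseline_correct_logit +
                                     a_corr[i] + b2_corr + eff_mem)
            correct2[climbed2 == 1L] <- stats::rbinom(nc2, 1L, p2_corr)
          }
          mem <- data.frame(ril_id = haps$ril_ids[i], replicate_id = rep_id,
                            trained_odor = odor, assay = "memory",
                            climbed = climbed2, correct = correct2,
                            stringsAsFactors = FALSE)
        }
        k <- k + 1L
        rows[[k]] <- if (is.null(mem)) learn else rbind(learn, mem)
      }
    }
  }
  flies <- do.call(rbind, rows[seq_len(k)])
  rownames(flies) <- NULL
  eff_tab <- if (length(effects)) {
    do.call(rbind, lapply(effects, function(e)
      data.frame(chrom = e$chromosome, index = e$position_index,
                 founder = names(e$effects), effect = unname(e$effects),
                 odor_scope = e$odor_scope,
                 phenotype_scope = e$phenotype_scope,
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(chrom = character(), index = integer(), founder = character(),
               effect = numeric(), odor_scope = character(),
               phenotype_scope = character(), stringsAsFactors = FALSE)
  }
  structure(list(flies = flies,
                 truth = list(
                   ril_intercepts = data.frame(
                     ril_id = haps$ril_ids, climb = a_climb,
                     correct = a_corr, stringsAsFactors = FALSE),
                   effects = eff_tab)),
            class = "fly_sim")
}

#' @export
print.fly_sim <- function(x, ...) {
  n_qtl <- length(unique(paste(x$truth$effects$chrom,
                               x$truth$effects$index)))
  cat("Simulated fly outcomes:", nrow(x$flies), "fly records,",
      length(unique(x$flies$ril_id)), "RILs,",
      n_qtl, "planted QTL position(s)\n")
  invisible(x)
}

#' Simulate untrained preference and acuity count tables
#'
#' Per-RIL latent proportions are drawn from Beta distributions and
#' observed through binomial vial counts: baseline OCT-vs-MCH preference
#' (`pref_beta`, default Beta(15, 15): most lines near neutral with a
#' realistic 0.2-0.8 spread), odor-vs-blank acuity per odorant
#' (`odor_beta`, default Beta(5, 5)), and sucrose split-plate acuity
#' (`sugar_beta`, default Beta(10, 7), mean ~0.59) with a censored count
#' drawn at rate `censor_prob`. Climbing at these assays uses the config's
#' climbing baseline without RIL effects.
#'
#' RNG stream (from `config$seed + 2`): latent proportions (preference,
#' OCT acuity, MCH acuity, sucrose), then count draws per assay in RIL-
#' within-replicate order.
#'
#' @param haps A `ril_hap_map` (supplies the RIL identifiers).
#' @param config A [sim_config()].
#' @param pref_beta,odor_beta,sugar_beta Beta shape pairs for the latent
#'   proportions.
#' @param censor_prob Per-fly censoring probability on the split plate.
#' @return List of class `acuity_sim`: `counts` (chamber-counts rows for
#'   `baseline`, `odor_acuity`, `sugar_acuity`) and `latent` (per-RIL
#'   latent proportions).
#' @export
simulate_acuity_and_preference <- function(haps, config,
                                           pref_beta = c(15, 15),
                                           odor_beta = c(5, 5),
                                           sugar_beta = c(10, 7),
                                           censor_prob = 0.1) {
  stopifnot(inherits(haps, "ril_hap_map"), inherits(config, "sim_config"))
  if (censor_prob < 0 || censor_prob > 1)
    stop("censor_prob must lie in [0, 1]")
  set.seed(.derive_seed(config$seed, 2))
  R <- length(haps$ril_ids)
  lat <- data.frame(
    ril_id = haps$ril_ids,
    pref_oct = stats::rbeta(R, pref_beta[1], pref_beta[2]),
    acuity_oct = stats::rbeta(R, odor_beta[1], odor_beta[2]),
    acuity_mch = stats::rbeta(R, odor_beta[1], odor_beta[2]),
    acuity_sugar = stats::rbeta(R, sugar_beta[1], sugar_beta[2]),
    stringsAsFactors = FALSE)
  p_climb <- stats::plogis(config$baseline_climb_logit)
  vial_n <- function() sample(seq(config$flies_per_vial[1],
                                  config$flies_per_vial[2]), 1L)
  rows <- list()
  for (i in seq_len(R)) {
    for (r in seq_len(config$n_replicates)) {
      n <- vial_n()
      climbers <- stats::rbinom(1, n, p_climb)
      oct <- stats::rbinom(1, climbers, lat$pref_oct[i])
      rows[[length(rows) + 1L]] <- chamber_counts(
        lat$ril_id[i], sprintf("%s_base_R%d", lat$ril_id[i], r), "none",
        "baseline", oct, climbers - oct, n - climbers)
      for (od in c("OCT", "MCH")) {
        n2 <- vial_n()
        climbers2 <- stats::rbinom(1, n2, p_climb)
        acu <- if (od == "OCT") lat$acuity_oct[i] else lat$acuity_mch[i]
        hit <- stats::rbinom(1, climbers2, acu)
        rows[[length(rows) + 1L]] <- chamber_counts(
          lat$ril_id[i], sprintf("%s_%s_acu_R%d", lat$ril_id[i], od, r), od,
          "odor_acuity", hit, climbers2 - hit, n2 - climbers2)
      }
      n3 <- vial_n()
      cen <- stats::rbinom(1, n3, censor_prob)
      suc <- stats::rbinom(1, n3 - cen, lat$acuity_sugar[i])
      rows[[length(rows) + 1L]] <- chamber_counts(
        lat$ril_id[i], sprintf("%s_sug_R%d", lat$ril_id[i], r), "none",
        "sugar_acuity", suc, n3 - cen - suc, 0, cen)
    }
  }
  structure(list(counts = do.call(rbind, rows), latent = lat),
            class = "acuity_sim")
}
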