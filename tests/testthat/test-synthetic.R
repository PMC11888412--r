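test_that("haplotype rows are normalized probability vectors", {
  cfg <- tiny_cfg(seed = 21, soft_prob_noise = 50)
  haps <- simulate_ril_haplotypes(tiny_panel(25), cfg)
  sums <- apply(haps$prob, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
  expect_gte(min(haps$prob), 0)
  expect_lte(max(haps$prob), 1)
})

test_that("zero recombination fixes each RIL on one founder per
           chromosome with hard probability 1", {
  cfg <- tiny_cfg(seed = 22, recomb_prob = 0)
  panel <- founder_panel(chromosomes = c(X = 10, `2` = 15))
  haps <- simulate_ril_haplotypes(panel, cfg)
  for (chrom in c("X", "2")) {
    idx <- which(haps$positions$chrom == chrom)
    for (i in seq_len(cfg$n_rils)) {
      rows <- haps$prob[i, idx, ]
      expect_true(all(rows %in% c(0, 1)))
      founder <- apply(rows, 1, which.max)
      expect_length(unique(founder), 1)
    }
  }
})

test_that("founder frequencies match the symmetric chain's uniform
           stationary distribution at large n", {
  cfg <- sim_config(n_rils = 4000, recomb_prob = 0.01, seed = 23)
  haps <- simulate_ril_haplotypes(founder_panel(chromosomes = c(`2` = 30)),
                                  cfg)
  se <- sqrt((1 / 8) * (7 / 8) / 4000)
  # position 1 is an iid uniform draw: strict 3 SE per founder
  expect_true(all(abs(colMeans(haps$prob[, 1, ]) - 1 / 8) < 3 * se))
  # downstream positions are serially correlated with position 1, so the
  # 16 additional per-founder checks get a multiplicity allowance
  for (j in c(15, 30)) {
    freq <- colMeans(haps$prob[, j, ])
    expect_true(all(abs(freq - 1 / 8) < 4 * se))
    expect_lt(mean(abs(freq - 1 / 8)), 2 * se)
  }
})

test_that("simulate_ril_haplotypes validates its configuration", {
  expect_error(sim_config(n_rils = 0), "n_rils")
  expect_error(sim_config(soft_prob_noise = -1), ">= 0")
  expect_error(sim_config(flies_per_vial = c(0, 10)), "min >= 1")
  expect_error(sim_config(recomb_prob = 1.5), "\\[0, 1\\]")
})

test_that("null outcomes are symmetric: pooled correctness near 0.5", {
  cfg <- sim_config(n_rils = 50, flies_per_vial = c(90, 110),
                    n_replicates = 20, sd_ril = 0, sd_replicate = 0,
                    baseline_correct_logit = 0, recomb_prob = 0.5,
                    seed = 24)
  haps <- simulate_ril_haplotypes(founder_panel(chromosomes = c(`2` = 2)),
                                  cfg)
  sim <- simulate_fly_outcomes(haps, list(), cfg)
  learn <- sim$flies[sim$flies$assay == "learning" & sim$flies$climbed == 1, ]
  expect_gt(nrow(learn), 1e5)
  phat <- mean(learn$correct)
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / nrow(learn)))
})

test_that("a planted +2 logit effect shifts carrier lines by the
           closed-form Bernoulli difference", {
  cfg <- sim_config(n_rils = 40, flies_per_vial = c(190, 210),
                    n_replicates = 6, sd_ril = 0, sd_replicate = 0,
                    recomb_prob = 0, seed = 25)
  haps <- simulate_ril_haplotypes(founder_panel(chromosomes = c(`2` = 3)),
                                  cfg)
  eff <- qtl_effect("2", 2, c(A1 = 2), odor_scope = "both",
                    phenotype_scope = "learning")
  sim <- simulate_fly_outcomes(haps, eff, cfg)
  g <- hap_at(haps, "2", 2)
  carriers <- haps$ril_ids[g[, "A1"] == 1]
  learn <- sim$flies[sim$flies$assay == "learning" &
                     sim$flies$climbed == 1, ]
  p_car <- mean(learn$correct[learn$ril_id %in% carriers])
  p_oth <- mean(learn$correct[!learn$ril_id %in% carriers])
  expected <- plogis(2) - plogis(0)
  n_car <- sum(learn$ril_id %in% carriers)
  n_oth <- sum(!learn$ril_id %in% carriers)
  mc_se <- sqrt(0.25 / n_car + 0.25 / n_oth)
  expect_lt(abs((p_car - p_oth) - expected), 3 * mc_se)
})

test_that("effects with unknown founders or absent positions are
           rejected", {
  st <- tiny_study(seed = 26, P = 10)
  bad <- qtl_effect("2", 3, c(Z9 = 1), founder_ids = c(paste0("A", 1:7),
                                                       "Z9"))
  expect_error(simulate_fly_outcomes(st$haps, bad, st$cfg), "match")
  off <- qtl_effect("2", 99, c(A1 = 1))
  expect_error(simulate_fly_outcomes(st$haps, off, st$cfg), "not in")
})

test_that("the same seed reproduces every table byte-identically", {
  a <- tiny_study(seed = 27)
  b <- tiny_study(seed = 27)
  expect_identical(a$haps, b$haps)
  expect_identical(a$sim$flies, b$sim$flies)
  expect_identical(a$acu$counts, b$acu$counts)
  c_ <- tiny_study(seed = 28)
  expect_false(identical(a$sim$flies, c_$sim$flies))
})

test_that("acuity tables keep the censored column and near-fixed latent
           preference concentrates scores near 0.5", {
  cfg <- sim_config(n_rils = 12, flies_per_vial = c(180, 220),
                    n_replicates = 4, seed = 29)
  haps <- simulate_ril_haplotypes(founder_panel(chromosomes = c(`2` = 2)),
                                  cfg)
  acu <- simulate_acuity_and_preference(haps, cfg,
                                        pref_beta = c(1e6, 1e6),
                                        censor_prob = 0)
  expect_true("n_censored" %in% names(acu$counts))
  sug <- acu$counts[acu$counts$assay == "sugar_acuity", ]
  expect_true(all(sug$n_censored == 0))
  base <- acu$counts[acu$counts$assay == "baseline", ]
  sc <- score_rils(rbind(
    base,
    chamber_counts(unique(base$ril_id), "x", "OCT", "learning", 5, 5, 0)))
  pref <- sc$preference_score[sc$trained_odor == "OCT"]
  expect_true(all(abs(pref - 0.5) < 0.07))
})

test_that("latent Beta preferences propagate to scored preferences
           within binomial noise", {
  cfg <- sim_config(n_rils = 30, flies_per_vial = c(150, 250),
                    n_replicates = 4, seed = 30)
  haps <- simulate_ril_haplotypes(founder_panel(chromosomes = c(`2` = 2)),
                                  cfg)
  acu <- simulate_acuity_and_preference(haps, cfg)
  base <- acu$counts[acu$counts$assay == "baseline", ]
  pooled <- aggregate(cbind(n_plus, n_minus) ~ ril_id, base, sum)
  scored <- pooled$n_plus / (pooled$n_plus + pooled$n_minus)
  lat <- acu$latent$pref_oct[match(pooled$ril_id, acu$latent$ril_id)]
  n_eff <- pooled$n_plus + pooled$n_minus
  expect_true(all(abs(scored - lat) < 4 * sqrt(0.25 / n_eff) + 0.02))
  expect_gt(cor(scored, lat), 0.9)
})
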