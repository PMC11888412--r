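# The founder drop rule, the nested-GLMM likelihood-ratio machinery,
# Storey q-values, and differential-peak selection.

test_that("the 4-line drop rule excludes founders at exactly 3 carriers
           and keeps them at 4", {
  # founder A1: 3 carriers; A2: 4 carriers; rest spread over A3/A4
  states <- matrix(c(rep(1L, 3), rep(2L, 4), rep(3L, 5), rep(4L, 8)), 20, 2)
  haps <- hap_map_from_states(states)
  des <- build_design(haps, "2", 1)
  expect_false("A1" %in% des$included_founders)
  expect_true("A2" %in% des$included_founders)
  expect_equal(des$n_hap, 3)
  expect_equal(unname(des$harbor_counts["A1"]), 3)

  # all 8 founders carried by >= 4 lines
  states8 <- matrix(rep(1:8, each = 4), 32, 1)
  des8 <- build_design(hap_map_from_states(states8), "2", 1)
  expect_equal(des8$n_hap, 8)
  expect_error(build_design(haps, "2", 99), "not in")
})

test_that("with no estimable haplotype term the nested models coincide:
           statistic 0, p = 1", {
  states <- matrix(rep(1:4, each = 5), 20, 1)
  haps <- hap_map_from_states(states)
  des <- build_design(haps, "2", 1, min_ril_count = 21)  # drops everything
  expect_equal(des$n_hap, 0)
  set.seed(41)
  counts <- counts_from_scores(haps$ril_ids, rbinom(20, 30, 0.5), 30)
  fit <- fit_position(des, binomial_data(counts, "OCT_learning"))
  expect_equal(fit$result$lrt_stat, 0)
  expect_equal(fit$result$p, 1)
  expect_equal(fit$result$neg_log10_p, 0)

  # a single complete founder is also unidentifiable beyond the intercept
  des1 <- build_design(hap_map_from_states(matrix(1L, 20, 1)), "2", 1)
  fit1 <- fit_position(des1, binomial_data(counts, "OCT_learning"))
  expect_equal(fit1$result$df, 0)
  expect_equal(fit1$result$p, 1)
})

test_that("aggregated binomial and expanded per-fly Bernoulli data give
           the same likelihood-ratio statistic", {
  st <- tiny_study(seed = 42, P = 6)
  d_agg <- binomial_data(st$counts, "OCT_learning")
  d_fly <- d_agg[rep(seq_len(nrow(d_agg)), d_agg$trials), ]
  d_fly$trials <- 1L
  ones <- unlist(lapply(seq_len(nrow(d_agg)), function(i)
    c(rep(1L, d_agg$successes[i]),
      rep(0L, d_agg$trials[i] - d_agg$successes[i]))))
  d_fly$successes <- ones
  des <- build_design(st$haps, "2", 3, min_ril_count = 2)
  f_agg <- fit_position(des, d_agg)
  f_fly <- fit_position(des, d_fly)
  expect_equal(f_agg$result$lrt_stat, f_fly$result$lrt_stat,
               tolerance = 1e-6)
  expect_equal(f_agg$result$df, f_fly$result$df)
})

test_that("the likelihood ratio agrees with an independent GLMM
           implementation", {
  st <- tiny_study(seed = 43, P = 5)
  d <- binomial_data(st$counts, "MCH_learning")
  d$ril_id <- factor(d$ril_id); d$replicate_id <- factor(d$replicate_id)
  des <- build_design(st$haps, "2", 2, min_ril_count = 2)
  ours <- fit_position(des, d)

  est <- setdiff(des$included_founders, des$reference)
  if (max(abs(rowSums(des$g) - 1)) >= 0.01) est <- des$included_founders
  for (f in est)
    d[[paste0("g_", f)]] <- des$g[as.character(d$ril_id), f]
  fml <- stats::as.formula(paste(
    "cbind(successes, trials - successes) ~",
    paste(paste0("g_", est), collapse = "+"),
    "+ (1 | ril_id) + (1 | replicate_id)"))
  t0 <- glmmTMB::glmmTMB(
    cbind(successes, trials - successes) ~ 1 + (1 | ril_id) +
      (1 | replicate_id), data = d, family = stats::binomial())
  t1 <- glmmTMB::glmmTMB(fml, data = d, family = stats::binomial())
  lrt_tmb <- max(0, 2 * (as.numeric(stats::logLik(t1)) -
                         as.numeric(stats::logLik(t0))))
  expect_equal(ours$result$lrt_stat, lrt_tmb, tolerance = 1e-3)
})

test_that("alternative log-likelihood dominates the base at every
           converged position and the scan is deterministic and
           row-order invariant", {
  st <- tiny_study(seed = 44, P = 12)
  sc1 <- genome_scan(st$haps, st$counts, "OCT_learning",
                     with_qvalues = FALSE)
  expect_true(all(sc1$lrt_stat >= 0, na.rm = TRUE))
  expect_true(all(sc1$converged))
  sc2 <- genome_scan(st$haps, st$counts, "OCT_learning",
                     with_qvalues = FALSE)
  expect_identical(as.data.frame(sc1), as.data.frame(sc2))
  shuffled <- st$counts[sample(nrow(st$counts)), ]
  sc3 <- genome_scan(st$haps, shuffled, "OCT_learning",
                     with_qvalues = FALSE)
  expect_equal(sc3$lrt_stat, sc1$lrt_stat, tolerance = 1e-6)
})

test_that("a strong planted effect is recovered at the planted position
           and destroyed by permuting line labels", {
  cfg <- sim_config(n_rils = 30, flies_per_vial = c(60, 80),
                    n_replicates = 2, sd_ril = 0.2, sd_replicate = 0.1,
                    recomb_prob = 0.3, seed = 45)
  haps <- simulate_ril_haplotypes(founder_panel(chromosomes = c(`2` = 15)),
                                  cfg)
  eff <- qtl_effect("2", 8, c(A1 = 3), phenotype_scope = "learning")
  sim <- simulate_fly_outcomes(haps, eff, cfg)
  counts <- aggregate_fly_records(sim$flies)
  sc <- genome_scan(haps, counts, "OCT_learning", with_qvalues = FALSE)
  expect_equal(sc$index[which.max(sc$neg_log10_p)], 8)

  # permute RIL identities in the phenotype: the signal must collapse
  perm <- counts
  map <- setNames(sample(unique(counts$ril_id)), unique(counts$ril_id))
  perm$ril_id <- unname(map[perm$ril_id])
  scp <- genome_scan(haps, perm, "OCT_learning", with_qvalues = FALSE)
  expect_lt(max(scp$neg_log10_p, na.rm = TRUE),
            max(sc$neg_log10_p, na.rm = TRUE))
})

test_that("null scan p-values are not grossly miscalibrated", {
  # marginal sanity check over independent small null datasets; at 40
  # RIL clusters the chi-square LRT tail is known to be mildly
  # anti-conservative (the methods vignette quantifies this), so this
  # guards against gross breakage only, not exact calibration
  ps <- c()
  for (r in 1:4) {
    cfg <- sim_config(n_rils = 40, flies_per_vial = c(40, 60),
                      n_replicates = 2, recomb_prob = 0.5, seed = 460 + r)
    haps <- simulate_ril_haplotypes(
      founder_panel(chromosomes = c(`2` = 15)), cfg)
    sim <- simulate_fly_outcomes(haps, list(), cfg)
    sc <- genome_scan(haps, aggregate_fly_records(sim$flies),
                      "OCT_learning", with_qvalues = FALSE)
    ps <- c(ps, sc$p[!is.na(sc$p)])
  }
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps < 0.05), 0.25)
  expect_gt(min(ps), 1e-8)
})

test_that("Storey q-values satisfy their construction properties and
           match a single-lambda oracle", {
  expect_error(qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  q1 <- suppressWarnings(qvalues(rep(1, 50)))
  expect_true(all(q1$qvalues == q1$pi0))

  set.seed(47)
  p <- c(rep(0.001, 20), runif(180))
  res <- qvalues(p, lambda = 0.5)
  # hand-coded single-lambda Storey oracle
  m <- length(p)
  pi0_or <- min(1, (sum(p > 0.5) / (m * 0.5)))
  ord <- order(p)
  q_or <- numeric(m)
  for (i in seq_len(m)) {
    pi_ <- p[ord][i:m]
    q_or[ord[i]] <- min(pi0_or * m * pi_ / rank(p, ties.method = "max")[ord][i:m])
  }
  expect_lt(max(abs(res$qvalues - q_or)), 1e-9)
  expect_equal(res$pi0, pi0_or)

  # monotonicity in p, and q bounded by pi0 at the top
  res2 <- qvalues(runif(500, 0, 1))
  o <- order(runif(500))  # arbitrary order: check via sort
  pp <- sort(runif(300)); qq <- qvalues(pp)$qvalues
  expect_true(all(diff(qq) >= -1e-12))
  expect_lte(max(qq), qvalues(pp)$pi0)
  expect_gte(min(qq), min(pp) * qvalues(pp)$pi0 - 1e-12)
})

test_that("differential peaks apply the strict threshold and the
           separation rule", {
  mk_scan <- function(nlp) data.frame(chrom = "2",
                                      index = seq_along(nlp),
                                      neg_log10_p = nlp)
  a <- mk_scan(rep(0, 120)); b <- mk_scan(rep(0, 120))
  b$neg_log10_p[c(10, 50, 90, 120)] <- c(3.0, 2.5, 2.1, 1.9)
  pk <- differential_peaks(a, b, threshold = 2, k = 3,
                           min_separation = 10)
  expect_equal(pk$index, c(10, 50, 90))
  expect_equal(pk$rank, 1:3)

  # d exactly 2.0 is excluded; 2.1 next to a bigger peak is suppressed
  b2 <- mk_scan(rep(0, 120))
  b2$neg_log10_p[c(10, 14, 40)] <- c(3.0, 2.8, 2.0)
  pk2 <- differential_peaks(a, b2, threshold = 2, k = 3,
                            min_separation = 10)
  expect_equal(pk2$index, 10)   # 14 suppressed, 40 excluded (d = 2)
  expect_error(differential_peaks(a, mk_scan(rep(0, 10))), "identical")
})

test_that("greedy differential-peak selection matches a brute-force
           loop oracle on random vectors", {
  greedy_oracle <- function(d, thr, k, sep) {
    sel <- integer(0)
    cand <- order(-d)
    for (i in cand) {
      if (d[i] <= thr) next
      if (length(sel) >= k) break
      if (all(abs(sel - i) >= sep)) sel <- c(sel, i)
    }
    sel
  }
  set.seed(48)
  for (rep_ in 1:25) {
    n <- sample(30:100, 1)
    d <- round(runif(n, 0, 4), 3)  # rounding avoids float ties issues
    a <- data.frame(chrom = "2", index = 1:n, neg_log10_p = d)
    b <- data.frame(chrom = "2", index = 1:n, neg_log10_p = 0)
    sep <- sample(2:10, 1)
    pk <- differential_peaks(a, b, threshold = 2, k = 3,
                             min_separation = sep)
    expect_equal(pk$index, greedy_oracle(d, 2, 3, sep))
  }
})

test_that("haplotype means summarize per-founder line scores with odor
           separation", {
  # all lines on one founder, identical scores: mean = s, SE = 0
  haps <- hap_map_from_states(matrix(1L, 6, 1))
  counts <- rbind(
    counts_from_scores(haps$ril_ids, rep(12, 6), rep(20, 6), "OCT"),
    counts_from_scores(haps$ril_ids, rep(12, 6), rep(20, 6), "MCH"))
  hm <- haplotype_means(haps, counts, "2", 1)
  expect_equal(nrow(hm), 2)
  expect_equal(hm$mean, c(0.6, 0.6))
  expect_equal(hm$se, c(0, 0))
  expect_equal(hm$n_rils, c(6L, 6L))

  # an OCT-only planted effect shows spread for OCT, flat for MCH
  cfg <- sim_config(n_rils = 32, flies_per_vial = c(80, 120),
                    n_replicates = 3, sd_ril = 0, sd_replicate = 0,
                    recomb_prob = 0, seed = 49)
  sh <- simulate_ril_haplotypes(founder_panel(chromosomes = c(`2` = 2)),
                                cfg)
  eff <- qtl_effect("2", 1, c(A1 = 2), odor_scope = "OCT_only",
                    phenotype_scope = "learning")
  sim <- simulate_fly_outcomes(sh, eff, cfg)
  hm2 <- haplotype_means(sh, aggregate_fly_records(sim$flies), "2", 1)
  oct <- hm2[hm2$trained_odor == "OCT", ]
  mch <- hm2[hm2$trained_odor == "MCH", ]
  a1 <- oct[oct$founder == "A1", ]
  others <- oct[oct$founder != "A1" & oct$n_rils > 1, ]
  expect_true(all(a1$mean - others$mean >
                  2 * sqrt(a1$se^2 + others$se^2)))
  expect_lt(diff(range(mch$mean[mch$n_rils > 1])),
            diff(range(oct$mean[oct$n_rils > 1])))
})
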