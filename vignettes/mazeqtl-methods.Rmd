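---
title: "Scoring and haplotype mapping of group-tested olfactory y-maze assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and haplotype mapping of group-tested olfactory y-maze assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mazeqtl)
```

## The problem

In group-tested olfactory conditioning, a vial of flies is trained to
associate one odorant (the CS+, paired with sucrose) against another
(the CS-, paired with plain agar) and then released into a y-maze whose
two upper arms carry the two odors. At the end of the run every fly is
in one of three places: the CS+ arm, the CS- arm, or still in the start
chamber. Classic performance indices only use flies that reached an odor
arm and behave badly when group sizes vary; `mazeqtl` instead scores
every fly on two separate binomial decisions:

1. **climbing** — did the fly leave the start chamber at all
   (`climbed` = 0/1); and
2. **correctness** — among climbers, did it choose the CS+ arm
   (`correct` = 0/1, missing for non-climbers).

`to_fly_records()` expands terminal chamber counts into these per-fly
records and `aggregate_fly_records()` inverts the expansion exactly, so
group counts and individual Bernoulli records are interchangeable
representations (their binomial log-likelihoods differ only by constants
that cancel in every likelihood-ratio statistic; a test asserts the
equivalence to 1e-6).

Two preference adjustments accompany the raw scores. The
preference-performance differential (`ppd()`) subtracts a line's
untrained baseline preference for the trained odor from its trained
performance; only its magnitude is interpreted (we fix the sign as
performance minus preference). The override rule
(`classify_override()`) flags lines with performance strictly above 0.5
while baseline preference for that odor is strictly below 0.5 — lines
that chose the sucrose-paired odor *against* their innate preference.
Both 0.5 boundaries are exclusive; the neutral preference band reported
by `run_score()` is the inclusive interval [0.45, 0.55] (the boundary
convention is a documented choice; the band's endpoints are arguments).

## The genome scan model

Phenotypes are vial-level binomial outcomes. For vial \(i\) of line
\(r\):

\[ y_i \sim \mathrm{Binomial}(N_i, p_i), \qquad
   \mathrm{logit}(p_i) = \mu + \alpha_{r(i)} + \beta_{v(i)} \]

with \(\alpha_r \sim N(0, \sigma^2_{\mathrm{RIL}})\) and
\(\beta_v \sim N(0, \sigma^2_{\mathrm{vial}})\) (vial identifiers are
globally unique, so the replicate effect is nested within line). The
alternative model at a genomic position adds the line's founder-ancestry
probabilities \(g_{rj}\) (an 8-founder multiparent panel) as fixed
covariates:

\[ \mathrm{logit}(p_i) = \mu + \sum_{j \in J} g_{r(i)j}\,\gamma_j
   + \alpha_{r(i)} + \beta_{v(i)} \]

Both models are fitted by Laplace-approximate maximum likelihood
(`lme4::glmer`); the likelihood-ratio statistic
\(\Lambda = \max(0,\, 2(\ell_1 - \ell_0))\) is referred to
\(\chi^2_{df}\) and reported as \(-\log_{10} p\). Scans run
independently per trained odor and assay (OCT/MCH x learning/memory)
plus climbing, because odor-specific performance behaves as distinct
phenotypes.

Three design details matter:

* **Founder drop rule.** A founder enters the model only if at least
  `min_ril_count = 4` lines harbor it at the position (harboring means
  \(g_{rj} > 0.5\); both thresholds are arguments). Founders carried by
  three or fewer lines are dropped to avoid overfitting, so the number
  of modelled haplotypes `n_hap` varies along the genome and is
  reported per position.
* **Identifiability.** When the retained probabilities sum to ~1 for
  every line, they are collinear with the intercept; the most frequent
  retained founder is then used as the reference level and
  \(df = n_{hap} - 1\). When a carried founder was dropped the retained
  columns are not complete and all of them are estimated
  (\(df = n_{hap}\)). `df` is always explicit in the output rather than
  inferred.
* **Failures are kept.** A position whose fit does not converge is
  reported with missing p-value but still counts (as p = 1) in the
  multiple-testing denominator, so non-convergence can never manufacture
  significance.

Multiplicity is handled with Storey's positive-FDR q-values, implemented
in `qvalues()`: \(\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))\)
over a grid \(\lambda = 0.05, \dots, 0.95\), smoothed with a cubic
spline and evaluated at the largest \(\lambda\) (below 100 p-values the
single-point \(\lambda = 0.5\) estimator is used);
\(q_i = \min_{p_j \ge p_i} \hat\pi_0\, m\, p_j / \mathrm{rank}_j\). If
every p-value falls below the tuning point the estimator degenerates and
we fall back conservatively to \(\pi_0 = 1\) (Benjamini-Hochberg
scaling) rather than toward significance. Positions are called
significant only at \(q \le 0.05\); on null-like data the pipeline's
verdict is "no significant QTLs".

Odor-differential suggestive peaks compare two scans over identical
positions: \(d = |\!-\!\log_{10} p_{\mathrm{OCT}} +
\log_{10} p_{\mathrm{MCH}}|\), keep \(d > 2\) *strictly* (exactly 2 is
excluded), and select up to three peaks greedily by decreasing \(d\)
while suppressing candidates within `min_separation = 10` scan positions
of an already selected peak. The separation window stands in for the
undefined notion of "unique" nearby positions; it is an explicit
argument, and the greedy procedure is tested against a brute-force
oracle. At reported peaks, `haplotype_means()` assigns each line its
argmax founder (ambiguous below 0.5) and contrasts per-founder mean
proportion-correct between the two trained odors with standard errors
\(sd/\sqrt{n}\).

## Line selection on prior peaks

`select_rils()` reproduces the five-step procedure used to pick extreme
panels: percentile both phenotypes through the empirical CDF, average
them into a cumulative score, call each line's founder at every prior
QTL peak (argmax with a 0.5 certainty floor; below it the call is
"ambiguous" and the line is excluded), keep lines whose calls are
consistently in the peak's high-performing or low-performing founder
sets, drop "mixed" lines, and return the top and bottom k by cumulative
score. Which founders count as high or low at each peak is an *input*
table — those assignments came from a prior mapping study and are not
recomputed here. Ties in cumulative score break deterministically by
line identifier.

## The synthetic study generator

Because the package must be testable without the archived raw data, the
generator produces studies with known ground truth:

* **Haplotypes** follow a symmetric first-order Markov founder mosaic
  per chromosome: uniform start over 8 founders, switch probability
  `recomb_prob` per interval, uniform over the other 7 founders on a
  switch. This simulates the *output format* of the ancestry HMM used
  for real panels; the HMM itself is consumed upstream and not
  re-implemented. Setting `soft_prob_noise = c > 0` draws each row from
  Dirichlet(1 + c x onehot), emulating near-certain soft probability
  rows.
* **Outcomes** are drawn exactly from the scan's data model: per-line
  and per-vial Gaussian logit intercepts for both decisions, vial sizes
  uniform over `flies_per_vial`, and planted `qtl_effect()`s adding
  \(\sum_j g_{rj}\,\mathrm{effect}_j\) to the correctness (or climbing)
  logit within their odor and assay scope. Flies that chose CS+ during
  learning are re-tested for memory with fresh vial intercepts,
  mirroring the assay protocol. Ground truth (line intercepts and
  planted effects) is returned alongside and written as a sidecar TSV.
* **Acuity and preference** tables draw per-line latent proportions
  from Beta distributions and observe them through binomial vial
  counts, with a censored count for the sucrose split plate.

Defaults are chosen to emulate a realistic 50-line study: 3 vials per
line and odor of 20-100 flies (per-line starting samples of roughly
60-600, averaging ~350), logit-scale SDs of 0.3 (line) and 0.2 (vial),
neutral baselines, a 0.05 per-interval switch probability (about five
ancestry breakpoints per ~100-position chromosome, the order observed
in multiparent RIL panels — enough independent blocks for the pFDR
layer to be meaningful at desk scale), and preference Beta(15, 15)
(about half the lines in the neutral band with a 0.2-0.8 spread). All draws flow from one integer
seed with a documented stream order, so identical configurations
reproduce byte-identical tables.

What the generator does *not* emulate: sex, age, or environmental
covariates; linkage-map estimation; sequence-level variants; selection
bias in which flies climb (climbing and correctness are independent
given the intercepts). Passing tests therefore demonstrate correctness
of the machinery under the model's own assumptions, not robustness to
real-data violations of them.

## Problem sizes and numerical choices

Simulation-backed checks run at sizes chosen to make their statistics
meaningful on a desk machine:

* *Null calibration*: 25 independent datasets of 50 lines x ~200 flies,
  20 positions each (500 null p-values). Independent datasets are used
  because all positions of one scan share a single phenotype
  realization — within-scan p-values are strongly dependent, and a
  uniformity test on one scan is uninterpretable.
* *Recovery*: 20 replicates of a +2 logit effect on one founder, 50
  lines x ~300 flies, scanned over a 100-position chromosome with a
  0.05 switch probability per interval (5 cM-equivalent spacing, so
  that "within +/- 5 positions of the plant" is a meaningful
  localization claim at a 50-line panel's resolution).
* GLMM fits use Laplace ML with derivative checks disabled for speed;
  alternative fits are warm-started from the base model's variance
  components (the base model does not depend on position and is fitted
  once per scan). Likelihood-ratio statistics are floored at 0 and
  p-values computed on the log scale for numerical stability at strong
  signals.

## Known limitations

The chi-square reference for the haplotype LRT is **mildly
anti-conservative at realistic panel sizes**. With 50 lines, each of
the ~6-7 retained founder coefficients is informed by only ~6 line
clusters; a parametric bootstrap under the fitted base model at one
such position gives a 0.05-level rejection rate of about 0.087 (mean
LRT 8.0 on 7 df), and marginal null simulations at the sizes above give
an empirical type-I rate of about 0.076 instead of 0.05. This is a
property of applying chi-square asymptotics at a 50-cluster design —
glmmTMB reproduces the same log-likelihoods to four decimals — not of
the implementation. In practice the q-value layer absorbs the mild
inflation for genome-wide decisions (inflated small p-values raise
\(\hat\pi_0\) as well), but nominal per-position p-values near the 0.05
boundary should not be over-read. Users who need exact per-position
error control at small panels should calibrate by parametric bootstrap.

The memory-assay sample is conditioned on learning-assay success (only
CS+ choosers are re-tested), so memory scores are estimated on smaller,
selected samples; the schema carries memory-specific denominators
rather than deriving them from learning counts.

## A worked null run

```{r, eval = FALSE}
cfg <- pipeline_config(
  panel = founder_panel(chromosomes = c(X = 60, `2` = 110, `3` = 110)),
  sim = sim_config(n_rils = 50, seed = 1),
  out_dir = "mazeqtl_run")
res <- run_full(cfg, progress = TRUE)
res$verdict                 # "no significant QTLs" for a null study
summary(res$scans$OCT_learning)
plot(res$scans$OCT_learning, overlay = res$scans$MCH_learning)
```
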