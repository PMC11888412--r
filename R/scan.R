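# Haplotype-probability genome scan with binomial GLMMs.
#
# At every genomic position two nested models are compared on per-vial
# binomial outcomes (successes / trials):
#   base: logit(p) = intercept + a_RIL + b_replicate
#   alt:  base + fixed founder-probability covariates g_ij
# with a_RIL and b_replicate Gaussian random intercepts. The likelihood
# ratio 2*(ll_alt - ll_base) is referred to chi-square with df equal to
# the number of haplotype coefficients actually estimated. Founders
# carried by too few lines at a position are dropped from the alternative
# model (overfitting guard), and since the retained probabilities sum to
# ~1 and the model has an intercept, one founder is used as the reference
# level.

#' Build the per-position design for the alternative model
#'
#' A founder is included at a position iff at least `min_ril_count` lines
#' harbor it, where a line harbors founder j when its probability for j
#' exceeds `harbor_threshold`.
#'
#' @param haps A `ril_hap_map`.
#' @param chromosome,index Position to scan.
#' @param min_ril_count Minimum number of harboring lines for a founder
#'   to stay in the model (default 4: founders carried by 3 or fewer
#'   lines are dropped).
#' @param harbor_threshold Probability above which a line counts as
#'   harboring a founder (default 0.5).
#' @return List of class `position_design`: `chromosome`, `index`, `g`
#'   (RIL x included-founder probability matrix), `included_founders`,
#'   `n_hap`, `harbor_counts` (all 8), `reference` (most-harbored
#'   included founder, used as reference level when probabilities are
#'   complete).
#' @export
build_design <- function(haps, chromosome, index, min_ril_count = 4,
                         harbor_threshold = 0.5) {
  g <- hap_at(haps, chromosome, index)
  harbor <- colSums(g > harbor_threshold)
  included <- haps$founders[harbor >= min_ril_count]
  ref <- if (length(included)) {
    inc_counts <- harbor[included]
    included[which.max(inc_counts)]  # ties: first in founder order
  } else NA_character_
  structure(list(chromosome = as.character(chromosome),
                 index = as.integer(index),
                 g = g[, included, drop = FALSE],
                 included_founders = included,
                 n_hap = length(included),
                 harbor_counts = harbor,
                 reference = ref),
            class = "position_design")
}

# Extract per-vial binomial rows for one scan phenotype from either a
# chamber-counts table or a per-fly record table.
#' Assemble the binomial response table for one scan phenotype
#'
#' For the odor-specific correctness phenotypes (`OCT_learning`,
#' `MCH_learning`, `OCT_memory`, `MCH_memory`) successes are CS+ choices
#' and trials are climbers; for `climbing` successes are climbers and
#' trials all flies in the relevant assay (`climbing_assay`, default
#' `"learning"`, or both assays pooled with `climbing_assay = "pooled"`).
#' Accepts a chamber-counts table or a fly-record table (expanded
#' Bernoulli rows); both give identical model likelihood differences.
#'
#' @param data Chamber-counts or fly-record `data.frame`.
#' @param phenotype One of `OCT_learning`, `MCH_learning`, `OCT_memory`,
#'   `MCH_memory`, `climbing`.
#' @param climbing_assay Assay used for the climbing phenotype.
#' @return Data frame with `ril_id`, `replicate_id`, `successes`,
#'   `trials` (rows with zero trials removed).
#' @export
binomial_data <- function(data, phenotype,
                          climbing_assay = c("learning", "memory",
                                             "pooled")) {
  phenotype <- match.arg(phenotype,
                         c("OCT_learning", "MCH_learning", "OCT_memory",
                           "MCH_memory", "climbing"))
  climbing_assay <- match.arg(climbing_assay)
  if (all(c("climbed", "correct") %in% names(data)))
    data <- aggregate_fly_records(data)
  .validate_counts(data)
  if (phenotype == "climbing") {
    keep <- if (climbing_assay == "pooled")
      data$assay %in% c("learning", "memory")
    else data$assay == climbing_assay
    d <- data[keep, , drop = FALSE]
    out <- data.frame(ril_id = d$ril_id, replicate_id = d$replicate_id,
                      successes = d$n_plus + d$n_minus,
                      trials = d$n_plus + d$n_minus + d$n_nc,
                      stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(phenotype, "_")[[1]]
    d <- data[data$trained_odor == parts[1] & data$assay == parts[2], ,
              drop = FALSE]
    out <- data.frame(ril_id = d$ril_id, replicate_id = d$replicate_id,
                      successes = d$n_plus,
                      trials = d$n_plus + d$n_minus,
                      stringsAsFactors = FALSE)
  }
  out <- out[out$trials > 0, , drop = FALSE]
  if (!nrow(out)) stop("no observations for phenotype ", phenotype)
  rownames(out) <- NULL
  out
}

.fit_glmm <- function(formula, data, start = NULL) {
  ok <- TRUE
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::glmer(formula, data = data, family = stats::binomial(),
                  start = start,
                  control = lme4::glmerControl(calc.derivs = FALSE,
                                               check.conv.singular =
                                                 "ignore")))),
    error = function(e) { ok <<- FALSE; NULL })
  if (ok && !is.null(fit)) {
    conv <- fit@optinfo$conv
    msgs <- unlist(conv$lme4$messages)
    if (!is.null(conv$opt) && conv$opt != 0) ok <- FALSE
    if (any(grepl("failed to converge", msgs, ignore.case = TRUE)))
      ok <- FALSE
  }
  list(fit = fit, converged = ok)
}

#' Fit the base and alternative GLMMs at one position
#'
#' Fits the intercept-plus-random-effects base model and the model adding
#' the position's included founder probabilities as fixed covariates, on
#' identical observations, and reports the likelihood-ratio test. When
#' the included probabilities sum to ~1 for every line (no founder was
#' dropped in practice), the most frequent included founder is omitted as
#' reference and `df = n_hap - 1`; otherwise all included columns are
#' estimated and `df = n_hap`. `df` is reported per position. With no
#' estimable haplotype term the models coincide: statistic 0, p = 1.
#'
#' @param design A [build_design()] result.
#' @param data Per-vial binomial rows from [binomial_data()].
#' @param base_fit Optional pre-fit base model (as returned in the
#'   `base` element) to reuse across positions.
#' @return List of class `position_fit`: `base`, `alt` (each with
#'   `fit`, `loglik`, `converged`), and `result`, a one-row data frame
#'   with `chrom`, `index`, `n_hap`, `df`, `lrt_stat`, `p`,
#'   `neg_log10_p`, `converged`. Non-converged positions carry `NA`
#'   p-values rather than being dropped.
#' @export
fit_position <- function(design, data, base_fit = NULL) {
  stopifnot(inherits(design, "position_design"))
  data <- data[data$ril_id %in% rownames(design$g), , drop = FALSE]
  if (length(unique(data$ril_id)) < 2)
    stop("need observations for at least 2 RILs present in the map")
  data$ril_id <- factor(data$ril_id)
  data$replicate_id <- factor(data$replicate_id)
  if (is.null(base_fit)) {
    base_fit <- .fit_glmm(
      cbind(successes, trials - successes) ~ 1 + (1 | ril_id) +
        (1 | replicate_id), data)
  }
  base_ll <- if (base_fit$converged)
    as.numeric(stats::logLik(base_fit$fit)) else NA_real_

  # attach founder-probability covariates, reference-dropped when the
  # included columns are complete (sum to ~1 for every line in the data)
  inc <- design$included_founders
  est_cols <- character(0)
  if (length(inc)) {
    gsub_ <- design$g[levels(data$ril_id), , drop = FALSE]
    complete <- max(abs(rowSums(gsub_) - 1)) < 0.01
    est_cols <- if (complete && length(inc) > 1) setdiff(inc, design$reference)
      else if (complete) character(0)  # single complete column = intercept
      else inc
  }
  if (length(est_cols)) {
    cn <- paste0("g_", gsub("[^A-Za-z0-9]", "_", est_cols))
    for (i in seq_along(est_cols))
      data[[cn[i]]] <- design$g[as.character(data$ril_id), est_cols[i]]
    f <- stats::as.formula(paste(
      "cbind(successes, trials - successes) ~",
      paste(cn, collapse = " + "),
      "+ (1 | ril_id) + (1 | replicate_id)"))
    start <- if (base_fit$converged)
      list(theta = lme4::getME(base_fit$fit, "theta")) else NULL
    alt_fit <- .fit_glmm(f, data, start = start)
  } else {
    alt_fit <- base_fit
  }
  alt_ll <- if (alt_fit$converged)
    as.numeric(stats::logLik(alt_fit$fit)) else NA_real_
  df <- if (length(est_cols) && alt_fit$converged)
    length(lme4::fixef(alt_fit$fit)) - 1L else length(est_cols)
  converged <- base_fit$converged && alt_fit$converged
  if (df == 0L) {
    lrt <- 0; p <- 1; nlp <- 0
  } else if (!converged) {
    lrt <- NA_real_; p <- NA_real_; nlp <- NA_real_
  } else {
    lrt <- max(0, 2 * (alt_ll - base_ll))
    logp <- stats::pchisq(lrt, df = df, lower.tail = FALSE, log.p = TRUE)
    p <- exp(logp)
    nlp <- -logp / log(10)
  }
  structure(list(
    base = list(fit = base_fit$fit, loglik = base_ll,
                converged = base_fit$converged),
    alt = list(fit = alt_fit$fit, loglik = alt_ll,
               converged = alt_fit$converged),
    result = data.frame(chrom = design$chromosome, index = design$index,
                        n_hap = design$n_hap, df = as.integer(df),
                        lrt_stat = lrt, p = p, neg_log10_p = nlp,
                        converged = converged,
                        stringsAsFactors = FALSE)),
    class = "position_fit")
}

#' @export
print.position_fit <- function(x, ...) {
  r <- x$result
  cat(sprintf(
    "Position %s:%d  n_hap=%d df=%d  LRT=%.3f  -log10 p=%.3f%s\n",
    r$chrom, r$index, r$n_hap, r$df,
    ifelse(is.na(r$lrt_stat), NaN, r$lrt_stat),
    ifelse(is.na(r$neg_log10_p), NaN, r$neg_log10_p),
    if (!r$converged) "  [not converged]" else ""))
  invisible(x)
}

#' Genome scan for one phenotype
#'
#' Runs the nested-GLMM likelihood-ratio test at every position of the
#' haplotype map for one phenotype. The base model does not depend on
#' position and is fitted once; each alternative fit is warm-started from
#' its variance components. Results are deterministic given the inputs
#' and invariant to RIL row order.
#'
#' @inheritParams binomial_data
#' @param haps A `ril_hap_map`.
#' @param min_ril_count,harbor_threshold See [build_design()].
#' @param with_qvalues Append Storey q-values (non-converged positions
#'   enter the correction as p = 1 but keep `NA` q).
#' @param progress Print a progress line every 100 positions.
#' @return A data frame of class `hap_scan` with one row per position:
#'   `chrom`, `index`, `n_hap`, `df`, `lrt_stat`, `p`, `neg_log10_p`,
#'   `converged`, and `q` if requested. Attributes: `phenotype`,
#'   `n_rils`, `n_obs`, `pi0`, `n_failed`.
#' @export
genome_scan <- function(haps, data, phenotype,
                        min_ril_count = 4, harbor_threshold = 0.5,
                        climbing_assay = "learning",
                        with_qvalues = TRUE, progress = FALSE) {
  stopifnot(inherits(haps, "ril_hap_map"))
  d <- binomial_data(data, phenotype, climbing_assay = climbing_assay)
  shared <- intersect(unique(d$ril_id), haps$ril_ids)
  if (!length(shared))
    stop("no RILs shared between haplotype map and phenotype data")
  d <- d[d$ril_id %in% shared, , drop = FALSE]
  d$ril_id <- factor(d$ril_id)
  d$replicate_id <- factor(d$replicate_id)
  base_fit <- .fit_glmm(
    cbind(successes, trials - successes) ~ 1 + (1 | ril_id) +
      (1 | replicate_id), d)
  if (!base_fit$converged)
    stop("base model failed to converge for phenotype ", phenotype)
  pos <- haps$positions
  rows <- vector("list", nrow(pos))
  for (i in seq_len(nrow(pos))) {
    des <- build_design(haps, pos$chrom[i], pos$index[i],
                        min_ril_count = min_ril_count,
                        harbor_threshold = harbor_threshold)
    rows[[i]] <- fit_position(des, d, base_fit = base_fit)$result
    if (progress && i %% 100 == 0)
      message("scanned ", i, "/", nrow(pos), " positions (",
              sum(!vapply(rows[seq_len(i)],
                          function(r) r$converged, logical(1))),
              " non-converged)")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  pi0 <- NA_real_
  if (with_qvalues) {
    p_all <- ifelse(is.na(out$p), 1, out$p)  # failed fits stay in m
    qv <- qvalues(p_all)
    out$q <- ifelse(is.na(out$p), NA_real_, qv$qvalues)
    pi0 <- qv$pi0
  }
  structure(out, class = c("hap_scan", "data.frame"),
            phenotype = phenotype, n_rils = length(shared),
            n_obs = nrow(d), pi0 = pi0,
            n_failed = sum(!out$converged))
}

#' Storey q-values and pi0 for positive FDR control
#'
#' Implements the Storey procedure directly: `pi0` is estimated from the
#' fraction of p-values above each `lambda` in a grid, smoothed with a
#' cubic spline and read off at the largest lambda (for fewer than 100
#' p-values, or a single supplied `lambda`, the single-point estimate
#' `#\{p > lambda\} / (m (1 - lambda))` is used). Each q-value is
#' `min_{p_j >= p_i} pi0 * m * p_j / rank_j`, so q is monotone
#' nondecreasing in p; `pi0` is clamped to `(0, 1]`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param lambda Tuning grid (default `seq(0.05, 0.95, 0.05)`) or a
#'   single value for the plug-in estimator.
#' @return List with `qvalues` (same order as `p`), `pi0`, `lambda`.
#' @export
qvalues <- function(p, lambda = seq(0.05, 0.95, 0.05)) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no NA")
  m <- length(p)
  if (m < 100 && length(lambda) > 1) lambda <- 0.5
  if (length(lambda) == 1) {
    pi0 <- mean(p > lambda) / (1 - lambda)
  } else {
    pl <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    pi0 <- tryCatch(
      stats::predict(stats::smooth.spline(lambda, pl, df = 3),
                     x = max(lambda))$y,
      error = function(e) mean(p > 0.5) / 0.5)
  }
  if (is.na(pi0) || pi0 <= 0) {
    # every p-value below the tuning point: the plug-in estimate is
    # degenerate, fall back to the conservative BH-like pi0 = 1
    warning("pi0 estimate was <= 0; using pi0 = 1")
    pi0 <- 1
  }
  pi0 <- min(pi0, 1)
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[ord] <- cummin(pi0 * m * p[ord] / (m:1))
  q <- pmin(q, 1)
  list(qvalues = q, pi0 = pi0, lambda = lambda)
}

#' Odor-differential suggestive peaks between two scans
#'
#' Computes `d = |neg_log10_p_A - neg_log10_p_B|` at every position of
#' two scans over identical positions, keeps positions with `d` strictly
#' greater than `threshold` (a difference of exactly 2 is excluded under
#' the default), and greedily selects up to `k` unique peaks in
#' decreasing `d`, suppressing candidates within `min_separation`
#' positions (same chromosome, index distance strictly less than
#' `min_separation`) of an already selected peak.
#'
#' @param scan_a,scan_b `hap_scan` objects over identical positions.
#' @param threshold Strict lower bound on `d` (default 2).
#' @param k Maximum number of peaks (default 3).
#' @param min_separation Suppression window in scan positions
#'   (default 10).
#' @return Data frame of class `diff_peaks`: `chrom`, `index`, `d`,
#'   `rank`, `neg_log10_p_a`, `neg_log10_p_b` (possibly 0 rows).
#' @export
differential_peaks <- function(scan_a, scan_b, threshold = 2, k = 3,
                               min_separation = 10) {
  if (!identical(scan_a$chrom, scan_b$chrom) ||
      !identical(scan_a$index, scan_b$index))
    stop("scans do not cover identical positions")
  d <- abs(scan_a$neg_log10_p - scan_b$neg_log10_p)
  cand <- which(!is.na(d) & d > threshold)
  cand <- cand[order(-d[cand], scan_a$chrom[cand], scan_a$index[cand])]
  sel <- integer(0)
  for (i in cand) {
    if (length(sel) >= k) break
    clash <- any(scan_a$chrom[sel] == scan_a$chrom[i] &
                 abs(scan_a$index[sel] - scan_a$index[i]) < min_separation)
    if (!clash) sel <- c(sel, i)
  }
  out <- data.frame(chrom = scan_a$chrom[sel], index = scan_a$index[sel],
                    d = d[sel], rank = seq_along(sel),
                    neg_log10_p_a = scan_a$neg_log10_p[sel],
                    neg_log10_p_b = scan_b$neg_log10_p[sel],
                    stringsAsFactors = FALSE)
  structure(out, class = c("diff_peaks", "data.frame"),
            threshold = threshold, min_separation = min_separation)
}

#' Per-founder mean phenotype scores at a position
#'
#' Assigns each line its most probable founder at the position (lines
#' with maximum probability below `call_threshold` are dropped as
#' ambiguous) and reports, separately for each trained odor, the mean of
#' line-level pooled proportion-correct scores per founder with its
#' standard error (`sd / sqrt(n_rils)`). Founders carried by no line are
#' omitted.
#'
#' @param haps A `ril_hap_map`.
#' @param data Chamber-counts or fly-record table.
#' @param chromosome,index Position to summarize.
#' @param assay `"learning"` or `"memory"`.
#' @param call_threshold Minimum argmax probability for a founder call.
#' @return Data frame of class `hap_means`: `trained_odor`, `founder`,
#'   `mean`, `se`, `n_rils`.
#' @export
haplotype_means <- function(haps, data, chromosome, index,
                            assay = c("learning", "memory"),
                            call_threshold = 0.5) {
  assay <- match.arg(assay)
  g <- hap_at(haps, chromosome, index)
  top <- max.col(g, ties.method = "first")
  pmax_ <- g[cbind(seq_len(nrow(g)), top)]
  call <- ifelse(pmax_ < call_threshold, NA_character_,
                 haps$founders[top])
  names(call) <- haps$ril_ids
  out <- list()
  for (odor in c("OCT", "MCH")) {
    ph <- paste0(odor, "_", assay)
    bd <- tryCatch(binomial_data(data, ph), error = function(e) NULL)
    if (is.null(bd)) next
    succ <- tapply(bd$successes, bd$ril_id, sum)
    tri <- tapply(bd$trials, bd$ril_id, sum)
    score <- succ / tri
    f <- call[names(score)]
    keep <- !is.na(f)
    score <- score[keep]; f <- f[keep]
    if (!length(score)) next
    mu <- tapply(score, f, mean)
    sdv <- tapply(score, f, stats::sd)
    n <- tapply(score, f, length)
    se <- ifelse(n > 1, sdv / sqrt(n), NA_real_)
    out[[odor]] <- data.frame(trained_odor = odor, founder = names(mu),
                              mean = as.numeric(mu), se = as.numeric(se),
                              n_rils = as.integer(n),
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("hap_means", "data.frame"),
            chromosome = as.character(chromosome), index = index,
            assay = assay)
}
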