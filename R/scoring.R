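# Scoring of group-tested y-maze runs.
#
# A y-maze run ends with every fly in one of three places: the CS+ arm
# (sucrose-paired odor; for untrained assays the focal arm), the CS- arm,
# or the start chamber (no choice, NC). Scores separate the decision to
# climb at all from the correctness of the choice among climbers.

.check_counts <- function(..., allow_zero_total = TRUE) {
  args <- list(...)
  for (a in args) {
    if (!is.numeric(a)) stop("counts must be numeric")
    if (any(is.na(a))) stop("counts must not contain NA")
    if (any(a < 0)) stop("counts must be nonnegative")
    if (any(a != floor(a))) stop("counts must be whole numbers")
  }
  invisible(TRUE)
}

#' Climbing score: proportion of flies entering either odor arm
#'
#' First decision point of the two-decision binomial scoring: did the fly
#' leave the start chamber at all? No-choice flies count in the denominator
#' here and nowhere else.
#'
#' @param n_plus Flies in the CS+ (or focal-odor) arm.
#' @param n_minus Flies in the CS- (or alternate) arm.
#' @param n_nc Flies remaining in the start chamber (no choice).
#' @return `(n_plus + n_minus) / (n_plus + n_minus + n_nc)`, vectorized.
#' @examples
#' climbing_score(10, 5, 5)  # 0.75
#' @export
climbing_score <- function(n_plus, n_minus, n_nc) {
  .check_counts(n_plus, n_minus, n_nc)
  tot <- n_plus + n_minus + n_nc
  if (any(tot == 0))
    stop("climbing score undefined: no flies in the assay")
  (n_plus + n_minus) / tot
}

#' Choice score: proportion of climbers choosing the focal arm
#'
#' Second decision point: among flies that entered an odor arm, the fraction
#' choosing CS+ (learning/memory performance), the focal odor (baseline
#' preference), or the odorized arm (odor acuity). No-choice flies never
#' enter the denominator; with zero climbers the score is undefined and an
#' error is raised rather than returning 0 or 0.5.
#'
#' @inheritParams climbing_score
#' @return `n_plus / (n_plus + n_minus)`, vectorized.
#' @export
choice_score <- function(n_plus, n_minus) {
  .check_counts(n_plus, n_minus)
  tot <- n_plus + n_minus
  if (any(tot == 0))
    stop("choice score undefined: no flies entered an odor chamber")
  n_plus / tot
}

#' Preference-performance differential (PPD)
#'
#' Difference between a trained group's performance score and the line's
#' untrained baseline preference for the same odor. Zero means the trained
#' flies chose at their baseline rate; values further from zero give more
#' confidence that choices reflect conditioning rather than innate
#' preference. Sign convention: performance minus preference (only the
#' magnitude is interpreted).
#'
#' @param performance Performance score in `[0, 1]`.
#' @param preference Baseline preference score for the trained odor, in
#'   `[0, 1]`.
#' @return `performance - preference`, in `[-1, 1]`.
#' @export
ppd <- function(performance, preference) {
  stopifnot(is.numeric(performance), is.numeric(preference))
  if (any(performance < 0 | performance > 1, na.rm = TRUE) ||
      any(preference < 0 | preference > 1, na.rm = TRUE))
    stop("ppd: scores must lie in [0, 1]")
  performance - preference
}

#' Override classification: performing against baseline preference
#'
#' A line "overrides" its preference when its trained performance exceeds
#' 0.5 while its baseline preference for the trained odor is below 0.5:
#' the group selected the sucrose-paired odor even though it innately
#' prefers the reciprocal odor. Both inequalities are strict; scores at
#' exactly 0.5 never qualify.
#'
#' @inheritParams ppd
#' @return Logical, vectorized.
#' @export
classify_override <- function(performance, preference) {
  stopifnot(is.numeric(performance), is.numeric(preference))
  performance > 0.5 & preference < 0.5
}

#' Sucrose acuity from a split-plate count
#'
#' Proportion of uncensored flies on the sucrose half of a split agar
#' plate. Censored flies (on the lid, unrecovered from anesthesia, or on
#' the agar boundary) are excluded from the denominator entirely.
#'
#' @param n_sucrose Flies on the sucrose side.
#' @param n_agar Flies on the non-nutritional agar side.
#' @param n_censored Censored flies (ignored by the score; accepted so
#'   whole count rows can be passed through).
#' @return `n_sucrose / (n_sucrose + n_agar)`.
#' @export
sucrose_acuity <- function(n_sucrose, n_agar, n_censored = 0) {
  .check_counts(n_sucrose, n_agar, n_censored)
  tot <- n_sucrose + n_agar
  if (any(tot == 0))
    stop("sucrose acuity undefined: all flies censored")
  n_sucrose / tot
}

#' Place-assay performance index
#'
#' Heat-box place learning/memory PI: time on the cool-associated side
#' minus time on the hot-associated side, over total chamber time.
#' 1 is total avoidance of the hot-associated side, -1 total preference
#' for it.
#'
#' @param t_cool Seconds on the cool-associated side.
#' @param t_hot Seconds on the hot-associated side.
#' @param t_total Total seconds in the chamber; must be positive and at
#'   least `t_cool + t_hot`.
#' @return `(t_cool - t_hot) / t_total`, in `[-1, 1]`.
#' @export
place_pi <- function(t_cool, t_hot, t_total) {
  stopifnot(is.numeric(t_cool), is.numeric(t_hot), is.numeric(t_total))
  if (any(t_cool < 0) || any(t_hot < 0))
    stop("place_pi: times must be nonnegative")
  if (any(t_total <= 0))
    stop("place_pi undefined: total time must be positive")
  if (any(t_cool + t_hot > t_total + 1e-9))
    stop("place_pi: side times exceed total time")
  (t_cool - t_hot) / t_total
}

# ---- chamber count tables and fly records ------------------------------

.counts_cols <- c("ril_id", "replicate_id", "trained_odor", "assay",
                  "n_plus", "n_minus", "n_nc", "n_censored")

#' Build a chamber-counts table
#'
#' Canonical tabular form of terminal y-maze (and split-plate) counts.
#' One row per vial run. Column semantics depend on `assay`:
#' * `learning`, `memory`: `n_plus` = CS+ arm, `n_minus` = CS- arm.
#' * `baseline`: `n_plus` = OCT arm, `n_minus` = MCH arm
#'   (`trained_odor = "none"`).
#' * `odor_acuity`: `n_plus` = odorized arm, `n_minus` = odor-free arm;
#'   `trained_odor` records which odorant was presented.
#' * `sugar_acuity`: `n_plus` = sucrose side, `n_minus` = agar side,
#'   `n_censored` the censored count (0 for all other assays).
#'
#' @param ril_id,replicate_id,trained_odor,assay Label columns.
#' @param n_plus,n_minus,n_nc,n_censored Nonnegative integer counts.
#' @return A `data.frame` with the columns above.
#' @export
chamber_counts <- function(ril_id, replicate_id, trained_odor, assay,
                           n_plus, n_minus, n_nc = 0, n_censored = 0) {
  .check_counts(n_plus, n_minus, n_nc, n_censored)
  assay <- match.arg(as.character(assay),
                     c("learning", "memory", "baseline",
                       "odor_acuity", "sugar_acuity"),
                     several.ok = TRUE)
  data.frame(ril_id = as.character(ril_id),
             replicate_id = as.character(replicate_id),
             trained_odor = as.character(trained_odor),
             assay = assay,
             n_plus = as.integer(n_plus), n_minus = as.integer(n_minus),
             n_nc = as.integer(n_nc), n_censored = as.integer(n_censored),
             stringsAsFactors = FALSE)
}

.validate_counts <- function(counts) {
  missing <- setdiff(.counts_cols, names(counts))
  if (length(missing))
    stop("counts table missing columns: ", paste(missing, collapse = ", "))
  .check_counts(counts$n_plus, counts$n_minus, counts$n_nc,
                counts$n_censored)
  invisible(counts)
}

#' Expand chamber counts into per-fly binomial records
#'
#' The two-decision scoring assigns every fly an individual record even
#' though flies are run as a group: `climbed` is 1 if the fly entered
#' either odor arm, and `correct` is 1/0 for CS+/CS- among climbers and
#' missing (`NA`) for no-choice flies. Expansion is exactly inverse to
#' [aggregate_fly_records()].
#'
#' @param counts A chamber-counts table (learning/memory/baseline rows).
#' @return A `data.frame` with columns `ril_id`, `replicate_id`,
#'   `trained_odor`, `assay`, `climbed`, `correct`; one row per fly.
#' @export
to_fly_records <- function(counts) {
  .validate_counts(counts)
  per_row <- function(i) {
    p <- counts$n_plus[i]; m <- counts$n_minus[i]; nc <- counts$n_nc[i]
    data.frame(
      ril_id = counts$ril_id[i], replicate_id = counts$replicate_id[i],
      trained_odor = counts$trained_odor[i], assay = counts$assay[i],
      climbed = c(rep(1L, p + m), rep(0L, nc)),
      correct = c(rep(1L, p), rep(0L, m), rep(NA_integer_, nc)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(counts)), per_row))
  rownames(out) <- NULL
  out
}

#' Aggregate per-fly records back into chamber counts
#'
#' Inverse of [to_fly_records()]: one row per
#' (ril, replicate, odor, assay) cell with terminal chamber counts.
#'
#' @param flies A fly-record table as produced by [to_fly_records()] or
#'   [simulate_fly_outcomes()].
#' @return A chamber-counts `data.frame` (with `n_censored = 0`).
#' @export
aggregate_fly_records <- function(flies) {
  need <- c("ril_id", "replicate_id", "trained_odor", "assay",
            "climbed", "correct")
  missing <- setdiff(need, names(flies))
  if (length(missing))
    stop("fly table missing columns: ", paste(missing, collapse = ", "))
  if (any(flies$climbed == 0 & !is.na(flies$correct)) ||
      any(flies$climbed == 1 & is.na(flies$correct)))
    stop("correct must be missing exactly when climbed = 0")
  key <- interaction(flies$ril_id, flies$replicate_id, flies$trained_odor,
                     flies$assay, drop = TRUE, lex.order = TRUE)
  agg <- function(x) as.integer(tapply(x, key, sum, na.rm = TRUE))
  first <- !duplicated(key)
  lab <- flies[first, c("ril_id", "replicate_id", "trained_odor", "assay")]
  lab <- lab[order(key[first]), , drop = FALSE]
  out <- data.frame(
    lab,
    n_plus = agg(!is.na(flies$correct) & flies$correct == 1L),
    n_minus = agg(!is.na(flies$correct) & flies$correct == 0L),
    n_nc = agg(flies$climbed == 0L),
    n_censored = 0L,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# ---- per-RIL score sets ------------------------------------------------

.pool <- function(counts, by) {
  key <- interaction(counts[by], drop = TRUE, lex.order = TRUE)
  sums <- function(col) as.integer(tapply(counts[[col]], key, sum))
  first <- !duplicated(key)
  lab <- counts[first, by, drop = FALSE]
  lab <- lab[order(key[first]), , drop = FALSE]
  out <- cbind(lab, n_plus = sums("n_plus"), n_minus = sums("n_minus"),
               n_nc = sums("n_nc"), n_censored = sums("n_censored"))
  rownames(out) <- NULL
  out
}

.safe_choice <- function(p, m) ifelse(p + m > 0, p / (p + m), NA_real_)
.safe_climb <- function(p, m, nc) {
  tot <- p + m + nc
  ifelse(tot > 0, (p + m) / tot, NA_real_)
}

#' Score a chamber-counts table per RIL
#'
#' Computes, for every (RIL, trained odor) cell, the pooled climbing and
#' performance scores for learning and memory, the baseline preference for
#' the trained odor, the preference-performance differential and the
#' override flag. Pooling sums counts across replicates (fly-weighted)
#' rather than averaging replicate proportions; set `pool = FALSE` to get
#' the unpooled per-replicate score rows instead.
#'
#' Baseline rows carry `trained_odor = "none"` with `n_plus` the OCT arm;
#' the preference for MCH is the complement of the OCT preference on the
#' same counts. Cells whose score is undefined (no flies, or no climbers)
#' are reported as `NA`.
#'
#' @param counts A chamber-counts table containing learning and/or memory
#'   rows and optionally baseline rows.
#' @param pool Sum counts across replicates before scoring (default) or
#'   score each replicate row separately.
#' @return A `data.frame` with one row per scored cell: `ril_id`,
#'   `trained_odor`, `assay`, `n_total`, `n_climbed`, `climbing_score`,
#'   `performance_score`, `preference_score`, `ppd`, `override` (for
#'   `pool = FALSE`, also `replicate_id`, and preference columns are `NA`).
#' @export
score_rils <- function(counts, pool = TRUE) {
  .validate_counts(counts)
  perf <- counts[counts$assay %in% c("learning", "memory"), , drop = FALSE]
  base <- counts[counts$assay == "baseline", , drop = FALSE]
  if (!nrow(perf)) stop("no learning or memory rows to score")
  by <- if (pool) c("ril_id", "trained_odor", "assay")
        else c("ril_id", "replicate_id", "trained_odor", "assay")
  pooled <- if (pool) .pool(perf, by) else perf[c(by, "n_plus", "n_minus",
                                                  "n_nc", "n_censored")]
  pooled$n_total <- pooled$n_plus + pooled$n_minus + pooled$n_nc
  pooled$n_climbed <- pooled$n_plus + pooled$n_minus
  pooled$climbing_score <- .safe_climb(pooled$n_plus, pooled$n_minus,
                                       pooled$n_nc)
  pooled$performance_score <- .safe_choice(pooled$n_plus, pooled$n_minus)

  # per-RIL baseline preference toward OCT, pooled over baseline replicates
  pref_oct <- rep(NA_real_, nrow(pooled))
  if (nrow(base)) {
    bp <- .pool(base, "ril_id")
    oct <- .safe_choice(bp$n_plus, bp$n_minus)
    names(oct) <- bp$ril_id
    pref_oct <- unname(oct[pooled$ril_id])
  }
  pooled$preference_score <- ifelse(pooled$trained_odor == "OCT", pref_oct,
                             ifelse(pooled$trained_odor == "MCH",
                                    1 - pref_oct, NA_real_))
  pooled$ppd <- pooled$performance_score - pooled$preference_score
  pooled$override <- ifelse(
    is.na(pooled$performance_score) | is.na(pooled$preference_score), NA,
    pooled$performance_score > 0.5 & pooled$preference_score < 0.5)
  pooled[c("n_plus", "n_minus", "n_nc", "n_censored")] <- NULL
  rownames(pooled) <- NULL
  pooled
}

#' Summarize per-RIL scores across a panel
#'
#' Panel-level descriptive statistics (mean, min, max, number of lines)
#' for each assay-by-odor phenotype, plus override tallies per trained
#' odor split into learning-only, memory-only, and both — the structure
#' used to list lines that perform well against their baseline preference.
#'
#' @param scores Output of [score_rils()] (pooled form).
#' @return A list with elements `phenotypes` (data.frame of summary rows
#'   for performance and climbing scores) and `override` (data.frame with
#'   one row per trained odor: `n_learning_only`, `n_memory_only`,
#'   `n_both`, plus the line identifiers as comma-separated strings).
#' @export
summarize_rils <- function(scores) {
  if (!nrow(scores)) stop("empty score table")
  cell <- interaction(scores$assay, scores$trained_odor, drop = TRUE)
  stat_rows <- function(col, label) {
    ok <- !is.na(scores[[col]])
    s <- scores[ok, , drop = FALSE]
    key <- interaction(s$assay, s$trained_odor, drop = TRUE)
    data.frame(
      assay = tapply(s$assay, key, `[`, 1),
      trained_odor = tapply(s$trained_odor, key, `[`, 1),
      score = label,
      mean = as.numeric(tapply(s[[col]], key, mean)),
      min = as.numeric(tapply(s[[col]], key, min)),
      max = as.numeric(tapply(s[[col]], key, max)),
      n_rils = as.integer(tapply(s[[col]], key, length)),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  phen <- rbind(stat_rows("performance_score", "performance"),
                stat_rows("climbing_score", "climbing"))

  ov <- scores[!is.na(scores$override) & scores$override, , drop = FALSE]
  odors <- sort(unique(scores$trained_odor[scores$trained_odor %in%
                                           c("OCT", "MCH")]))
  ov_rows <- lapply(odors, function(od) {
    l <- unique(ov$ril_id[ov$trained_odor == od & ov$assay == "learning"])
    m <- unique(ov$ril_id[ov$trained_odor == od & ov$assay == "memory"])
    data.frame(trained_odor = od,
               n_learning_only = length(setdiff(l, m)),
               n_memory_only = length(setdiff(m, l)),
               n_both = length(intersect(l, m)),
               learning_only = paste(sort(setdiff(l, m)), collapse = ","),
               memory_only = paste(sort(setdiff(m, l)), collapse = ","),
               both = paste(sort(intersect(l, m)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  list(phenotypes = phen, override = do.call(rbind, ov_rows))
}
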