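# Selection of extreme-performing RILs conditional on founder haplotype
# at previously mapped QTL peaks. The peak positions and which founders
# count as high- vs low-performing at each peak are inputs (derived from
# a prior study), not recomputed here.

#' Empirical cumulative distribution percentile
#'
#' Fraction of `values` less than or equal to `x` (the right-continuous
#' ECDF evaluated at `x`).
#'
#' @param values Nonempty numeric vector.
#' @param x Query value(s).
#' @return Proportion(s) in `[0, 1]`.
#' @export
ecdf_percentile <- function(values, x) {
  if (!length(values)) stop("ecdf_percentile: empty value vector")
  stats::ecdf(values)(x)
}

#' Cumulative learning/memory percentile scores
#'
#' For each line, the ECDF percentile of its learning score within the
#' panel, likewise for memory, and their mean as the cumulative score
#' used to rank lines.
#'
#' @param phenotypes Data frame with columns `ril_id`, `learning`,
#'   `memory`.
#' @return Data frame with `ril_id`, `pct_learning`, `pct_memory`,
#'   `cumulative`.
#' @export
cumulative_scores <- function(phenotypes) {
  need <- c("ril_id", "learning", "memory")
  if (!all(need %in% names(phenotypes)))
    stop("phenotypes must have columns ril_id, learning, memory")
  data.frame(
    ril_id = as.character(phenotypes$ril_id),
    pct_learning = ecdf_percentile(phenotypes$learning,
                                   phenotypes$learning),
    pct_memory = ecdf_percentile(phenotypes$memory, phenotypes$memory),
    cumulative = (ecdf_percentile(phenotypes$learning,
                                  phenotypes$learning) +
                  ecdf_percentile(phenotypes$memory,
                                  phenotypes$memory)) / 2,
    stringsAsFactors = FALSE)
}

#' Call the founder haplotype of each RIL at QTL peaks
#'
#' Assigns each line its most probable founder at every peak position;
#' lines whose maximum founder probability falls below `call_threshold`
#' are called `"ambiguous"` and are excluded downstream.
#'
#' @param haps A `ril_hap_map`.
#' @param peaks Data frame with columns `peak_id`, `chrom`, `index`.
#' @param call_threshold Minimum probability to accept the argmax call
#'   (default 0.5).
#' @return Data frame with `ril_id`, `peak_id`, `founder`.
#' @export
call_peak_haplotypes <- function(haps, peaks, call_threshold = 0.5) {
  need <- c("peak_id", "chrom", "index")
  if (!all(need %in% names(peaks)))
    stop("peaks must have columns peak_id, chrom, index")
  out <- lapply(seq_len(nrow(peaks)), function(i) {
    g <- hap_at(haps, peaks$chrom[i], peaks$index[i])
    top <- max.col(g, ties.method = "first")
    pmax_ <- g[cbind(seq_len(nrow(g)), top)]
    data.frame(ril_id = haps$ril_ids,
               peak_id = as.character(peaks$peak_id[i]),
               founder = ifelse(pmax_ < call_threshold, "ambiguous",
                                haps$founders[top]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Select extreme RILs with consistent founder haplotypes at prior peaks
#'
#' Partitions lines by whether their founder call at every peak belongs to
#' that peak's high-performing or low-performing founder set. Lines with a
#' high-set call at one peak and a low-set call at another ("mixed
#' haplotypes"), an ambiguous call, or a founder in neither set are
#' excluded. The top `k` lines by cumulative score among consistent-high
#' lines and the bottom `k` among consistent-low lines are returned; ties
#' in cumulative score break by RIL identifier order.
#'
#' @param scores Output of [cumulative_scores()].
#' @param calls Output of [call_peak_haplotypes()]; every RIL in `scores`
#'   needs a call at every peak.
#' @param peaks Data frame with columns `peak_id`, `high_founders`,
#'   `low_founders` (comma-separated founder labels).
#' @param k Lines to select per group.
#' @return List of class `ril_selection`: `high`, `low` (character
#'   vectors of `ril_id`, ordered by rank) and `audit`, a per-RIL data
#'   frame with cumulative scores, per-peak class, and the final group.
#' @export
select_rils <- function(scores, calls, peaks, k) {
  if (!all(c("peak_id", "high_founders", "low_founders") %in% names(peaks)))
    stop("peaks must have columns peak_id, high_founders, low_founders")
  if (k < 1) stop("k must be at least 1")
  split_set <- function(s) trimws(strsplit(as.character(s), ",")[[1]])
  classify <- function(ril) {
    cls <- character(nrow(peaks))
    for (i in seq_len(nrow(peaks))) {
      f <- calls$founder[calls$ril_id == ril &
                         calls$peak_id == peaks$peak_id[i]]
      if (length(f) != 1)
        stop("RIL ", ril, " lacks a call at peak ", peaks$peak_id[i])
      cls[i] <- if (f == "ambiguous") "ambiguous"
        else if (f %in% split_set(peaks$high_founders[i])) "high"
        else if (f %in% split_set(peaks$low_founders[i])) "low"
        else "neither"
    }
    if (any(cls %in% c("ambiguous", "neither"))) "excluded"
    else if (all(cls == "high")) "high"
    else if (all(cls == "low")) "low"
    else "mixed"
  }
  grp <- vapply(scores$ril_id, classify, character(1))
  audit <- data.frame(scores, group = unname(grp), stringsAsFactors = FALSE)
  ord <- order(-audit$cumulative, audit$ril_id)
  high_pool <- audit$ril_id[ord][audit$group[ord] == "high"]
  ord_lo <- order(audit$cumulative, audit$ril_id)
  low_pool <- audit$ril_id[ord_lo][audit$group[ord_lo] == "low"]
  if (length(high_pool) < k)
    stop("only ", length(high_pool),
         " consistent high-haplotype RILs available; need k = ", k)
  if (length(low_pool) < k)
    stop("only ", length(low_pool),
         " consistent low-haplotype RILs available; need k = ", k)
  structure(list(high = high_pool[seq_len(k)], low = low_pool[seq_len(k)],
                 audit = audit),
            class = "ril_selection")
}

#' @export
print.ril_selection <- function(x, ...) {
  cat("RIL selection:", length(x$high), "high /", length(x$low),
      "low lines selected from", nrow(x$audit), "candidates\n")
  cat("high:", paste(utils::head(x$high, 10), collapse = " "),
      if (length(x$high) > 10) "...\n" else "\n")
  cat("low: ", paste(utils::head(x$low, 10), collapse = " "),
      if (length(x$low) > 10) "...\n" else "\n")
  invisible(x)
}
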