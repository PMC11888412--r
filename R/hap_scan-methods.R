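# Methods for scan results.

#' @export
print.hap_scan <- function(x, ...) {
  cat("Haplotype genome scan:", attr(x, "phenotype"), "\n")
  cat(" ", nrow(x), "positions,", attr(x, "n_rils"), "RILs,",
      attr(x, "n_obs"), "vial observations\n")
  nf <- attr(x, "n_failed")
  if (!is.null(nf) && nf > 0) cat(" ", nf, "positions failed to converge\n")
  top <- x[order(-x$neg_log10_p), ][1, ]
  cat(sprintf("  max -log10 p = %.3f at %s:%d (n_hap=%d, df=%d)\n",
              top$neg_log10_p, top$chrom, top$index, top$n_hap, top$df))
  if (!is.null(x$q))
    cat(sprintf("  min q = %.3f (pi0 = %.3f)\n", min(x$q, na.rm = TRUE),
                attr(x, "pi0")))
  invisible(x)
}

#' Summarize a genome scan
#'
#' @param object A `hap_scan`.
#' @param alpha Significance level on q-values (default 0.05).
#' @param ... Unused.
#' @return List with the top position, minimum q, `pi0`, the number of
#'   significant positions at `alpha`, and a verdict string.
#' @export
summary.hap_scan <- function(object, alpha = 0.05, ...) {
  top <- object[order(-object$neg_log10_p), ][1, ]
  min_q <- if (!is.null(object$q)) min(object$q, na.rm = TRUE) else NA_real_
  n_sig <- if (!is.null(object$q)) sum(object$q <= alpha, na.rm = TRUE)
           else NA_integer_
  out <- list(phenotype = attr(object, "phenotype"), top = top,
              min_q = min_q, pi0 = attr(object, "pi0"), n_sig = n_sig,
              alpha = alpha,
              verdict = if (!is.na(n_sig) && n_sig == 0)
                "no significant QTLs" else
                  sprintf("%d significant position(s)", n_sig))
  class(out) <- "summary.hap_scan"
  out
}

#' @export
print.summary.hap_scan <- function(x, ...) {
  cat("Scan summary (", x$phenotype, "): ", x$verdict, " at q <= ",
      x$alpha, "\n", sep = "")
  cat(sprintf("  top: %s:%d  -log10 p = %.3f; min q = %.3f, pi0 = %.3f\n",
              x$top$chrom, x$top$index, x$top$neg_log10_p, x$min_q,
              x$pi0))
  invisible(x)
}

#' Manhattan-style plot of a genome scan
#'
#' Plots `-log10 p` against cumulative scan position, alternating color
#' by chromosome.
#'
#' @param x A `hap_scan` (or a second scan overlaid via `overlay`).
#' @param overlay Optional second `hap_scan` drawn in a second color.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hap_scan <- function(x, overlay = NULL, ...) {
  chroms <- unique(x$chrom)
  offs <- c(0, cumsum(tapply(x$index, factor(x$chrom, levels = chroms),
                             max)))
  names(offs) <- c(chroms, "end")
  xp <- x$index + offs[x$chrom]
  col <- c("grey25", "steelblue")[1 + (match(x$chrom, chroms) %% 2)]
  graphics::plot(xp, x$neg_log10_p, pch = 16, cex = 0.6, col = col,
                 xlab = "scan position", ylab = expression(-log[10] ~ p),
                 main = attr(x, "phenotype"), ...)
  if (!is.null(overlay)) {
    xo <- overlay$index + offs[overlay$chrom]
    graphics::points(xo, overlay$neg_log10_p, pch = 16, cex = 0.6,
                     col = "indianred")
    graphics::legend("topright",
                     legend = c(attr(x, "phenotype"),
                                attr(overlay, "phenotype")),
                     col = c("grey25", "indianred"), pch = 16, bty = "n")
  }
  invisible(x)
}

#' @export
print.diff_peaks <- function(x, ...) {
  cat("Odor-differential suggestive peaks (|d| >",
      attr(x, "threshold"), "):", nrow(x), "peak(s)\n")
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
print.hap_means <- function(x, ...) {
  cat(sprintf("Haplotype mean %s scores at %s:%d\n", attr(x, "assay"),
              attr(x, "chromosome"), attr(x, "index")))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Per-founder mean +/- SE plot at a position
#'
#' @param x A `hap_means` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hap_means <- function(x, ...) {
  odors <- unique(x$trained_odor)
  founders <- sort(unique(x$founder))
  xi <- match(x$founder, founders) +
    ifelse(x$trained_odor == odors[1], -0.12, 0.12)
  col <- ifelse(x$trained_odor == odors[1], "steelblue", "indianred")
  ylim <- range(c(x$mean - x$se, x$mean + x$se, 0, 1), na.rm = TRUE)
  graphics::plot(xi, x$mean, pch = 16, col = col, xaxt = "n",
                 xlab = "founder", ylab = "mean proportion correct",
                 ylim = ylim,
                 main = sprintf("%s at %s:%d", attr(x, "assay"),
                                attr(x, "chromosome"), attr(x, "index")),
                 ...)
  graphics::axis(1, at = seq_along(founders), labels = founders)
  ok <- !is.na(x$se)
  graphics::arrows(xi[ok], x$mean[ok] - x$se[ok], xi[ok],
                   x$mean[ok] + x$se[ok], angle = 90, code = 3,
                   length = 0.03, col = col[ok])
  graphics::legend("topright", legend = odors,
                   col = c("steelblue", "indianred")[seq_along(odors)],
                   pch = 16, bty = "n")
  invisible(x)
}
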