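# Tabular input/output. One dialect everywhere: TSV with a header row,
# UTF-8, "." decimal separator, no thousands separators.

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8")
}

#' Read / write a chamber-counts table
#'
#' Columns: `ril_id`, `replicate_id`, `trained_odor`, `assay`, `n_plus`,
#' `n_minus`, `n_nc`, `n_censored` (see [chamber_counts()] for the
#' per-assay column semantics). Schema violations are reported with row
#' numbers.
#'
#' Externally deposited tables use `col_map` to translate their column
#' names (`internal = file_column`) instead of hard-coding a layout.
#'
#' @param path File path.
#' @param col_map Optional named character vector mapping internal column
#'   names to the file's column names.
#' @return `read_counts_tsv`: a validated chamber-counts data frame.
#' @export
read_counts_tsv <- function(path, col_map = NULL) {
  x <- .read_tsv(path)
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      j <- match(col_map[[nm]], names(x))
      if (is.na(j)) stop("mapped column ", col_map[[nm]], " not in ", path)
      names(x)[j] <- nm
    }
    if (!"n_censored" %in% names(x)) x$n_censored <- 0L
  }
  missing <- setdiff(.counts_cols, names(x))
  if (length(missing))
    stop("counts TSV ", path, " missing columns: ",
         paste(missing, collapse = ", "))
  for (col in c("n_plus", "n_minus", "n_nc", "n_censored")) {
    bad <- which(is.na(x[[col]]) | x[[col]] < 0 |
                 x[[col]] != floor(x[[col]]))
    if (length(bad))
      stop("counts TSV ", path, ": invalid ", col, " in row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  x
}

#' @rdname read_counts_tsv
#' @param counts Chamber-counts data frame.
#' @export
write_counts_tsv <- function(counts, path) {
  .validate_counts(counts)
  .write_tsv(counts, path)
}

#' Read / write a haplotype-probability map as TSV
#'
#' Wide format: `ril_id`, `chrom`, `index`, then one probability column
#' per founder (`p_A1` .. `p_A8` for the default panel). Rows must sum to
#' 1 within 1e-6.
#'
#' @param path File path.
#' @param map_path Optional column-name mapping (named character vector
#'   `internal = file_column`) for externally deposited layouts.
#' @return `read_hap_tsv`: a `ril_hap_map`.
#' @export
read_hap_tsv <- function(path, map_path = NULL) {
  x <- .read_tsv(path)
  if (!is.null(map_path)) {
    for (nm in names(map_path)) {
      j <- match(map_path[[nm]], names(x))
      if (is.na(j)) stop("mapped column ", map_path[[nm]], " not in ", path)
      names(x)[j] <- nm
    }
  }
  need <- c("ril_id", "chrom", "index")
  if (!all(need %in% names(x)))
    stop("haplotype TSV needs columns ril_id, chrom, index")
  pcols <- grep("^p_", names(x), value = TRUE)
  if (length(pcols) != 8)
    stop("haplotype TSV needs exactly 8 p_<founder> columns")
  founders <- sub("^p_", "", pcols)
  rils <- unique(x$ril_id)
  pos <- unique(x[c("chrom", "index")])
  pos <- pos[order(match(pos$chrom, unique(pos$chrom)), pos$index), ]
  pos$map_pos <- NA_real_
  R <- length(rils); P <- nrow(pos)
  prob <- array(NA_real_, dim = c(R, P, 8),
                dimnames = list(NULL, NULL, founders))
  ri <- match(x$ril_id, rils)
  pi_ <- match(paste(x$chrom, x$index), paste(pos$chrom, pos$index))
  for (j in seq_len(8))
    prob[cbind(ri, pi_, j)] <- x[[pcols[j]]]
  if (anyNA(prob)) stop("haplotype TSV is not a complete RIL x position grid")
  sums <- apply(prob, c(1, 2), sum)
  if (max(abs(sums - 1)) > 1e-6)
    stop("haplotype probabilities must sum to 1 per row")
  rownames(pos) <- NULL
  structure(list(founders = founders, ril_ids = rils, positions = pos,
                 prob = prob),
            class = "ril_hap_map")
}

#' @rdname read_hap_tsv
#' @param haps A `ril_hap_map`.
#' @export
write_hap_tsv <- function(haps, path) {
  stopifnot(inherits(haps, "ril_hap_map"))
  R <- length(haps$ril_ids); P <- nrow(haps$positions)
  out <- data.frame(
    ril_id = rep(haps$ril_ids, each = P),
    chrom = rep(haps$positions$chrom, R),
    index = rep(haps$positions$index, R),
    stringsAsFactors = FALSE)
  for (j in seq_along(haps$founders))
    out[[paste0("p_", haps$founders[j])]] <-
      as.vector(t(haps$prob[, , j]))
  .write_tsv(out, path)
}

#' Read / write fly-record tables
#'
#' Columns: `ril_id`, `replicate_id`, `trained_odor`, `assay`, `climbed`,
#' `correct` (empty for no-choice flies).
#'
#' @param path File path.
#' @export
read_fly_tsv <- function(path) {
  x <- .read_tsv(path)
  need <- c("ril_id", "replicate_id", "trained_odor", "assay", "climbed",
            "correct")
  if (!all(need %in% names(x)))
    stop("fly TSV needs columns ", paste(need, collapse = ", "))
  if (any(x$climbed == 0 & !is.na(x$correct)) ||
      any(x$climbed == 1 & is.na(x$correct)))
    stop("fly TSV: correct must be missing exactly when climbed = 0")
  x
}

#' @rdname read_fly_tsv
#' @param flies Fly-record data frame.
#' @export
write_fly_tsv <- function(flies, path) .write_tsv(flies, path)

#' Read / write a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Numeric-looking
#' values are converted, comma-separated values become vectors. Writing
#' then reading reproduces the configuration exactly.
#'
#' @param path File path.
#' @return `read_config`: a named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (l in lines) {
    kv <- regmatches(l, regexpr("=", l), invert = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", l)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    parts <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

#' @rdname read_config
#' @param config Named list of scalar/vector values.
#' @export
write_config <- function(config, path) {
  fmt <- function(v) {
    if (is.numeric(v)) paste(format(v, digits = 17, trim = TRUE,
                                    scientific = FALSE), collapse = ",")
    else paste(as.character(v), collapse = ",")
  }
  writeLines(paste0(names(config), " = ",
                    vapply(config, fmt, character(1))), path)
  invisible(path)
}
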