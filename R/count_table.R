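#' Construct a sample-by-feature count table
#'
#' The basic container for amplicon (ASV), rank-aggregated, or pathway count
#' data: a nonnegative integer matrix with samples in rows and features in
#' columns, plus a lineage entry for every feature. Unclassified ranks are
#' recorded as `"UN"`.
#'
#' @param counts numeric matrix, samples x features; nonnegative, integral.
#' @param lineages data.frame with columns `feature`, `phylum`, `family`,
#'   `genus` covering every column of `counts`. May be `NULL` for tables
#'   whose features carry no taxonomy (e.g. pathway abundances), in which
#'   case an all-`"UN"` lineage is filled in.
#' @return An object of class `count_table`: a list with elements `counts`
#'   and `lineages`.
#' @export
count_table <- function(counts, lineages = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have sample rownames and feature colnames")
  }
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(abs(counts - round(counts)) > 1e-8)) stop("counts must be integers")
  storage.mode(counts) <- "double"
  feats <- colnames(counts)
  if (is.null(lineages)) {
    lineages <- data.frame(feature = feats, phylum = "UN", family = "UN",
                           genus = "UN", stringsAsFactors = FALSE)
  }
  need <- c("feature", "phylum", "family", "genus")
  if (!all(need %in% names(lineages))) {
    stop("lineages must have columns: ", paste(need, collapse = ", "))
  }
  missing <- setdiff(feats, lineages$feature)
  if (length(missing) > 0) {
    stop("features without a lineage entry: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  lineages <- lineages[match(feats, lineages$feature), need, drop = FALSE]
  rownames(lineages) <- NULL
  structure(list(counts = counts, lineages = lineages), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d features (total %s reads)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Subset a count table by sample
#'
#' @param x a `count_table`.
#' @param samples character vector of sample ids (row names) to keep.
#' @return A `count_table` restricted to the requested samples.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "count_table"))
  bad <- setdiff(samples, rownames(x$counts))
  if (length(bad) > 0) stop("unknown samples: ", paste(utils::head(bad, 5), collapse = ", "))
  count_table(x$counts[samples, , drop = FALSE], x$lineages)
}

# ---- plain-text I/O -------------------------------------------------------
# All tabular files are TSV with a header row; the first column holds the
# sample (or feature) identifiers.

#' Write a count table to TSV files
#'
#' @param x a `count_table`.
#' @param counts_path path for the sample-by-feature count TSV.
#' @param lineage_path optional path for the lineage TSV.
#' @export
write_count_table <- function(x, counts_path, lineage_path = NULL) {
  stopifnot(inherits(x, "count_table"))
  df <- data.frame(sample_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(lineage_path)) {
    utils::write.table(x$lineages, lineage_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(x)
}

#' Read a count table from TSV files
#'
#' @param counts_path sample-by-feature count TSV (first column sample ids).
#' @param lineage_path optional lineage TSV with columns
#'   `feature`, `phylum`, `family`, `genus`.
#' @return A `count_table`.
#' @export
read_count_table <- function(counts_path, lineage_path = NULL) {
  df <- utils::read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  lin <- if (!is.null(lineage_path)) {
    utils::read.delim(lineage_path, check.names = FALSE, stringsAsFactors = FALSE)
  } else NULL
  count_table(m, lin)
}

#' Write/read a generic TSV table (first column = identifier)
#'
#' @param df data.frame to write.
#' @param path file path.
#' @return `read_tsv_table` returns a data.frame.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
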