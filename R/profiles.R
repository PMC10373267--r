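#' Taxonomy best-hit acceptance gate
#'
#' A best alignment hit is accepted when the mean of its percent identity
#' and percent coverage is at least 93; rejected features are left
#' unclassified ("UN") at all ranks.
#'
#' @param percent_identity,percent_coverage percentages in 0-100
#'   (vectorised).
#' @return Logical vector: accept the hit?
#' @export
accept_hit <- function(percent_identity, percent_coverage) {
  if (any(percent_identity < 0 | percent_identity > 100) ||
      any(percent_coverage < 0 | percent_coverage > 100)) {
    stop("percentages must lie in [0, 100]")
  }
  (percent_identity + percent_coverage) / 2 >= 93
}

#' Build a lineage table from tabular alignment hits
#'
#' Applies [accept_hit()]; rejected hits get "UN" at phylum, family and
#' genus rank.
#'
#' @param hits data.frame with columns `feature`, `percent_identity`,
#'   `percent_coverage`, `phylum`, `family`, `genus`.
#' @return Lineage data.frame (`feature`, `phylum`, `family`, `genus`).
#' @export
lineages_from_hits <- function(hits) {
  ok <- accept_hit(hits$percent_identity, hits$percent_coverage)
  data.frame(feature = hits$feature,
             phylum = ifelse(ok, hits$phylum, "UN"),
             family = ifelse(ok, hits$family, "UN"),
             genus = ifelse(ok, hits$genus, "UN"),
             stringsAsFactors = FALSE)
}

# Label features at a rank, pooling unclassified ones under the nearest
# classified parent as "UN:<parent>" (so distinct UN rows per parent exist).
rank_labels <- function(lineages, rank) {
  is_un <- function(x) is.na(x) | x == "UN" | x == ""
  lab <- switch(rank,
    phylum = ifelse(is_un(lineages$phylum), "UN:Bacteria", lineages$phylum),
    family = ifelse(!is_un(lineages$family), lineages$family,
                    ifelse(!is_un(lineages$phylum),
                           paste0("UN:", lineages$phylum), "UN:Bacteria")),
    genus = ifelse(!is_un(lineages$genus), lineages$genus,
                   ifelse(!is_un(lineages$family),
                          paste0("UN:", lineages$family),
                          ifelse(!is_un(lineages$phylum),
                                 paste0("UN:", lineages$phylum), "UN:Bacteria"))),
    stop("unknown rank: ", rank))
  lab
}

#' Aggregate a count table to a taxonomic rank
#'
#' Counts are summed over features sharing the rank label; features
#' unclassified at the rank are pooled under `"UN:<parent>"` keyed by the
#' nearest classified parent label. Per-sample totals are conserved
#' exactly.
#'
#' @param x a `count_table` with lineages.
#' @param rank `"phylum"`, `"family"` or `"genus"`.
#' @return A `count_table` whose features are rank labels.
#' @export
aggregate_rank <- function(x, rank = c("phylum", "family", "genus")) {
  stopifnot(inherits(x, "count_table"))
  rank <- match.arg(rank)
  lab <- rank_labels(x$lineages, rank)
  agg <- t(rowsum(t(x$counts), group = lab))
  # lineage of an aggregated feature: ranks at/above the aggregation rank
  first <- match(colnames(agg), lab)
  lin <- data.frame(feature = colnames(agg),
                    phylum = x$lineages$phylum[first],
                    family = if (rank %in% c("family", "genus")) x$lineages$family[first] else "UN",
                    genus = if (rank == "genus") x$lineages$genus[first] else "UN",
                    stringsAsFactors = FALSE)
  count_table(agg, lin)
}

#' Per-sample relative abundances, optionally averaged over groups
#'
#' Converts counts to per-sample proportions (each row sums to 1) and, when
#' a grouping is given, returns arithmetic mean and SD of the proportions
#' per group. Zero-depth samples are dropped with a warning.
#'
#' @param x a `count_table`.
#' @param group_by optional factor/character vector (one entry per sample)
#'   to average over, e.g. season.
#' @return Without grouping: a samples x features proportion matrix. With
#'   grouping: list with `mean` and `sd` matrices (groups x features).
#' @export
relative_abundance <- function(x, group_by = NULL) {
  stopifnot(inherits(x, "count_table"))
  depth <- rowSums(x$counts)
  if (any(depth == 0)) {
    warning(sum(depth == 0), " zero-depth sample(s) excluded")
    keep <- depth > 0
    x <- count_table(x$counts[keep, , drop = FALSE], x$lineages)
    if (!is.null(group_by)) group_by <- group_by[keep]
    depth <- depth[keep]
  }
  prop <- sweep(x$counts, 1, depth, "/")
  if (is.null(group_by)) return(prop)
  g <- as.factor(group_by)
  mean_m <- apply(prop, 2, function(col) tapply(col, g, mean))
  sd_m <- apply(prop, 2, function(col) tapply(col, g, stats::sd))
  if (nlevels(g) == 1) {
    mean_m <- matrix(mean_m, 1, dimnames = list(levels(g), colnames(prop)))
    sd_m <- matrix(sd_m, 1, dimnames = list(levels(g), colnames(prop)))
  }
  list(mean = mean_m, sd = sd_m)
}

#' Top-k features by mean relative abundance
#'
#' @param prop samples x features proportion matrix.
#' @param k number of features to keep.
#' @return Character vector of the k feature names with largest mean
#'   proportion, most abundant first.
#' @export
top_features <- function(prop, k) {
  mu <- colMeans(prop)
  names(sort(mu, decreasing = TRUE))[seq_len(min(k, length(mu)))]
}

#' Merge seasonal biological replicates per individual
#'
#' Collapses the per-sample table to one row per (individual, season):
#' the mean of the per-sample relative abundances (library depth varies, so
#' proportions rather than raw counts are averaged). For count-based
#' downstream fits, mean counts rounded to the nearest integer are also
#' returned. Individuals with no sample in a season simply contribute no
#' row for it.
#'
#' @param x a `count_table`.
#' @param metadata data.frame with columns `sample_id`, `individual`,
#'   `season` covering every sample of `x`.
#' @return list with `rel` (merged relative-abundance matrix, rows named
#'   `<individual>.<season>`), `counts` (a `count_table` of rounded mean
#'   counts), and `keys` (data.frame `individual`, `season` per row).
#' @export
merge_replicates <- function(x, metadata) {
  stopifnot(inherits(x, "count_table"))
  need <- c("sample_id", "individual", "season")
  if (!all(need %in% names(metadata))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  idx <- match(rownames(x$counts), metadata$sample_id)
  if (anyNA(idx)) stop("samples missing from metadata: ",
                       paste(utils::head(rownames(x$counts)[is.na(idx)], 5), collapse = ", "))
  md <- metadata[idx, , drop = FALSE]
  key <- paste(md$individual, md$season, sep = ".")
  prop <- relative_abundance(x)
  n_per <- table(key)
  rel <- rowsum(prop, key)
  rel <- rel / as.vector(n_per[rownames(rel)])
  cnt <- rowsum(x$counts, key)
  cnt <- round(cnt / as.vector(n_per[rownames(cnt)]))
  first <- match(rownames(rel), key)
  list(rel = rel,
       counts = count_table(cnt, x$lineages),
       keys = data.frame(individual = md$individual[first],
                         season = md$season[first],
                         row.names = rownames(rel), stringsAsFactors = FALSE))
}

#' Per-sample read-depth summary
#'
#' @param x a `count_table`.
#' @return list with `total` (integer), `mean` (truncated toward zero, the
#'   convention for reporting mean reads per sample), `sd` (n-1 denominator;
#'   `NA` for a single sample), `median`, and `range` (min, max).
#' @export
read_stats <- function(x) {
  stopifnot(inherits(x, "count_table"))
  depth <- rowSums(x$counts)
  if (length(depth) == 0) stop("empty table")
  list(total = sum(depth),
       mean = trunc(sum(depth) / length(depth)),
       sd = if (length(depth) > 1) stats::sd(depth) else NA_real_,
       median = stats::median(depth),
       range = c(min(depth), max(depth)))
}
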