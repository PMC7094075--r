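# Filtering and normalization rules applied to feature tables ahead of the
# diversity, ordination and network stages.

#' Prevalence/abundance filter for feature tables
#'
#' Retains features observed with at least `min_reads` reads in at least
#' `min_samples` samples (both thresholds inclusive). The sample set is
#' unchanged. The fraction of total reads carried by the retained features is
#' attached as attribute `retained_read_fraction`.
#'
#' @param counts feature table matrix (features x samples).
#' @param min_samples minimum number of qualifying samples (default 5).
#' @param min_reads minimum reads per qualifying sample (default 25).
#' @return filtered feature table with attribute `retained_read_fraction`.
#' @export
filter_prevalence <- function(counts, min_samples = 5, min_reads = 25) {
  validate_feature_table(counts)
  stopifnot(min_samples >= 1, min_reads >= 1)
  if (sum(counts) == 0) stop("feature table has no reads")
  keep <- rowSums(counts >= min_reads) >= min_samples
  out <- counts[keep, , drop = FALSE]
  frac <- sum(out) / sum(counts)
  attr(out, "retained_read_fraction") <- frac
  out
}

#' Proportional abundance (relative abundance) normalization
#'
#' Divides each sample's counts by its total so columns sum to one.
#'
#' @param counts feature table matrix; every sample must have reads.
#' @return numeric matrix of per-sample proportions.
#' @export
relative_abundance <- function(counts) {
  totals <- colSums(counts)
  zero <- colnames(counts)[totals == 0]
  if (length(zero))
    stop("samples with zero total reads: ", paste(zero, collapse = ", "))
  sweep(counts, 2L, totals, "/")
}

#' Rarefy a feature table to fixed depth
#'
#' Subsamples each sample's reads uniformly without replacement to exactly
#' `depth` reads (multivariate hypergeometric). Samples with fewer than
#' `depth` total reads are dropped and reported. Deterministic given `seed`.
#'
#' @param counts feature table matrix.
#' @param depth target reads per sample (default 1000).
#' @param seed integer seed (required for reproducibility; NULL uses the
#'   current RNG stream).
#' @return rarefied feature table; dropped sample ids in attribute
#'   `dropped_samples`.
#' @export
rarefy_table <- function(counts, depth = 1000, seed = NULL) {
  validate_feature_table(counts)
  stopifnot(depth >= 1)
  totals <- colSums(counts)
  drop <- colnames(counts)[totals < depth]
  report_dropped(sprintf("samples with < %d reads", depth), drop)
  keep <- counts[, totals >= depth, drop = FALSE]
  if (ncol(keep) == 0L) stop("no samples reach rarefaction depth ", depth)
  out <- with_seed(seed, t(suppressWarnings(vegan::rrarefy(t(keep), depth))))
  dimnames(out) <- dimnames(keep)
  attr(out, "dropped_samples") <- drop
  out
}

#' Centered log-ratio (clr) transform
#'
#' Per sample, log(count + pseudocount) minus the mean of those logs, so each
#' sample (column) sums to zero.
#'
#' @param counts feature table matrix.
#' @param pseudocount positive offset added before the log (default 1).
#' @return numeric matrix, same shape as input.
#' @export
clr_transform <- function(counts, pseudocount = 1) {
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be > 0")
  lg <- log(counts + pseudocount)
  sweep(lg, 2L, colMeans(lg), "-")
}

#' Per-community node filter for network inference
#'
#' Retains features with at least `min_reads` reads in at least
#' `ceiling(min_sample_frac * n_samples)` samples. Intended to be applied to
#' one community type at a time (subset the table before calling).
#'
#' @param counts feature table restricted to one community type.
#' @param min_reads minimum reads per qualifying sample (default 10).
#' @param min_sample_frac fraction of samples required (default 0.5).
#' @return filtered feature table.
#' @export
filter_network_nodes <- function(counts, min_reads = 10, min_sample_frac = 0.5) {
  validate_feature_table(counts)
  if (ncol(counts) == 0L) stop("empty table")
  need <- ceiling(min_sample_frac * ncol(counts))
  keep <- rowSums(counts >= min_reads) >= need
  counts[keep, , drop = FALSE]
}
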