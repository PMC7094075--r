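# Weighted UniFrac distances and principal coordinates analysis.

#' Weighted UniFrac distance matrix
#'
#' For each pair of samples X, Y, with p_X(b) the summed relative abundance
#' of the tips descending from branch b and l_b the branch length, the raw
#' weighted UniFrac distance is sum_b l_b |p_X(b) - p_Y(b)|; the normalized
#' variant (the default) divides by sum_b l_b (p_X(b) + p_Y(b)), giving
#' values in [0, 1]. Proportions are computed from relative abundances so the
#' distance is independent of library size.
#'
#' @param counts feature table matrix (features x samples); every sample must
#'   have reads.
#' @param tree rooted `phylo`; tips must cover the table's features (extra
#'   tips are pruned).
#' @param normalized divide by the abundance-weighted total branch length
#'   (default TRUE).
#' @return symmetric labelled distance matrix (zero diagonal).
#' @export
weighted_unifrac <- function(counts, tree, normalized = TRUE) {
  validate_feature_table(counts)
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("samples with zero total reads: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  tree <- prune_to(tree, rownames(counts))
  ed <- edge_descendants(tree)
  rel <- relative_abundance(counts)[ed$tips, , drop = FALSE]
  P <- ed$edge_tip %*% rel                      # n_edge x n_sample
  n <- ncol(P)
  dm <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n - 1L)) {
    di <- abs(P[, (i + 1L):n, drop = FALSE] - P[, i])
    num <- as.numeric(crossprod(di, ed$lengths))
    if (normalized) {
      den <- as.numeric(crossprod(P[, (i + 1L):n, drop = FALSE] + P[, i],
                                  ed$lengths))
      num <- ifelse(den > 0, num / den, 0)
    }
    dm[i, (i + 1L):n] <- num
    dm[(i + 1L):n, i] <- num
  }
  dm
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers -D^2/2 with the centering operator, eigendecomposes, and
#' returns sample scores eigenvector * sqrt(eigenvalue) for the positive
#' eigenvalues. Negative eigenvalues (non-Euclidean input) are reported but
#' excluded from the scores; no Lingoes/Cailliez correction is applied.
#' Proportion explained is relative to the sum of positive eigenvalues.
#'
#' @param dm symmetric distance matrix with labels.
#' @return object of class `pcoa_ordination`: `scores` (samples x axes),
#'   `eigenvalues` (all, descending), `proportion_explained` (positive axes),
#'   `negative_eigenvalues` (count).
#' @export
pcoa <- function(dm) {
  validate_distance_matrix(dm)
  n <- nrow(dm)
  A <- -0.5 * dm^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  scores <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                                    length(pos))
  rownames(scores) <- rownames(dm)
  colnames(scores) <- paste0("PCoA", seq_along(pos))
  structure(list(
    scores = scores,
    eigenvalues = e$values,
    proportion_explained = e$values[pos] / sum(e$values[pos]),
    negative_eigenvalues = sum(e$values < -tol)
  ), class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  k <- min(3L, ncol(x$scores))
  cat("PCoA of", nrow(x$scores), "samples;", ncol(x$scores),
      "positive axes\n")
  cat("  proportion explained (first axes):",
      paste(sprintf("%.3f", x$proportion_explained[seq_len(k)]), collapse = ", "),
      "\n")
  if (x$negative_eigenvalues > 0)
    cat("  negative eigenvalues dropped:", x$negative_eigenvalues, "\n")
  invisible(x)
}

#' Ordination scores for the leading axes
#'
#' @param ord a `pcoa_ordination`.
#' @param axes how many leading axes (default 2); zero-padded if the
#'   ordination has fewer positive axes.
#' @return samples x axes score matrix.
#' @export
ordination_scores <- function(ord, axes = 2) {
  stopifnot(inherits(ord, "pcoa_ordination"))
  have <- ncol(ord$scores)
  out <- ord$scores[, seq_len(min(axes, have)), drop = FALSE]
  if (have < axes) {
    pad <- matrix(0, nrow(out), axes - have)
    out <- cbind(out, pad)
    colnames(out) <- paste0("PCoA", seq_len(axes))
  }
  out
}
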