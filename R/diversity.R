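# Per-sample alpha diversity: richness, inverse Simpson, evenness and
# Faith's phylogenetic diversity.

#' Alpha diversity of one count vector
#'
#' Richness R is the number of features with non-zero reads; inverse Simpson
#' is 1 / sum(p_i^2) over proportions p; evenness is inverse Simpson divided
#' by richness (1 when all present features are equally abundant).
#'
#' @param x non-negative count vector, not all zero.
#' @return list with `richness`, `inverse_simpson`, `evenness`.
#' @export
alpha_diversity_vector <- function(x) {
  stopifnot(is.numeric(x), all(x >= 0))
  if (sum(x) == 0) stop("all-zero count vector")
  p <- x / sum(x)
  r <- sum(x > 0)
  inv_simpson <- 1 / sum(p^2)
  list(richness = r, inverse_simpson = inv_simpson,
       evenness = inv_simpson / r)
}

#' Alpha diversity table for all samples
#'
#' Computes richness, inverse Simpson diversity, evenness and (when a tree is
#' supplied) Faith's phylogenetic diversity for every sample of a feature
#' table.
#'
#' @param counts feature table matrix (features x samples).
#' @param tree optional rooted `phylo` covering the features; adds a
#'   `faith_pd` column.
#' @param include_root passed to [faith_pd()].
#' @return data.frame with one row per sample.
#' @export
alpha_diversity <- function(counts, tree = NULL, include_root = TRUE) {
  recs <- apply(counts, 2L, alpha_diversity_vector)
  out <- data.frame(
    sample_id = colnames(counts),
    richness = vapply(recs, `[[`, numeric(1), "richness"),
    inverse_simpson = vapply(recs, `[[`, numeric(1), "inverse_simpson"),
    evenness = vapply(recs, `[[`, numeric(1), "evenness"),
    row.names = colnames(counts), stringsAsFactors = FALSE
  )
  if (!is.null(tree))
    out$faith_pd <- faith_pd(counts, tree, include_root = include_root)
  out
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree spanning the features present
#' (count > 0) in each sample. With `include_root = TRUE` (the default, and
#' the convention of the standard ecophylogenetics tools) the spanning
#' subtree is anchored at the tree root, so the stem path to the root is
#' counted; with `FALSE` it is anchored at the most recent common ancestor of
#' the present features (0 for a single feature).
#'
#' @param counts feature table matrix (features x samples); presence/absence
#'   is what matters.
#' @param tree rooted `phylo`; tips must cover the features present.
#' @param include_root anchor the spanning subtree at the root (default TRUE).
#' @return named numeric vector of PD per sample, in branch-length units.
#' @export
faith_pd <- function(counts, tree, include_root = TRUE) {
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1,
                                             dimnames = list(names(counts), "s1"))
  tree <- prune_to(tree, rownames(counts))
  ed <- edge_descendants(tree)
  pres <- (counts[ed$tips, , drop = FALSE] > 0) * 1
  on_path <- (ed$edge_tip %*% pres) > 0   # edge has a present descendant
  pd <- as.numeric(crossprod(on_path, ed$lengths))
  names(pd) <- colnames(counts)
  if (!include_root) {
    # subtract the stem path from the root down to the MRCA of present tips
    for (j in seq_len(ncol(pres))) {
      tips <- ed$tips[pres[, j] > 0]
      if (length(tips) < 1L) next
      if (length(tips) == 1L) { pd[j] <- 0; next }
      node <- ape::getMRCA(ed$tree, tips)
      pd[j] <- pd[j] - node_depth_length(ed$tree, node)
    }
  }
  pd
}

# branch-length distance from the root to `node`
node_depth_length <- function(tree, node) {
  root <- length(tree$tip.label) + 1L
  d <- 0
  while (node != root) {
    k <- which(tree$edge[, 2L] == node)
    d <- d + tree$edge.length[k]
    node <- tree$edge[k, 1L]
  }
  d
}
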