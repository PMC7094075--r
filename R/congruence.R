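# Symmetric Procrustes congruence between ordinations, permutation
# significance, and leave-one-out clade attribution (delta-t).

# center columns and scale the configuration to unit total sum of squares
procrustes_prepare <- function(M) {
  M <- as.matrix(M)
  M <- sweep(M, 2L, colMeans(M), "-")
  ss <- sum(M^2)
  if (ss <= 0) stop("degenerate configuration (all points identical)")
  M / sqrt(ss)
}

#' Symmetric Procrustes fit between two paired score matrices
#'
#' Both configurations are centered and scaled to unit total sum of squares;
#' the singular value decomposition of t(Y) X gives the optimal rotation
#' (reflections allowed). The congruence statistic t0 is the sum of singular
#' values, in [0, 1]; the residual m12^2 = 1 - t0^2, so t0 = sqrt(1 - m12^2).
#' t0 = 1 means Y is a similarity transform of X; 0 means complete
#' discordance.
#'
#' @param X,Y numeric matrices with the same dimensions, rows paired (same
#'   specimen in the same row), at least 3 rows and 2 columns.
#' @return object of class `procrustes_fit` with `t0`, `m12_squared`,
#'   `rotation`, `n`.
#' @export
procrustes_fit <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y))) stop("X and Y must have matching dimensions")
  if (nrow(X) < 3L) stop("need at least 3 paired rows")
  if (ncol(X) < 2L) stop("need at least 2 axes")
  Xc <- procrustes_prepare(X)
  Yc <- procrustes_prepare(Y)
  s <- svd(crossprod(Yc, Xc))
  t0 <- min(1, sum(s$d))
  structure(list(t0 = t0, m12_squared = 1 - t0^2,
                 rotation = s$u %*% t(s$v), n = nrow(X)),
            class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat(sprintf("Procrustes fit (n = %d): t0 = %.4f, m12^2 = %.4f\n",
              x$n, x$t0, x$m12_squared))
  if (!is.null(x$permutation_p))
    cat(sprintf("  permutation p = %.4g (%d permutations)\n",
                x$permutation_p, x$n_permutations))
  invisible(x)
}

#' Procrustes permutation test (protest)
#'
#' Permutes the row order of Y, recomputes the Procrustes t statistic for
#' each permutation, and reports p = (#\{t_perm >= t0\} + 1) /
#' (n_permutations + 1), so p is never zero. Deterministic given `seed`.
#'
#' @inheritParams procrustes_fit
#' @param n_permutations number of row permutations (default 999).
#' @param seed integer seed (NULL uses the current RNG stream).
#' @return a `procrustes_fit` with `permutation_p`, `n_permutations` and the
#'   permutation distribution `t_permuted`.
#' @export
protest_fit <- function(X, Y, n_permutations = 999, seed = NULL) {
  fit <- procrustes_fit(X, Y)
  Xc <- procrustes_prepare(X)
  Yc <- procrustes_prepare(Y)
  n <- nrow(Xc)
  t_perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      idx <- sample.int(n)
      sum(svd(crossprod(Yc[idx, , drop = FALSE], Xc))$d)
    }, numeric(1))
  })
  fit$t_permuted <- t_perm
  fit$n_permutations <- n_permutations
  fit$permutation_p <- (sum(t_perm >= fit$t0 - 1e-10) + 1) / (n_permutations + 1)
  fit
}

#' Leave-one-out clade attribution of Procrustes congruence
#'
#' For each clade at the given taxonomic rank present in the parasite table,
#' removes all parasite features assigned to the clade, recomputes weighted
#' UniFrac distances and a fresh PCoA on the parasite samples only, refits
#' the symmetric Procrustes against the fixed host scores, and reports
#' delta_t = t_excluded - t0. Negative delta_t marks clades contributing to
#' host-parasite congruence; positive delta_t marks clades contributing to
#' discordance. Clades whose exclusion would empty any parasite sample are
#' flagged and skipped; features unassigned at the rank never form a clade.
#'
#' @param parasite_bundle `analysis_bundle` restricted to the parasite
#'   samples, ordered to pair row-for-row with `host_scores`.
#' @param host_scores fixed host ordination scores (samples x 2), NOT
#'   recomputed during exclusions.
#' @param rank taxonomic rank, "phylum" or "order" (any taxonomy column).
#' @param t0_baseline baseline t0 from the un-excluded fit; computed from the
#'   full parasite table when NULL.
#' @param clades optional subset of clade names to evaluate.
#' @param axes number of leading PCoA axes to match (default 2).
#' @param normalized passed to [weighted_unifrac()].
#' @return data.frame with one row per clade: rank, clade,
#'   n_features_excluded, t_excluded, delta_t, flagged.
#' @export
leave_one_out <- function(parasite_bundle, host_scores, rank = "phylum",
                          t0_baseline = NULL, clades = NULL, axes = 2,
                          normalized = TRUE) {
  stopifnot(inherits(parasite_bundle, "analysis_bundle"))
  tax <- parasite_bundle$taxonomy
  if (!rank %in% names(tax)) stop("rank not in taxonomy: ", rank)
  counts <- parasite_bundle$counts
  host_scores <- as.matrix(host_scores)
  if (nrow(host_scores) != ncol(counts))
    stop("host_scores rows must pair with parasite samples")

  parasite_scores <- function(tab) {
    ordination_scores(pcoa(weighted_unifrac(tab, parasite_bundle$tree,
                                            normalized = normalized)), axes)
  }
  if (is.null(t0_baseline))
    t0_baseline <- procrustes_fit(host_scores, parasite_scores(counts))$t0

  labels <- tax[rownames(counts), rank]
  all_clades <- sort(unique(labels[labels != "unassigned"]))
  if (!is.null(clades)) all_clades <- intersect(all_clades, clades)

  rows <- lapply(all_clades, function(cl) {
    excl <- labels == cl
    kept <- counts[!excl, , drop = FALSE]
    if (nrow(kept) == 0L || any(colSums(kept) == 0)) {
      return(data.frame(rank = rank, clade = cl,
                        n_features_excluded = sum(excl),
                        t_excluded = NA_real_, delta_t = NA_real_,
                        flagged = TRUE, stringsAsFactors = FALSE))
    }
    if (sum(counts[excl, , drop = FALSE]) == 0) {
      # excluding features absent from every sample provably leaves the
      # distances unchanged; report delta_t = 0 exactly
      t_ex <- t0_baseline
    } else {
      t_ex <- procrustes_fit(host_scores, parasite_scores(kept))$t0
    }
    data.frame(rank = rank, clade = cl, n_features_excluded = sum(excl),
               t_excluded = t_ex, delta_t = t_ex - t0_baseline,
               flagged = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(rank = character(0), clade = character(0),
                      n_features_excluded = integer(0),
                      t_excluded = numeric(0), delta_t = numeric(0),
                      flagged = logical(0), stringsAsFactors = FALSE)
  attr(out, "t0_baseline") <- t0_baseline
  out
}

#' Drill the leave-one-out attribution down to orders within top phyla
#'
#' Reruns [leave_one_out()] at the order rank, restricted to orders belonging
#' to the `top_k` phyla with the largest absolute delta_t in the phylum-rank
#' records.
#'
#' @param records phylum-rank data.frame from [leave_one_out()].
#' @param parasite_bundle,host_scores,t0_baseline,axes,normalized as in
#'   [leave_one_out()].
#' @param top_k how many phyla to drill into (default 3).
#' @return data.frame of order-rank leave-one-out records.
#' @export
drill_down <- function(records, parasite_bundle, host_scores,
                       t0_baseline = NULL, top_k = 3, axes = 2,
                       normalized = TRUE) {
  if (top_k <= 0 || nrow(records) == 0L)
    return(leave_one_out(parasite_bundle, host_scores, rank = "order",
                         t0_baseline = t0_baseline, clades = character(0),
                         axes = axes, normalized = normalized))
  ok <- records[!records$flagged, , drop = FALSE]
  top <- ok$clade[order(-abs(ok$delta_t))]
  top <- utils::head(top, top_k)
  tax <- parasite_bundle$taxonomy
  present <- rownames(parasite_bundle$counts)
  orders <- unique(tax[present, "order"][tax[present, "phylum"] %in% top])
  orders <- setdiff(orders, "unassigned")
  leave_one_out(parasite_bundle, host_scores, rank = "order",
                t0_baseline = t0_baseline %||% attr(records, "t0_baseline"),
                clades = orders, axes = axes, normalized = normalized)
}

#' Pair two community types' samples by specimen
#'
#' Returns the sample ids of two community types ordered so that row i of
#' both refers to the same excavated specimen. Types sharing specimen ids
#' (e.g. a parasite organ and the host organ it is attached to) are matched
#' on `specimen_id`; types from different specimens (e.g. infected versus
#' uninfected patches) are matched positionally within site after sorting by
#' (site_id, specimen_id).
#'
#' @param metadata sample metadata data.frame.
#' @param type_a,type_b community-type codes.
#' @return list with character vectors `a` and `b` of equal length.
#' @export
match_specimens <- function(metadata, type_a, type_b) {
  ma <- metadata[metadata$community_type == type_a, , drop = FALSE]
  mb <- metadata[metadata$community_type == type_b, , drop = FALSE]
  shared <- intersect(ma$specimen_id, mb$specimen_id)
  if (length(shared) >= 3L) {
    shared <- sort(shared)
    a <- ma$sample_id[match(shared, ma$specimen_id)]
    b <- mb$sample_id[match(shared, mb$specimen_id)]
    return(list(a = a, b = b))
  }
  ma <- ma[order(ma$site_id, ma$specimen_id), , drop = FALSE]
  mb <- mb[order(mb$site_id, mb$specimen_id), , drop = FALSE]
  n <- min(nrow(ma), nrow(mb))
  list(a = ma$sample_id[seq_len(n)], b = mb$sample_id[seq_len(n)])
}
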