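# Compositional co-association network inference and comparison:
# SparCC-style log-ratio correlations with bootstrap pseudo-p-values,
# neighborhood-selection (MB) networks with StARS stability selection,
# igraph-backed network statistics, and the bootstrap mean-centrality
# Kolmogorov-Smirnov comparison.

# ---- SparCC ----------------------------------------------------------------

# variation matrix T_ij = var(log(f_i / f_j)) from a fractions matrix
# (features x samples), computed as v_i + v_j - 2 cov_ij on log fractions.
variation_matrix <- function(frac) {
  L <- log(frac)
  C <- stats::cov(t(L))
  v <- diag(C)
  outer(v, v, "+") - 2 * C
}

# solve the sparsity-approximation linear system for basis variances omega,
# given the variation matrix and a logical inclusion matrix over pairs
# (diagonal ignored). t_i = sum_included T_ij ~ n_i omega_i + sum omega_j.
solve_basis_variances <- function(TT, incl) {
  diag(incl) <- FALSE
  A <- incl * 1
  diag(A) <- rowSums(incl)
  tvec <- rowSums(TT * incl)
  solve(A, tvec)
}

basis_correlations <- function(TT, omega) {
  # non-positive basis variances mark degenerate features: their rows are
  # reported as missing rather than propagated through the square root
  om <- omega
  om[!is.finite(om) | om <= 0] <- NA_real_
  denom <- 2 * sqrt(outer(om, om))
  rho <- (outer(om, om, "+") - TT) / denom
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  diag(rho) <- 1
  rho
}

# one SparCC estimate from one fractions matrix, with iterative exclusion of
# the most strongly correlated pairs (the "strongly correlated pair" removal
# heuristic of the reference algorithm).
sparcc_once <- function(frac, exclusion_threshold, exclusion_rounds) {
  D <- nrow(frac)
  TT <- variation_matrix(frac)
  incl <- matrix(TRUE, D, D); diag(incl) <- FALSE
  omega <- solve_basis_variances(TT, incl)
  rho <- basis_correlations(TT, omega)
  if (D >= 4L) {
    for (r in seq_len(exclusion_rounds)) {
      cand <- abs(rho); cand[!incl | !is.finite(cand)] <- -Inf
      diag(cand) <- -Inf
      m <- which.max(cand)
      if (!is.finite(cand[m]) || cand[m] <= exclusion_threshold) break
      ij <- arrayInd(m, dim(cand))
      # keep every feature attached to at least 2 pairs, else stop excluding
      if (sum(incl[ij[1L], ]) <= 2L || sum(incl[ij[2L], ]) <= 2L) break
      incl[ij[1L], ij[2L]] <- incl[ij[2L], ij[1L]] <- FALSE
      omega <- solve_basis_variances(TT, incl)
      rho <- basis_correlations(TT, omega)
    }
  }
  list(rho = rho, omega = omega, TT = TT)
}

#' SparCC compositional correlations
#'
#' Estimates linear correlations between the latent (unobserved) log basis
#' abundances of features from compositional count data. Per inner
#' iteration, fractions are drawn from a Dirichlet posterior (counts + 1) per
#' sample; the log-ratio variation matrix T_ij = var(log(f_i/f_j)) is formed;
#' basis variances are solved from the sparsity approximation; and
#' rho_ij = (omega_i + omega_j - T_ij) / (2 sqrt(omega_i omega_j)), clipped
#' to [-1, 1]. Pairs correlated beyond `exclusion_threshold` are iteratively
#' excluded from the basis-variance system (up to `exclusion_rounds` pairs).
#' The returned correlation is the element-wise median over inner iterations.
#' Features with non-positive estimated basis variance are flagged and their
#' rows/columns set to NA. Deterministic given `seed`.
#'
#' @param counts feature table matrix (features x samples); at least 3
#'   features (D = 3 is solved exactly; the exclusion heuristic needs D >= 4)
#'   and 3 samples.
#' @param inner_iterations Dirichlet resampling iterations (default 20).
#' @param exclusion_threshold correlation magnitude above which a pair is
#'   excluded from the basis system (default 0.1).
#' @param exclusion_rounds maximum excluded pairs (default 10).
#' @param seed integer seed (NULL uses the current RNG stream).
#' @return correlation matrix with attributes `omega` (median basis
#'   variances) and `variation_matrix` (median T).
#' @export
sparcc_correlations <- function(counts, inner_iterations = 20,
                                exclusion_threshold = 0.1,
                                exclusion_rounds = 10, seed = NULL) {
  D <- nrow(counts); n <- ncol(counts)
  if (D < 3L) stop("SparCC needs at least 3 features")
  if (n < 3L) stop("SparCC needs at least 3 samples")
  with_seed(seed, {
    rhos <- array(NA_real_, c(D, D, inner_iterations))
    omegas <- matrix(NA_real_, D, inner_iterations)
    TTs <- array(NA_real_, c(D, D, inner_iterations))
    for (it in seq_len(inner_iterations)) {
      g <- matrix(stats::rgamma(D * n, shape = counts + 1), D, n)
      frac <- sweep(g, 2L, colSums(g), "/")
      est <- sparcc_once(frac, exclusion_threshold, exclusion_rounds)
      rhos[, , it] <- est$rho
      omegas[, it] <- est$omega
      TTs[, , it] <- est$TT
    }
    rho <- apply(rhos, c(1L, 2L), stats::median, na.rm = TRUE)
    rho[is.nan(rho)] <- NA_real_
    diag(rho) <- 1
    dimnames(rho) <- list(rownames(counts), rownames(counts))
    attr(rho, "omega") <- apply(omegas, 1L, stats::median, na.rm = TRUE)
    attr(rho, "variation_matrix") <- apply(TTs, c(1L, 2L), stats::median)
    rho
  })
}

#' Bootstrap pseudo-p-values for SparCC correlations
#'
#' Resamples samples with replacement `n_bootstrap` times, recomputes the
#' SparCC correlation each time, and reports the two-sided sign-crossing
#' pseudo-p for each pair: 2 * min(#\{rho_b <= 0\}, #\{rho_b >= 0\}) / B,
#' floored at 1/B and capped at 1. Deterministic given `seed`.
#'
#' @inheritParams sparcc_correlations
#' @param n_bootstrap number of bootstrap datasets (default 100; fewer than
#'   20 triggers a granularity warning).
#' @return matrix of pseudo-p-values.
#' @export
sparcc_pvalues <- function(counts, n_bootstrap = 100, inner_iterations = 20,
                           exclusion_threshold = 0.1, exclusion_rounds = 10,
                           seed = NULL) {
  if (n_bootstrap < 20) warning("fewer than 20 bootstraps: p-values are coarse")
  D <- nrow(counts); n <- ncol(counts)
  with_seed(seed, {
    n_le <- matrix(0, D, D)
    n_ge <- matrix(0, D, D)
    for (b in seq_len(n_bootstrap)) {
      idx <- sample.int(n, n, replace = TRUE)
      rb <- sparcc_correlations(counts[, idx, drop = FALSE],
                                inner_iterations = inner_iterations,
                                exclusion_threshold = exclusion_threshold,
                                exclusion_rounds = exclusion_rounds,
                                seed = NULL)
      n_le <- n_le + (!is.na(rb) & rb <= 0)
      n_ge <- n_ge + (!is.na(rb) & rb >= 0)
    }
    p <- 2 * pmin(n_le, n_ge) / n_bootstrap
    p <- pmin(pmax(p, 1 / n_bootstrap), 1)
    dimnames(p) <- list(rownames(counts), rownames(counts))
    diag(p) <- NA_real_
    p
  })
}

# ---- network construction --------------------------------------------------

#' Threshold correlation/p matrices into a co-association network
#'
#' Keeps edge (i, j) iff |rho_ij| > `min_abs_corr` AND p_ij < `alpha` (both
#' strict). Isolated nodes are retained in the node set.
#'
#' @param rho symmetric correlation matrix with feature dimnames.
#' @param p matching matrix of pseudo-p-values.
#' @param min_abs_corr correlation magnitude threshold (default 0.6).
#' @param alpha significance threshold (default 0.05).
#' @param node_data optional data.frame of per-node annotation (abundance,
#'   phylum), rownames = feature ids.
#' @param method label stored on the network (default "sparcc").
#' @return object of class `coassoc_network`.
#' @export
threshold_edges <- function(rho, p, min_abs_corr = 0.6, alpha = 0.05,
                            node_data = NULL, method = "sparcc") {
  stopifnot(all(dim(rho) == dim(p)))
  ids <- rownames(rho)
  keep <- !is.na(rho) & !is.na(p) & abs(rho) > min_abs_corr & p < alpha
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1L]], to = ids[idx[, 2L]],
                      weight = rho[keep], sign = sign(rho[keep]),
                      stringsAsFactors = FALSE)
  coassoc_network(ids, edges, method = method,
                  params = list(min_abs_corr = min_abs_corr, alpha = alpha),
                  node_data = node_data)
}

#' Construct a co-association network object
#'
#' @param nodes character vector of node (feature) ids.
#' @param edges data.frame with columns from, to, weight, sign (each
#'   unordered pair at most once, no self-edges).
#' @param method inference method label.
#' @param params list of inference parameters.
#' @param node_data optional per-node annotation data.frame.
#' @return object of class `coassoc_network`.
#' @export
coassoc_network <- function(nodes, edges, method = "unknown",
                            params = list(), node_data = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    stopifnot(all(c("from", "to", "weight") %in% names(edges)))
    if (any(edges$from == edges$to)) stop("self-edges are not allowed")
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (anyDuplicated(key)) stop("duplicate edges")
    if (!all(c(edges$from, edges$to) %in% nodes))
      stop("edge endpoints must be nodes")
    if (is.null(edges$sign)) edges$sign <- sign(edges$weight)
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0), sign = numeric(0),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = as.character(nodes), edges = edges, method = method,
                 params = params, node_data = node_data),
            class = "coassoc_network")
}

#' @export
print.coassoc_network <- function(x, ...) {
  cat(sprintf("coassoc_network (%s): %d nodes, %d edges (%d positive, %d negative)\n",
              x$method, length(x$nodes), nrow(x$edges),
              sum(x$edges$sign > 0), sum(x$edges$sign < 0)))
  invisible(x)
}

#' Convert a co-association network to an igraph graph
#' @param net a `coassoc_network`.
#' @return undirected igraph object with `weight` and `sign` edge attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "coassoc_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Write a co-association network to file
#'
#' @param net a `coassoc_network`.
#' @param path output path.
#' @param format "edge-tsv" (one record per edge: from, to, weight, sign) or
#'   "graphml".
#' @export
write_network <- function(net, path, format = c("edge-tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "edge-tsv") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Read a co-association network from file
#' @param path file written by [write_network()].
#' @param format "edge-tsv" or "graphml".
#' @param nodes full node set for edge-tsv input (isolated nodes are not
#'   recoverable from the edge list alone); defaults to the edge endpoints.
#' @return a `coassoc_network`.
#' @export
read_network <- function(path, format = c("edge-tsv", "graphml"),
                         nodes = NULL) {
  format <- match.arg(format)
  if (format == "edge-tsv") {
    edges <- utils::read.delim(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    if (is.null(nodes)) nodes <- unique(c(edges$from, edges$to))
    return(coassoc_network(nodes, edges, method = "file"))
  }
  g <- igraph::read_graph(path, format = "graphml")
  edges <- igraph::as_data_frame(g, what = "edges")
  coassoc_network(igraph::V(g)$name, edges, method = "file")
}

# ---- MB / StARS ------------------------------------------------------------

#' Neighborhood-selection network with StARS model selection
#'
#' Meinshausen-Buhlmann neighborhood selection on clr-transformed data: each
#' feature is lasso-regressed on all others over a geometric lambda path from
#' lambda_max (the largest absolute off-diagonal empirical correlation) down
#' to lambda_max * `min_lambda_ratio`. The penalty is chosen by StARS
#' stability selection: over `n_subsamples` subsamples of floor(0.8 n)
#' samples, per-pair edge instability 2 theta (1 - theta) is averaged; the
#' selected lambda is the largest one whose monotonized mean instability is
#' at most `instability_threshold`. The final graph is the union (OR rule) of
#' neighborhoods refit on the full data at the selected lambda; edge weight
#' is the mean of the two directed coefficients.
#'
#' @param x clr-transformed real matrix, features x samples.
#' @param nlambda path length (default 100).
#' @param min_lambda_ratio smallest lambda as a fraction of lambda_max
#'   (default 0.002).
#' @param n_subsamples StARS subsamples (default 30).
#' @param instability_threshold StARS instability cutoff (default 0.05).
#' @param seed integer seed (NULL uses the current RNG stream).
#' @param node_data optional per-node annotation.
#' @return a `coassoc_network`; attributes record the lambda path, selected
#'   lambda and instability curve.
#' @export
mb_stars_network <- function(x, nlambda = 100, min_lambda_ratio = 0.002,
                             n_subsamples = 30, instability_threshold = 0.05,
                             seed = NULL, node_data = NULL) {
  x <- as.matrix(x)
  keep <- apply(x, 1L, stats::sd) > 0
  if (any(!keep)) {
    warning("dropping constant features: ",
            paste(rownames(x)[!keep], collapse = ", "))
    x <- x[keep, , drop = FALSE]
  }
  D <- nrow(x); n <- ncol(x)
  if (n < 4L) stop("need at least 4 samples")
  ids <- rownames(x) %||% paste0("V", seq_len(D))
  Z <- scale(t(x))                       # n x D, standardized columns
  cors <- abs(stats::cor(Z)); diag(cors) <- 0
  lambda_max <- max(cors)
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * min_lambda_ratio),
                     length.out = nlambda))

  # adjacency (upper triangle, OR rule) per lambda for one data subset
  neighborhoods <- function(Zs) {
    Zs <- scale(Zs)
    adj <- array(FALSE, c(D, D, nlambda))
    for (i in seq_len(D)) {
      fit <- glmnet::glmnet(Zs[, -i, drop = FALSE], Zs[, i],
                            family = "gaussian", lambda = lambdas,
                            standardize = FALSE, intercept = FALSE)
      B <- as.matrix(fit$beta)            # (D-1) x length(fit$lambda)
      used <- length(fit$lambda)
      nz <- B != 0
      others <- seq_len(D)[-i]
      for (l in seq_len(used)) {
        sel <- others[nz[, l]]
        adj[i, sel, l] <- TRUE
      }
      if (used < nlambda)                  # glmnet may truncate the path
        for (l in seq.int(used + 1L, nlambda)) adj[, , l] <- adj[, , used]
    }
    adj | aperm(adj, c(2L, 1L, 3L))
  }

  sub_size <- floor(0.8 * n)
  theta <- with_seed(seed, {
    acc <- array(0, c(D, D, nlambda))
    for (b in seq_len(n_subsamples)) {
      idx <- sample.int(n, sub_size)
      acc <- acc + neighborhoods(Z[idx, , drop = FALSE])
    }
    acc / n_subsamples
  })
  inst <- apply(2 * theta * (1 - theta), 3L, function(M)
    sum(M[upper.tri(M)]) / choose(D, 2))
  inst_bar <- cummax(inst)                 # monotonize along decreasing lambda
  ok <- which(inst_bar <= instability_threshold)
  sel <- if (length(ok)) max(ok) else 1L
  lambda_star <- lambdas[sel]

  # final fit on full data at lambda*
  coefs <- matrix(0, D, D, dimnames = list(ids, ids))
  for (i in seq_len(D)) {
    fit <- glmnet::glmnet(Z[, -i, drop = FALSE], Z[, i], family = "gaussian",
                          lambda = lambdas, standardize = FALSE,
                          intercept = FALSE)
    b <- as.matrix(glmnet::coef.glmnet(fit, s = lambda_star,
                                       exact = FALSE))[-1L, 1L]
    coefs[i, seq_len(D)[-i]] <- b
  }
  W <- (coefs + t(coefs)) / 2
  A <- (coefs != 0) | (t(coefs) != 0)      # OR rule
  A[lower.tri(A, diag = TRUE)] <- FALSE
  idx <- which(A, arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1L]], to = ids[idx[, 2L]],
                      weight = W[A], sign = sign(W[A]),
                      stringsAsFactors = FALSE)
  net <- coassoc_network(ids, edges, method = "mb-stars",
                         params = list(nlambda = nlambda,
                                       min_lambda_ratio = min_lambda_ratio,
                                       n_subsamples = n_subsamples,
                                       instability_threshold = instability_threshold),
                         node_data = node_data)
  attr(net, "lambda_path") <- lambdas
  attr(net, "lambda_star") <- lambda_star
  attr(net, "instability") <- inst_bar
  net
}

# ---- network statistics ----------------------------------------------------

#' Node- and network-level statistics of a co-association network
#'
#' Degree and betweenness centrality are computed on the unweighted,
#' sign-ignored graph (shortest-path counting with each unordered pair
#' counted once, endpoints excluded). Edge density is |E| / (V(V-1)/2).
#' Betweenness centralization is the Freeman index
#' sum_i (b_max - b_i) / ((V-1)^2 (V-2) / 2), 0 when V < 3; it is 0 when all
#' nodes are equally central and 1 for a star.
#'
#' @param net a `coassoc_network`.
#' @return list of class `network_stats`: `degree`, `betweenness` (named
#'   vectors), `edge_density`, `betweenness_centralization`, `n_nodes`,
#'   `n_edges`.
#' @export
network_stats <- function(net) {
  g <- as_igraph(net)
  V <- igraph::vcount(g)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  dens <- if (V < 2L) 0 else igraph::edge_density(g)
  centr <- if (V < 3L) 0 else
    igraph::centr_betw(g, directed = FALSE, normalized = TRUE)$centralization
  structure(list(degree = deg, betweenness = btw, edge_density = dens,
                 betweenness_centralization = centr,
                 n_nodes = V, n_edges = igraph::ecount(g)),
            class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf("network_stats: %d nodes, %d edges, density %.3f, betweenness centralization %.3f\n",
              x$n_nodes, x$n_edges, x$edge_density,
              x$betweenness_centralization))
  invisible(x)
}

#' Bootstrap mean-centrality Kolmogorov-Smirnov comparison
#'
#' For each network's node-statistic vector, draws `n_reps` bootstrap means
#' of `k` values sampled with replacement, then compares the two
#' distributions of means with a two-sample Kolmogorov-Smirnov test
#' (asymptotic p). `k` is used as-is even when a network has fewer than `k`
#' nodes. Deterministic given `seed`.
#'
#' @param values_a,values_b node-statistic vectors (e.g. betweenness) of the
#'   two networks; non-empty.
#' @param k resample size per mean (default 50).
#' @param n_reps number of bootstrap means per network (default 10000).
#' @param seed integer seed (NULL uses the current RNG stream).
#' @return list of class `bootstrap_ks`: `D`, `p`, `k`, `n_reps`, and the
#'   two mean distributions.
#' @export
bootstrap_centrality_ks <- function(values_a, values_b, k = 50,
                                    n_reps = 10000, seed = NULL) {
  stopifnot(length(values_a) >= 1L, length(values_b) >= 1L)
  with_seed(seed, {
    ma <- colMeans(matrix(sample(values_a, k * n_reps, replace = TRUE), k))
    mb <- colMeans(matrix(sample(values_b, k * n_reps, replace = TRUE), k))
    ks <- suppressWarnings(stats::ks.test(ma, mb, exact = FALSE))
    structure(list(D = unname(ks$statistic), p = unname(ks$p.value),
                   k = k, n_reps = n_reps,
                   means_a = ma, means_b = mb),
              class = "bootstrap_ks")
  })
}

#' @export
print.bootstrap_ks <- function(x, ...) {
  cat(sprintf("bootstrap mean-centrality KS: D = %.3f, p = %.3g (k = %d, reps = %d)\n",
              x$D, x$p, x$k, x$n_reps))
  invisible(x)
}
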