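# Independent brute-force oracles and small fixture builders, kept free of
# the package's own computational paths.

# Weighted UniFrac by explicit enumeration: walk from every tip to the root
# accumulating per-edge descendant abundance, branch by branch.
unifrac_bruteforce <- function(counts, tree, normalized = TRUE) {
  rel <- sweep(counts, 2, colSums(counts), "/")
  n <- ncol(counts)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  # per-edge descendant proportion accumulated along each tip's root path
  P <- matrix(0, nrow(tree$edge), n)
  for (tip in seq_len(ntip)) {
    ab <- rel[match(tree$tip.label[tip], rownames(counts)), ]
    if (all(is.na(ab))) next
    node <- tip
    while (node != root) {
      k <- which(tree$edge[, 2] == node)
      P[k, ] <- P[k, ] + ab
      node <- tree$edge[k, 1]
    }
  }
  dm <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- sum(tree$edge.length * abs(P[, i] - P[, j]))
    if (normalized) {
      den <- sum(tree$edge.length * (P[, i] + P[, j]))
      num <- if (den > 0) num / den else 0
    }
    dm[i, j] <- num
  }
  dm
}

# Faith's PD by explicit union of root paths of the present tips.
pd_bruteforce <- function(present_tips, tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  edges <- integer(0)
  for (tip in match(present_tips, tree$tip.label)) {
    node <- tip
    while (node != root) {
      k <- which(tree$edge[, 2] == node)
      edges <- union(edges, k)
      node <- tree$edge[k, 1]
    }
  }
  sum(tree$edge.length[edges])
}

# Betweenness by exhaustive path enumeration over all simple paths, for
# graphs small enough to enumerate (<= 8 nodes). Unordered pairs counted
# once, endpoints excluded, shortest-path ties averaged.
betweenness_bruteforce <- function(nodes, edges) {
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (e in seq_len(nrow(edges))) {
    adj[edges$from[e], edges$to[e]] <- TRUE
    adj[edges$to[e], edges$from[e]] <- TRUE
  }
  all_paths <- function(from, to, visited) {
    if (from == to) return(list(visited))
    out <- list()
    for (nxt in nodes[adj[from, ]]) {
      if (nxt %in% visited) next
      out <- c(out, all_paths(nxt, to, c(visited, nxt)))
    }
    out
  }
  btw <- setNames(numeric(length(nodes)), nodes)
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    paths <- all_paths(nodes[i], nodes[j], nodes[i])
    if (!length(paths)) next
    lens <- vapply(paths, length, integer(1))
    shortest <- paths[lens == min(lens)]
    for (p in shortest) {
      interior <- setdiff(p, c(nodes[i], nodes[j]))
      btw[interior] <- btw[interior] + 1 / length(shortest)
    }
  }
  btw
}

# Two-sample KS D by exhaustive ECDF gap scan over all sample points.
ks_bruteforce <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(vapply(pts, function(x) abs(mean(a <= x) - mean(b <= x)), numeric(1)))
}

# tiny 4-tip fixture tree used across files
fixture_tree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# random feature table over the tips of `tree`
random_table <- function(tree, n_samples, max_count = 50) {
  nt <- length(tree$tip.label)
  m <- matrix(sample.int(max_count, nt * n_samples, replace = TRUE) - 1L,
              nt, n_samples,
              dimnames = list(tree$tip.label,
                              paste0("S", seq_len(n_samples))))
  # guarantee positive sample totals
  m[1, colSums(m) == 0] <- 1L
  storage.mode(m) <- "double"
  m
}

# random labelled distance matrix from points in the plane
random_euclidean_dm <- function(n) {
  pts <- matrix(stats::rnorm(2 * n), n)
  dm <- as.matrix(stats::dist(pts))
  dimnames(dm) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  dm
}
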