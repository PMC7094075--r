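test_that("SparCC D=3 basis system is solved exactly in closed form", {
  TT <- matrix(2, 3, 3); diag(TT) <- 0
  incl <- matrix(TRUE, 3, 3)
  omega <- parasitome:::solve_basis_variances(TT, incl)
  expect_equal(omega, rep(1, 3))
  rho <- parasitome:::basis_correlations(TT, omega)
  expect_equal(rho[1, 2], 0)
  expect_equal(diag(rho), rep(1, 3))
  # asymmetric variation matrix: the solution still satisfies the linear
  # system t_i = (D-2) omega_i + sum(omega)
  TT2 <- matrix(c(0, 0.2, 2, 0.2, 0, 2, 2, 2, 0), 3, 3)
  om2 <- parasitome:::solve_basis_variances(TT2, incl)
  A <- matrix(1, 3, 3); diag(A) <- 2
  expect_equal(as.numeric(A %*% om2), rowSums(TT2))
  # under the sparsity approximation this T is attributed to variance of
  # feature 3, leaving the pair uncorrelated: omega = (0.1, 0.1, 1.9)
  expect_equal(om2, c(0.1, 0.1, 1.9))
  rho2 <- parasitome:::basis_correlations(TT2, om2)
  expect_equal(rho2[1, 2], 0)
})

test_that("SparCC output is symmetric, unit-diagonal, deterministic, near zero under independence", {
  counts <- simulate_null_counts(20, 150, seed = 200)
  rho <- sparcc_correlations(counts, seed = 1)
  expect_equal(rho, t(rho), ignore_attr = TRUE)
  expect_equal(unname(diag(rho)), rep(1, 20))
  expect_true(all(abs(rho) <= 1 + 1e-12))
  off <- rho[upper.tri(rho)]
  expect_lt(max(abs(off)), 0.35)
  rho2 <- sparcc_correlations(counts, seed = 1)
  expect_identical(rho, rho2)
})

test_that("SparCC recovers a strong planted association and is compositionally invariant", {
  set.seed(210)
  n <- 200; D <- 32
  z <- matrix(rnorm(D * n), D)
  z[2, ] <- 0.9 * z[1, ] + sqrt(1 - 0.81) * rnorm(n)
  counts <- sapply(seq_len(n), function(j) {
    pr <- exp(z[, j]); pr <- pr / sum(pr)
    rmultinom(1, 20000, pr)[, 1]
  })
  dimnames(counts) <- list(paste0("f", 1:D), paste0("s", 1:n))
  rho <- sparcc_correlations(counts, seed = 3)
  expect_gte(rho["f1", "f2"], 0.6)
  expect_lte(rho["f1", "f2"], 1)
  # compositional invariance: per-sample rescaling leaves rho ~ unchanged
  scaled <- round(sweep(counts, 2, rep(c(1, 4), length.out = n), "*"))
  rho_s <- sparcc_correlations(scaled, seed = 3)
  expect_lt(max(abs(rho - rho_s), na.rm = TRUE), 0.1)
  expect_gte(rho_s["f1", "f2"], 0.6)
})

test_that("bootstrap pseudo-p-values hit the floor for stable edges and ~1 for null edges", {
  set.seed(220)
  n <- 60
  z1 <- rnorm(n)
  z <- rbind(z1, 0.95 * z1 + 0.1 * rnorm(n), matrix(rnorm(4 * n), 4))
  counts <- sapply(seq_len(n), function(j) {
    pr <- exp(z[, j]); pr <- pr / sum(pr)
    rmultinom(1, 5000, pr)[, 1]
  })
  dimnames(counts) <- list(paste0("f", 1:6), paste0("s", 1:n))
  p <- sparcc_pvalues(counts, n_bootstrap = 40, seed = 9)
  expect_equal(p["f1", "f2"], 1 / 40)        # never crosses zero
  null_ps <- p[upper.tri(p)][-1]
  expect_gt(mean(null_ps), 0.3)              # sign-symmetric bootstrap rho
  expect_identical(p, sparcc_pvalues(counts, n_bootstrap = 40, seed = 9))
  expect_warning(sparcc_pvalues(counts[, 1:10], n_bootstrap = 10, seed = 1),
                 "coarse")
})

test_that("edge thresholding is strict and monotone in both thresholds", {
  ids <- paste0("f", 1:4)
  rho <- matrix(0, 4, 4, dimnames = list(ids, ids)); diag(rho) <- 1
  p <- matrix(1, 4, 4, dimnames = list(ids, ids))
  rho["f1", "f2"] <- rho["f2", "f1"] <- 0.6    # exactly at threshold: excluded
  p["f1", "f2"] <- p["f2", "f1"] <- 0.001
  rho["f1", "f3"] <- rho["f3", "f1"] <- 0.95
  p["f1", "f3"] <- p["f3", "f1"] <- 0.01
  rho["f2", "f4"] <- rho["f4", "f2"] <- -0.8
  p["f2", "f4"] <- p["f4", "f2"] <- 0.04
  rho["f3", "f4"] <- rho["f4", "f3"] <- 0.9
  p["f3", "f4"] <- p["f4", "f3"] <- 0.05       # exactly at alpha: excluded
  net <- threshold_edges(rho, p)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(paste(net$edges$from, net$edges$to),
                  c("f1 f3", "f2 f4"))
  expect_equal(net$edges$sign[net$edges$from == "f2"], -1)
  expect_length(net$nodes, 4)                  # isolated nodes retained
  # monotonicity
  grid_corr <- c(0.3, 0.5, 0.7, 0.9)
  n_by_corr <- vapply(grid_corr, function(mc)
    nrow(threshold_edges(rho, p, min_abs_corr = mc)$edges), numeric(1))
  expect_true(all(diff(n_by_corr) <= 0))
  grid_alpha <- c(0.001, 0.02, 0.05, 0.5)
  n_by_alpha <- vapply(grid_alpha, function(a)
    nrow(threshold_edges(rho, p, alpha = a)$edges), numeric(1))
  expect_true(all(diff(n_by_alpha) >= 0))
})

test_that("network stats match hand enumeration and the path oracle", {
  path <- coassoc_network(c("A", "B", "C"),
                          data.frame(from = c("A", "B"), to = c("B", "C"),
                                     weight = c(0.7, -0.8)))
  s <- network_stats(path)
  expect_equal(unname(s$betweenness[c("A", "B", "C")]), c(0, 1, 0))
  expect_equal(s$edge_density, 2 / 3)
  expect_equal(unname(s$degree[c("A", "B", "C")]), c(1, 2, 1))

  star <- coassoc_network(c("hub", paste0("l", 1:4)),
                          data.frame(from = "hub", to = paste0("l", 1:4),
                                     weight = 1))
  ss <- network_stats(star)
  expect_equal(unname(ss$betweenness["hub"]), 6)   # C(4,2) pairs
  expect_equal(ss$betweenness_centralization, 1)

  ring <- coassoc_network(paste0("n", 1:5),
                          data.frame(from = paste0("n", 1:5),
                                     to = paste0("n", c(2:5, 1)), weight = 1))
  rs <- network_stats(ring)
  expect_true(all(rs$betweenness == rs$betweenness[1]))
  expect_equal(rs$betweenness_centralization, 0)
  expect_equal(sum(rs$degree), 2 * 5)
})

test_that("betweenness agrees with exhaustive path enumeration on random graphs", {
  set.seed(230)
  for (rep in 1:10) {
    nv <- sample(4:8, 1)
    ids <- paste0("v", seq_len(nv))
    pairs <- t(combn(ids, 2))
    sel <- runif(nrow(pairs)) < 0.45
    if (!any(sel)) next
    edges <- data.frame(from = pairs[sel, 1], to = pairs[sel, 2], weight = 1)
    net <- coassoc_network(ids, edges)
    got <- network_stats(net)$betweenness
    want <- betweenness_bruteforce(ids, edges)
    expect_equal(got[ids], want[ids], tolerance = 1e-9)
    expect_equal(sum(network_stats(net)$degree), 2 * nrow(edges))
  }
})

test_that("bootstrap KS comparison: identical, disjoint, and oracle-checked D", {
  same <- bootstrap_centrality_ks(c(1, 2, 3, 4), c(1, 2, 3, 4),
                                  k = 50, n_reps = 4000, seed = 5)
  expect_lt(same$D, 0.05)
  disjoint <- bootstrap_centrality_ks(rep(0, 7), rep(1, 9),
                                      k = 50, n_reps = 500, seed = 5)
  expect_equal(disjoint$D, 1)
  expect_lt(disjoint$p, 0.001)

  r <- bootstrap_centrality_ks(rexp(20), rexp(20) + 0.3,
                               k = 10, n_reps = 300, seed = 11)
  expect_equal(r$D, ks_bruteforce(r$means_a, r$means_b), tolerance = 1e-12)
  r2 <- bootstrap_centrality_ks(rexp(20), rexp(20) + 0.3,
                                k = 10, n_reps = 300, seed = 11)
  expect_identical(r$D, r2$D)
})

test_that("MB/StARS recovers a chain graph and is deterministic", {
  # stability selection on a 10-node graph is itself a stochastic procedure:
  # the recovery claim is about the typical dataset, so assert the median F1
  # over replicate draws
  D <- 10
  A <- cbind(1:(D - 1), 2:D)
  Om <- diag(D)
  for (e in seq_len(nrow(A)))
    Om[A[e, 1], A[e, 2]] <- Om[A[e, 2], A[e, 1]] <- -0.35
  L <- t(chol(solve(Om)))
  truth <- paste0("f", A[, 1], "-f", A[, 2])
  f1s <- vapply(1:5, function(s) {
    set.seed(240 + s)
    X <- L %*% matrix(rnorm(D * 200), D)
    rownames(X) <- paste0("f", 1:D)
    net <- mb_stars_network(X, seed = 9)
    got <- paste0(pmin(net$edges$from, net$edges$to), "-",
                  pmax(net$edges$from, net$edges$to))
    tp <- length(intersect(truth, got))
    prec <- tp / max(1, length(got)); rec <- tp / length(truth)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  expect_gte(median(f1s), 0.8)

  set.seed(241)
  X <- L %*% matrix(rnorm(D * 200), D)
  rownames(X) <- paste0("f", 1:D)
  net <- mb_stars_network(X, seed = 9)
  net2 <- mb_stars_network(X, seed = 9)
  expect_identical(net$edges, net2$edges)

  # empty precision graph: selected graph stays sparse
  X0 <- matrix(rnorm(12 * 150), 12, dimnames = list(paste0("g", 1:12), NULL))
  net0 <- mb_stars_network(X0, seed = 13)
  dens0 <- nrow(net0$edges) / choose(12, 2)
  expect_lt(dens0, 0.08)

  # constant features are dropped with a warning
  Xc <- rbind(X, const = rep(1, 200))
  expect_warning(mb_stars_network(Xc, seed = 9), "constant")
})
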