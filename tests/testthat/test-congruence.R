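test_that("t0 is 1 for similarity transforms and symmetric in its arguments", {
  set.seed(91)
  X <- matrix(rnorm(24), 12, 2)
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  Y <- 3.7 * X %*% R + 5
  f <- procrustes_fit(X, Y)
  expect_equal(f$t0, 1, tolerance = 1e-10)
  expect_equal(f$m12_squared, 0, tolerance = 1e-10)

  # pure scaling of a 3-point configuration
  X3 <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(procrustes_fit(X3, 2 * X3)$t0, 1, tolerance = 1e-12)

  # symmetry and invariances
  Y2 <- matrix(rnorm(24), 12, 2)
  expect_equal(procrustes_fit(X, Y2)$t0, procrustes_fit(Y2, X)$t0,
               tolerance = 1e-10)
  refl <- Y2 %*% diag(c(-1, 1))
  expect_equal(procrustes_fit(X, refl)$t0, procrustes_fit(X, Y2)$t0,
               tolerance = 1e-10)
  expect_equal(procrustes_fit(X, 0.1 * Y2 + 3)$t0,
               procrustes_fit(X, Y2)$t0, tolerance = 1e-10)
  expect_error(procrustes_fit(X, Y2[1:11, ]), "matching dimensions")
  expect_error(procrustes_fit(X[, 1, drop = FALSE], Y2[, 1, drop = FALSE]),
               "2 axes")
})

test_that("t0 of randomly re-paired rows is near zero at large n", {
  set.seed(101)
  X <- matrix(rnorm(1000), 500, 2)
  ts <- vapply(1:50, function(i) procrustes_fit(X, X[sample(500), ])$t0,
               numeric(1))
  expect_lt(mean(ts), 0.15)
})

test_that("t0 agrees with vegan's protest statistic", {
  skip_if_not_installed("vegan")
  set.seed(111)
  X <- matrix(rnorm(24), 12, 2)
  Y <- matrix(rnorm(24), 12, 2)
  ours <- procrustes_fit(X, Y)
  theirs <- vegan::protest(X, Y, permutations = 19)
  expect_equal(ours$t0, theirs$t0, tolerance = 1e-10)
  expect_equal(ours$m12_squared, theirs$ss, tolerance = 1e-10)
})

test_that("protest permutation p is deterministic, minimal under identity, calibrated", {
  set.seed(121)
  X <- matrix(rnorm(24), 12, 2)
  Y <- X %*% matrix(c(0, 1, -1, 0), 2) * 2
  p1 <- protest_fit(X, Y, 999, seed = 7)
  p2 <- protest_fit(X, Y, 999, seed = 7)
  expect_identical(p1$permutation_p, p2$permutation_p)
  expect_equal(p1$permutation_p, (sum(p1$t_permuted >= 1 - 1e-10) + 1) / 1000)
  expect_lt(p1$permutation_p, 0.05)

  # p never zero, bounded by the (+1)/(n+1) convention
  expect_gte(p1$permutation_p, 1 / 1000)

  # super-uniformity under an exchangeable null (independent Gaussian sets)
  set.seed(131)
  ps <- vapply(1:200, function(i) {
    A <- matrix(rnorm(24), 12, 2); B <- matrix(rnorm(24), 12, 2)
    protest_fit(A, B, 99)$permutation_p
  }, numeric(1))
  rate <- mean(ps <= 0.05)
  expect_lt(rate, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 200))
})

test_that("leave-one-out: absent clades give exactly zero delta-t and bounds hold", {
  d <- simulate_paired_communities(sim_params(n_taxa = 40, seed = 17,
                                              community_types = c("PR", "IIR")))
  b <- d$bundle
  m <- match_specimens(b$metadata, "PR", "IIR")
  hb <- subset_bundle(b, samples = m$b)
  hsc <- ordination_scores(pcoa(weighted_unifrac(hb$counts, hb$tree)), 2)
  pb <- subset_bundle(b, samples = m$a)
  # plant a clade with zero abundance in all parasite samples
  pb$counts[pb$taxonomy$order == pb$taxonomy$order[1], ] <- 0
  pb$counts[which(pb$taxonomy$order != pb$taxonomy$order[1])[1], ] <-
    pb$counts[which(pb$taxonomy$order != pb$taxonomy$order[1])[1], ] + 1
  rec <- leave_one_out(pb, hsc, rank = "order")
  zero_clade <- rec[rec$clade == pb$taxonomy$order[1], ]
  expect_false(zero_clade$flagged)
  expect_identical(zero_clade$delta_t, 0)
  t0 <- attr(rec, "t0_baseline")
  ok <- rec[!rec$flagged, ]
  expect_true(all(ok$delta_t >= -t0 - 1e-9))
  expect_true(all(ok$delta_t <= 1 - t0 + 1e-9))
  expect_true(all(ok$t_excluded >= 0 & ok$t_excluded <= 1))
})

test_that("leave-one-out skips clades whose exclusion empties a sample and ignores unassigned", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  counts <- cbind(s1 = c(A = 5, B = 0, C = 9, D = 1),
                  s2 = c(A = 0, B = 6, C = 2, D = 8),
                  s3 = c(A = 4, B = 4, C = 0, D = 0))
  tax <- data.frame(feature_id = c("A", "B", "C", "D"),
                    phylum = c("P1", "P1", "P2", "unassigned"),
                    class = "c", order = "o", family = "f", genus = "g",
                    row.names = c("A", "B", "C", "D"))
  meta <- data.frame(sample_id = colnames(counts), species = "parasite",
                     organ = "root", community_type = "PR", site_id = "s",
                     specimen_id = paste0("sp", 1:3))
  pb <- analysis_bundle(counts, tr, tax, meta)
  hsc <- matrix(rnorm(6), 3, 2, dimnames = list(colnames(counts), NULL))
  rec <- leave_one_out(pb, hsc, rank = "phylum")
  expect_setequal(rec$clade, c("P1", "P2"))      # unassigned never a clade
  expect_true(rec$flagged[rec$clade == "P1"])    # s3 would be emptied
  expect_false(rec$flagged[rec$clade == "P2"])
  expect_error(leave_one_out(pb, hsc, rank = "superkingdom"), "rank")
})

test_that("drill-down targets orders of the top phyla and finds a planted driver", {
  d <- simulate_paired_communities(
    sim_params(kappa = 1, background_loading = 0, taxon_sd = 1, seed = 23,
               community_types = c("PR", "IIR")))
  b <- d$bundle
  m <- match_specimens(b$metadata, "PR", "IIR")
  hb <- subset_bundle(b, samples = m$b)
  hsc <- ordination_scores(pcoa(weighted_unifrac(hb$counts, hb$tree)), 2)
  pb <- subset_bundle(b, samples = m$a)
  phy <- leave_one_out(pb, hsc, rank = "phylum")
  expect_identical(phy$clade[which.min(phy$delta_t)], d$truth$driver_phylum)

  drl <- drill_down(phy, pb, hsc, top_k = 1)
  tax <- pb$taxonomy
  expect_true(all(tax$phylum[match(drl$clade, tax$order)] ==
                    phy$clade[which.max(abs(phy$delta_t))]))
  ok <- drl[!drl$flagged, ]
  expect_identical(ok$clade[which.min(ok$delta_t)], d$truth$driver_clade)

  expect_equal(nrow(drill_down(phy, pb, hsc, top_k = 0)), 0)
})

test_that("specimen matching pairs shared specimens and falls back to site order", {
  d <- simulate_paired_communities(sim_params(n_taxa = 20, seed = 29))
  meta <- d$bundle$metadata
  m <- match_specimens(meta, "PR", "IIR")
  expect_identical(meta[m$a, "specimen_id"], meta[m$b, "specimen_id"])
  expect_length(m$a, 12)
  # PR and UR never share specimens: positional fallback within site
  m2 <- match_specimens(meta, "PR", "UR")
  expect_length(m2$a, 12)
  expect_identical(meta[m2$a, "site_id"], meta[m2$b, "site_id"])
})
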