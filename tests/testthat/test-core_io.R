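test_that("feature table validation names the offending cell and ids", {
  m <- matrix(c(1, 2, 3, 4), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_silent(validate_feature_table(m))
  bad <- m; bad["b", "s2"] <- 2.5
  expect_error(validate_feature_table(bad), "b, s2")
  dup <- m; rownames(dup) <- c("a", "a")
  expect_error(validate_feature_table(dup), "duplicate feature ids")
  neg <- m; neg[1, 1] <- -1
  expect_error(validate_feature_table(neg), "non-negative")
})

test_that("a bundle round-trips through write/read unchanged", {
  d <- simulate_paired_communities(sim_params(n_taxa = 24, seed = 11,
                                              community_types = c("PR", "IIR")))
  dir <- withr::local_tempdir()
  write_bundle(d$bundle, dir)
  b2 <- read_bundle(file.path(dir, "table.tsv"), file.path(dir, "tree.nwk"),
                    file.path(dir, "taxonomy.tsv"),
                    file.path(dir, "metadata.tsv"))
  expect_equal(b2$counts, d$bundle$counts)
  expect_identical(rownames(b2$taxonomy), rownames(d$bundle$taxonomy))
  expect_equal(b2$taxonomy$order, d$bundle$taxonomy$order)
  expect_identical(b2$metadata$community_type, d$bundle$metadata$community_type)
  # branch lengths survive to high precision
  t1 <- d$bundle$tree; t2 <- ape::keep.tip(b2$tree, t1$tip.label)
  expect_lt(max(abs(sort(t1$edge.length) - sort(t2$edge.length))), 1e-9)
})

test_that("features missing from tree or taxonomy are dropped deterministically", {
  tr <- fixture_tree()
  counts <- rbind(random_table(tr, 3),
                  Z = c(5, 5, 5))
  tax <- data.frame(feature_id = rownames(counts), phylum = "P1",
                    class = "C1", order = "O1", family = "F1", genus = "G1",
                    row.names = rownames(counts))
  meta <- data.frame(sample_id = colnames(counts), species = "host",
                     organ = "root", community_type = "UR", site_id = "s1",
                     specimen_id = paste0("sp", 1:3))
  msgs <- capture_messages(b <- analysis_bundle(counts, tr, tax, meta))
  expect_match(paste(msgs, collapse = ""), "dropped 1")
  expect_identical(rownames(b$counts), tr$tip.label[match(rownames(b$counts), tr$tip.label)])
  expect_false("Z" %in% rownames(b$counts))
  expect_identical(b$dropped_features, "Z")
  # identical rerun gives identical order and messages
  msgs2 <- capture_messages(b2 <- analysis_bundle(counts, tr, tax, meta))
  expect_identical(msgs, msgs2)
  expect_identical(rownames(b$counts), rownames(b2$counts))
})

test_that("metadata validation cross-checks community type against species x organ", {
  meta <- data.frame(sample_id = "x1", species = "host", organ = "leaf",
                     community_type = "PR", site_id = "s1", specimen_id = "sp1")
  expect_error(validate_metadata(meta), "inconsistent")
  meta$community_type <- "IL"
  expect_silent(validate_metadata(meta))
  meta$community_type <- "XX"
  expect_error(validate_metadata(meta), "unknown community types")
})

test_that("distance matrices round-trip losslessly and reject bad input", {
  dm <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  path <- withr::local_tempfile()
  write_distance_matrix(dm, path)
  expect_equal(read_distance_matrix(path), dm)

  set.seed(5)
  dm5 <- random_euclidean_dm(5)
  write_distance_matrix(dm5, path)
  expect_lt(max(abs(read_distance_matrix(path) - dm5)), 1e-12)

  expect_error(write_distance_matrix(matrix(numeric(0), 0, 0), path))
  asym <- dm5; asym[1, 2] <- asym[1, 2] + 1
  expect_error(validate_distance_matrix(asym), "not symmetric")
})

test_that("networks round-trip via edge-TSV and GraphML", {
  path <- withr::local_tempfile()
  empty <- coassoc_network(c("a", "b"), data.frame())
  write_network(empty, path, "edge-tsv")
  expect_identical(readLines(path), "from\tto\tweight\tsign")

  set.seed(9)
  ids <- paste0("n", 1:20)
  pairs <- t(combn(ids, 2))
  sel <- sample(nrow(pairs), 25)
  edges <- data.frame(from = pairs[sel, 1], to = pairs[sel, 2],
                      weight = round(runif(25, -1, 1), 6))
  net <- coassoc_network(ids, edges)
  for (fmt in c("edge-tsv", "graphml")) {
    write_network(net, path, fmt)
    back <- read_network(path, fmt, nodes = ids)
    g1 <- as_igraph(net); g2 <- as_igraph(back)
    expect_true(igraph::isomorphic(g1, g2))
    key <- function(e) {
      o <- order(pmin(e$from, e$to), pmax(e$from, e$to))
      e[o, c("from", "to", "weight")]
    }
    k1 <- key(net$edges); k2 <- key(back$edges)
    expect_equal(sort(k1$weight), sort(k2$weight), tolerance = 1e-9)
  }
  expect_error(write_network(net, path, "dot"))
})
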