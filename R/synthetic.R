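# Synthetic paired host/parasite microbiome datasets with known congruence
# strength (kappa), a planted driver clade, and an optional planted
# co-association graph, so every pipeline stage can be checked against
# ground truth. The sampling design mirrors a paired-patch field survey:
# 4 sites x 3 replicate specimens per community type, 7 plant community
# types (PL, PR, IL, IIR, IUR, UL, UR) plus soil.

PLANT_TYPES <- c("PL", "PR", "IL", "IIR", "IUR", "UL", "UR")
PARASITE_TYPES <- c("PL", "PR")
HOST_ROOT_TYPES <- c("IIR", "IUR", "UR")

#' Simulation parameters for paired host/parasite communities
#'
#' Defaults encode the emulated survey design: 4 sites x 3 replicate
#' specimens (12 samples per community type), the 7 plant community types
#' plus soil, sparse overdispersed counts with log-normal library sizes, and
#' a host-parasite shared-signal strength kappa in [0, 1] concentrated on a
#' planted driver clade (a pseudo-order).
#'
#' @param n_taxa number of features (default 120).
#' @param n_sites number of sites (default 4).
#' @param reps_per_site replicate specimens per site (default 3).
#' @param community_types community types to simulate (default all 7 plant
#'   types plus SOIL).
#' @param kappa host-parasite congruence strength in [0, 1] (default 0.5).
#' @param driver_clade_fraction approximate fraction of taxa in the driver
#'   clade (default 0.15); the pseudo-order closest to this size is chosen.
#' @param n_phyla,orders_per_phylum taxonomy shape (defaults 4 and 3).
#' @param library_size_log_mean,library_size_log_sd log-normal library-size
#'   parameters (defaults log(20000) and 0.5).
#' @param taxon_sd spread of the shared mean log-abundance profile across
#'   taxa (default 2, giving the strong rank-abundance skew and sample
#'   sparsity typical of amplicon surveys).
#' @param type_sd spread of the per-community-type composition offset
#'   (default 0.5; types are distinct but share the global abundance
#'   profile, as homologous organs of co-occurring plants do).
#' @param signal_sd scale of the shared site/specimen signal (default 1.5).
#' @param specimen_weight weight of the specimen-level signal relative to
#'   the site-level signal (default 0.5; congruence in the emulated survey
#'   is primarily a cross-site pattern).
#' @param noise_sd residual per-taxon, per-sample noise (default 0.3).
#' @param overdispersion extra latent heavy-tail noise (default 0.2).
#' @param background_loading loading of the shared signal outside the driver
#'   clade (default 0.2).
#' @param true_graph NULL, "chain", list(type = "erdos", p = ...), or a
#'   two-column edge matrix of feature indices: planted residual
#'   co-association structure.
#' @param graph_strength partial-association strength of planted edges
#'   (default 0.35).
#' @param seed integer seed.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_taxa = 120, n_sites = 4, reps_per_site = 3,
                       community_types = c(PLANT_TYPES, "SOIL"),
                       kappa = 0.5, driver_clade_fraction = 0.15,
                       n_phyla = 4, orders_per_phylum = 3,
                       library_size_log_mean = log(20000),
                       library_size_log_sd = 0.5, taxon_sd = 2,
                       type_sd = 0.5,
                       signal_sd = 1.5, specimen_weight = 0.5,
                       noise_sd = 0.3, overdispersion = 0.2,
                       background_loading = 0.2, true_graph = NULL,
                       graph_strength = 0.35, seed = 1L) {
  stopifnot(kappa >= 0, kappa <= 1, n_taxa >= n_phyla * orders_per_phylum)
  structure(as.list(environment()), class = "sim_params")
}

#' Simulate a random tree with a nested clade taxonomy
#'
#' Builds a rooted tree by nesting random bifurcating order subtrees inside
#' phylum clades, with exponential branch lengths, so every pseudo-phylum
#' and pseudo-order is monophyletic by construction. Taxonomy ranks below
#' order (family, genus) are finer splits of each order.
#'
#' @param n_taxa number of tips.
#' @param n_phyla number of phylum clades (default 4).
#' @param orders_per_phylum orders per phylum (default 3).
#' @param seed integer seed (NULL uses the current RNG stream).
#' @return list with `tree` (`phylo`) and `taxonomy` (data.frame).
#' @export
simulate_tree_taxonomy <- function(n_taxa, n_phyla = 4, orders_per_phylum = 3,
                                   seed = NULL) {
  if (n_taxa < n_phyla * orders_per_phylum)
    stop("n_taxa must be at least n_phyla * orders_per_phylum")
  with_seed(seed, {
    ids <- sprintf("ASV%04d", seq_len(n_taxa))
    phylum_sizes <- even_partition(n_taxa, n_phyla)
    tax_rows <- list()
    phylum_newicks <- character(n_phyla)
    cursor <- 0L
    for (ph in seq_len(n_phyla)) {
      order_sizes <- even_partition(phylum_sizes[ph], orders_per_phylum)
      order_newicks <- character(orders_per_phylum)
      for (od in seq_len(orders_per_phylum)) {
        tips <- ids[cursor + seq_len(order_sizes[od])]
        cursor <- cursor + order_sizes[od]
        order_newicks[od] <- subtree_newick(tips)
        fam_split <- even_partition(length(tips), min(2L, length(tips)))
        fam <- rep(seq_along(fam_split), fam_split)
        tax_rows[[length(tax_rows) + 1L]] <- data.frame(
          feature_id = tips,
          phylum = sprintf("Phylum%02d", ph),
          class = sprintf("Class%02d", ph),
          order = sprintf("Order%02d_%02d", ph, od),
          family = sprintf("Family%02d_%02d_%d", ph, od, fam),
          genus = sprintf("Genus%02d_%02d_%d", ph, od, fam),
          stringsAsFactors = FALSE)
      }
      phylum_newicks[ph] <- sprintf("(%s):%.6f",
                                    paste(order_newicks, collapse = ","),
                                    stats::rexp(1, rate = 2))
    }
    nwk <- sprintf("(%s):0;", paste(phylum_newicks, collapse = ","))
    tree <- ape::read.tree(text = nwk)
    taxonomy <- do.call(rbind, tax_rows)
    rownames(taxonomy) <- taxonomy$feature_id
    list(tree = tree, taxonomy = taxonomy)
  })
}

# split n into k near-equal positive parts
even_partition <- function(n, k) {
  base <- n %/% k
  sizes <- rep(base, k)
  extra <- n - base * k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

# random bifurcating newick over the given tips, exponential branch lengths
subtree_newick <- function(tips) {
  nodes <- sprintf("%s:%.6f", tips, stats::rexp(length(tips), rate = 2))
  while (length(nodes) > 1L) {
    pick <- sample.int(length(nodes), 2L)
    merged <- sprintf("(%s,%s):%.6f", nodes[pick[1L]], nodes[pick[2L]],
                      stats::rexp(1, rate = 2))
    nodes <- c(nodes[-pick], merged)
  }
  nodes
}

#' Simulate a paired host/parasite microbiome dataset
#'
#' Latent per-sample log-abundances are the sum of a community-type
#' baseline, a shared site/specimen signal weighted by a clade loading
#' (loading 1 on the planted driver clade, `background_loading` elsewhere),
#' and Gaussian noise; counts are multinomial draws with log-normal library
#' sizes. Host-root samples carry the site/specimen signal at full strength;
#' parasite samples carry kappa times the same signal plus
#' sqrt(1 - kappa^2) times an independent one, so kappa tunes the
#' host-parasite congruence from none (0) to perfect sharing (1). When
#' `true_graph` is set, residual latent covariance follows the graph's
#' precision structure. All ground truth is recorded.
#'
#' @param params a [sim_params()] list.
#' @return list of class `synthetic_dataset` with elements `bundle` (an
#'   `analysis_bundle`) and `truth` (kappa, driver clade/phylum, driver
#'   feature ids, true graph edges, parameters).
#' @export
simulate_paired_communities <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  with_seed(p$seed, {
    tt <- simulate_tree_taxonomy(p$n_taxa, p$n_phyla, p$orders_per_phylum,
                                 seed = NULL)
    tax <- tt$taxonomy
    ids <- tax$feature_id
    D <- p$n_taxa

    # driver clade: the pseudo-order closest to the requested fraction
    ord_sizes <- table(tax$order)
    target <- p$driver_clade_fraction * D
    driver <- names(ord_sizes)[which.min(abs(ord_sizes - target))]
    driver_idx <- which(tax$order == driver)
    loading <- rep(p$background_loading, D)
    loading[driver_idx] <- 1

    # planted residual covariance from the true graph, if any
    graph_edges <- resolve_true_graph(p$true_graph, D, p$n_taxa)
    chol_sigma <- NULL
    if (!is.null(graph_edges) && nrow(graph_edges)) {
      Om <- diag(D)
      for (e in seq_len(nrow(graph_edges))) {
        i <- graph_edges[e, 1L]; j <- graph_edges[e, 2L]
        Om[i, j] <- Om[j, i] <- -p$graph_strength
      }
      lam <- min(eigen(Om, symmetric = TRUE, only.values = TRUE)$values)
      if (lam < 0.05) Om <- Om + diag(0.05 - lam, D)
      chol_sigma <- chol(solve(Om))
    }

    base <- stats::rnorm(D, 0, p$taxon_sd)
    type_effect <- sapply(p$community_types,
                          function(ct) stats::rnorm(D, 0, p$type_sd))

    # shared latent signals: one per site and per infected-patch specimen
    # (host stream), plus independent parasite streams
    site_host <- matrix(stats::rnorm(D * p$n_sites), D)
    n_spec <- p$n_sites * p$reps_per_site
    spec_host <- matrix(stats::rnorm(D * n_spec), D)
    # the parasite-specific component is specimen-idiosyncratic (no site
    # grouping of its own): a parasite community acquires site structure
    # only through the shared host path, and the kappa = 0 configuration
    # is fully exchangeable across specimens
    ind_sd <- sqrt(1 + p$specimen_weight^2)
    para_own <- sapply(PARASITE_TYPES, function(x)
      matrix(stats::rnorm(D * n_spec, 0, ind_sd), D), simplify = FALSE)
    site_other <- sapply(c("leaf", "soil", "uninf"), function(x)
      matrix(stats::rnorm(D * p$n_sites), D), simplify = FALSE)

    meta_rows <- list()
    count_cols <- list()
    for (ct in p$community_types) {
      for (s in seq_len(p$n_sites)) {
        for (r in seq_len(p$reps_per_site)) {
          q <- (s - 1L) * p$reps_per_site + r
          infected_patch <- ct %in% c("PL", "PR", "IL", "IIR", "IUR")
          specimen <- if (ct == "SOIL") sprintf("soil_s%d_r%d", s, r)
          else if (infected_patch) sprintf("inf_s%d_r%d", s, r)
          else sprintf("unf_s%d_r%d", s, r)
          host_signal <- p$signal_sd * loading *
            (site_host[, s] + p$specimen_weight * spec_host[, q])
          ind_signal <- if (ct %in% PARASITE_TYPES)
            p$signal_sd * loading * para_own[[ct]][, q] else 0
          eta <- base + type_effect[, ct]
          if (ct %in% HOST_ROOT_TYPES) {
            eta <- eta + host_signal
          } else if (ct %in% PARASITE_TYPES) {
            eta <- eta + p$kappa * host_signal +
              sqrt(1 - p$kappa^2) * ind_signal
          } else if (ct == "SOIL") {
            eta <- eta + p$signal_sd * loading * site_other$soil[, s]
          } else { # host leaves
            eta <- eta + p$signal_sd * loading * site_other$leaf[, s]
          }
          res <- stats::rnorm(D, 0, p$noise_sd) +
            stats::rnorm(D, 0, p$overdispersion)
          if (!is.null(chol_sigma))
            res <- res + as.numeric(crossprod(chol_sigma, stats::rnorm(D))) *
              p$noise_sd
          eta <- eta + res
          pr <- exp(eta - max(eta)); pr <- pr / sum(pr)
          N <- round(stats::rlnorm(1, p$library_size_log_mean,
                                   p$library_size_log_sd))
          counts <- stats::rmultinom(1, max(N, 1), pr)[, 1L]
          sid <- sprintf("%s_s%d_r%d", ct, s, r)
          count_cols[[sid]] <- counts
          meta_rows[[sid]] <- data.frame(
            sample_id = sid,
            species = COMMUNITY_TYPES$species[COMMUNITY_TYPES$community_type == ct],
            organ = COMMUNITY_TYPES$organ[COMMUNITY_TYPES$community_type == ct],
            community_type = ct, site_id = sprintf("site%d", s),
            specimen_id = specimen, stringsAsFactors = FALSE)
        }
      }
    }
    counts <- do.call(cbind, count_cols)
    rownames(counts) <- ids
    metadata <- do.call(rbind, meta_rows)
    metadata$total_usable_reads <- colSums(counts)[metadata$sample_id]
    bundle <- suppressMessages(
      analysis_bundle(counts, tt$tree, tax, metadata))
    truth <- list(kappa = p$kappa, driver_clade = driver,
                  driver_phylum = tax$phylum[driver_idx[1L]],
                  driver_features = ids[driver_idx],
                  true_edges = if (is.null(graph_edges)) NULL else
                    cbind(ids[graph_edges[, 1L]], ids[graph_edges[, 2L]]),
                  params = p)
    structure(list(bundle = bundle, truth = truth),
              class = "synthetic_dataset")
  })
}

resolve_true_graph <- function(spec, D, n_taxa) {
  if (is.null(spec)) return(NULL)
  if (is.matrix(spec)) return(spec)
  if (identical(spec, "chain"))
    return(cbind(seq_len(D - 1L), seq_len(D - 1L) + 1L))
  if (is.list(spec) && identical(spec$type, "erdos")) {
    pairs <- which(upper.tri(matrix(0, D, D)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < spec$p
    return(pairs[keep, , drop = FALSE])
  }
  if (is.list(spec) && identical(spec$type, "chain"))
    return(cbind(seq_len(D - 1L), seq_len(D - 1L) + 1L))
  stop("unknown true_graph specification")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset: kappa =", x$truth$kappa,
      "driver =", x$truth$driver_clade, "\n")
  print(x$bundle)
  invisible(x)
}

#' Simulate a null feature table with no true co-associations
#'
#' Independent log-normal latent abundances per feature and sample, turned
#' into counts by multinomial draws with log-normal library sizes. Used to
#' measure false-edge rates of network inference.
#'
#' @param n_taxa,n_samples table dimensions (each >= 2).
#' @param seed integer seed (NULL uses the current RNG stream).
#' @param library_size_log_mean,library_size_log_sd library-size model
#'   (defaults log(20000), 0.5).
#' @param taxon_sd spread of mean log-abundances across taxa (default 1).
#' @param sample_sd within-taxon log-abundance noise (default 1).
#' @return feature table matrix.
#' @export
simulate_null_counts <- function(n_taxa, n_samples, seed = NULL,
                                 library_size_log_mean = log(20000),
                                 library_size_log_sd = 0.5,
                                 taxon_sd = 1, sample_sd = 1) {
  stopifnot(n_taxa >= 2, n_samples >= 2)
  with_seed(seed, {
    a <- stats::rnorm(n_taxa, 0, taxon_sd)
    eta <- a + matrix(stats::rnorm(n_taxa * n_samples, 0, sample_sd), n_taxa)
    counts <- sapply(seq_len(n_samples), function(j) {
      pr <- exp(eta[, j] - max(eta[, j])); pr <- pr / sum(pr)
      N <- max(1, round(stats::rlnorm(1, library_size_log_mean,
                                      library_size_log_sd)))
      stats::rmultinom(1, N, pr)[, 1L]
    })
    dimnames(counts) <- list(sprintf("ASV%04d", seq_len(n_taxa)),
                             sprintf("S%03d", seq_len(n_samples)))
    counts
  })
}
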