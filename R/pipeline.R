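# End-to-end orchestration: filter -> normalize -> alpha diversity ->
# weighted UniFrac / PCoA -> Procrustes congruence grid -> leave-one-out
# attribution -> per-community networks -> bootstrap-KS comparisons.

#' Study analysis configuration
#'
#' Every threshold used anywhere in the pipeline appears here explicitly;
#' the shipped defaults are the standard thresholds of the emulated survey
#' protocol (5-sample/25-read prevalence filter, 10-read/50% per-community
#' node filter, |rho| > 0.6 and p < 0.05 edge rule, 999 Procrustes
#' permutations, 100 SparCC bootstraps, 50-node/10000-rep KS resampling).
#'
#' @param min_samples,min_reads prevalence filter thresholds.
#' @param rarefy_depth optional rarefaction depth (NULL = none).
#' @param node_min_reads,node_min_frac per-community network node filter.
#' @param edge_min_abs_corr,edge_alpha SparCC edge thresholds.
#' @param sparcc_bootstraps SparCC pseudo-p bootstrap count.
#' @param n_permutations Procrustes permutations.
#' @param procrustes_axes leading PCoA axes matched (default 2).
#' @param procrustes_pairs list of c(type_a, type_b) community-type pairs
#'   for the congruence grid (NULL = all pairs of plant types present).
#' @param loo_pairs list of c(parasite_type, host_type) pairs for the
#'   leave-one-out attribution (default PR:IIR and PL:IIR).
#' @param loo_top_k phyla drilled into at order rank.
#' @param network_method "sparcc" or "mb".
#' @param network_types community types to build networks for (NULL = all
#'   types with enough samples).
#' @param ks_stat "betweenness" or "degree".
#' @param ks_k,ks_reps bootstrap mean-centrality KS parameters.
#' @param seed master seed; stage sub-seeds are derived from it by name.
#' @return list of class `study_config`.
#' @export
study_config <- function(min_samples = 5, min_reads = 25, rarefy_depth = NULL,
                         node_min_reads = 10, node_min_frac = 0.5,
                         edge_min_abs_corr = 0.6, edge_alpha = 0.05,
                         sparcc_bootstraps = 100, n_permutations = 999,
                         procrustes_axes = 2, procrustes_pairs = NULL,
                         loo_pairs = list(c("PR", "IIR"), c("PL", "IIR")),
                         loo_top_k = 3, network_method = "sparcc",
                         network_types = NULL, ks_stat = "betweenness",
                         ks_k = 50, ks_reps = 10000, seed = 1L) {
  structure(as.list(environment()), class = "study_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full study analysis
#'
#' Applies the prevalence filter, computes alpha diversity, per-community
#' weighted UniFrac PCoAs, the Procrustes congruence grid with permutation
#' p-values (plus a Benjamini-Hochberg adjusted column as an extension),
#' leave-one-out clade attribution at phylum rank drilled down to orders,
#' per-community co-association networks with summary statistics, and
#' pairwise bootstrap-KS comparisons of node centrality. All stochastic
#' stages draw independent named sub-seeds from `config$seed`, so a rerun
#' with the same config is identical.
#'
#' @param bundle an `analysis_bundle` (real or synthetic).
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, report tables are written
#'   as TSV plus a JSON run manifest.
#' @return list of class `study_report`.
#' @export
run_study <- function(bundle, config = study_config(), out_dir = NULL) {
  stopifnot(inherits(bundle, "analysis_bundle"))
  cfg <- config
  meta <- bundle$metadata

  filtered <- stage("filter", {
    counts <- filter_prevalence(bundle$counts, cfg$min_samples, cfg$min_reads)
    if (nrow(counts) == 0L) stop("no features pass the prevalence filter")
    frac <- attr(counts, "retained_read_fraction")
    if (!is.null(cfg$rarefy_depth))
      counts <- rarefy_table(counts, cfg$rarefy_depth,
                             seed = derive_seed(cfg$seed, "rarefy"))
    counts <- counts[, colSums(counts) > 0, drop = FALSE]
    attr(counts, "retained_read_fraction") <- frac
    counts
  })
  retained_fraction <- attr(filtered, "retained_read_fraction")
  meta <- meta[colnames(filtered), , drop = FALSE]

  alpha <- stage("alpha_diversity",
                 alpha_diversity(filtered, bundle$tree))

  types <- sort(unique(meta$community_type))
  types_ok <- types[vapply(types, function(ct)
    sum(meta$community_type == ct) >= 3L, logical(1))]
  skipped <- setdiff(types, types_ok)
  for (ct in skipped)
    message("community type ", ct, " has < 3 samples; ordination skipped")

  ordinations <- stage("ordination", {
    out <- list()
    for (ct in types_ok) {
      ids <- meta$sample_id[meta$community_type == ct]
      dm <- weighted_unifrac(filtered[, ids, drop = FALSE], bundle$tree)
      out[[ct]] <- list(distance = dm, ordination = pcoa(dm))
    }
    out
  })

  pairs <- cfg$procrustes_pairs
  if (is.null(pairs)) {
    plant <- intersect(types_ok, c(PLANT_TYPES, "SOIL"))
    pairs <- utils::combn(plant, 2L, simplify = FALSE)
  }
  procrustes_grid <- stage("procrustes", {
    rows <- lapply(pairs, function(pr) {
      a <- pr[1L]; b <- pr[2L]
      if (!a %in% names(ordinations) || !b %in% names(ordinations))
        return(NULL)
      m <- match_specimens(meta, a, b)
      if (length(m$a) < 3L) return(NULL)
      sa <- ordination_scores(ordinations[[a]]$ordination,
                              cfg$procrustes_axes)[m$a, , drop = FALSE]
      sb <- ordination_scores(ordinations[[b]]$ordination,
                              cfg$procrustes_axes)[m$b, , drop = FALSE]
      fit <- protest_fit(sa, sb, cfg$n_permutations,
                         seed = derive_seed(cfg$seed,
                                            paste("protest", a, b)))
      data.frame(type_a = a, type_b = b, n = fit$n, t0 = fit$t0,
                 m12_squared = fit$m12_squared, p = fit$permutation_p,
                 stringsAsFactors = FALSE)
    })
    grid <- do.call(rbind, rows)
    if (!is.null(grid)) grid$p_adj_bh <- stats::p.adjust(grid$p, "BH")
    grid
  })

  loo <- stage("leave_one_out", {
    out <- list()
    for (pr in cfg$loo_pairs) {
      pt <- pr[1L]; ht <- pr[2L]
      if (!pt %in% names(ordinations) || !ht %in% names(ordinations)) next
      m <- match_specimens(meta, pt, ht)
      if (length(m$a) < 3L) next
      pb <- subset_bundle(bundle, samples = m$a,
                          features = rownames(filtered))
      present <- rownames(pb$counts)[rowSums(pb$counts) > 0]
      pb <- subset_bundle(pb, features = present)
      host_scores <- ordination_scores(ordinations[[ht]]$ordination,
                                       cfg$procrustes_axes)[m$b, , drop = FALSE]
      phy <- leave_one_out(pb, host_scores, rank = "phylum",
                           axes = cfg$procrustes_axes)
      ords <- drill_down(phy, pb, host_scores, top_k = cfg$loo_top_k,
                         axes = cfg$procrustes_axes)
      out[[paste(pt, ht, sep = ":")]] <- list(phylum = phy, order = ords)
    }
    out
  })

  net_types <- cfg$network_types %||% types_ok
  networks <- stage("networks", {
    out <- list()
    for (ct in intersect(net_types, types_ok)) {
      ids <- meta$sample_id[meta$community_type == ct]
      sub <- filter_network_nodes(filtered[, ids, drop = FALSE],
                                  cfg$node_min_reads, cfg$node_min_frac)
      if (nrow(sub) < 3L) {
        message("community type ", ct,
                " has < 3 features after the node filter; network skipped")
        next
      }
      node_data <- data.frame(
        mean_clr = rowMeans(clr_transform(sub)),
        phylum = bundle$taxonomy[rownames(sub), "phylum"],
        row.names = rownames(sub), stringsAsFactors = FALSE)
      net <- if (identical(cfg$network_method, "mb")) {
        mb_stars_network(clr_transform(sub),
                         seed = derive_seed(cfg$seed, paste("mb", ct)),
                         node_data = node_data)
      } else {
        rho <- sparcc_correlations(sub,
                                   seed = derive_seed(cfg$seed,
                                                      paste("sparcc", ct)))
        pv <- sparcc_pvalues(sub, n_bootstrap = cfg$sparcc_bootstraps,
                             seed = derive_seed(cfg$seed,
                                                paste("sparccboot", ct)))
        threshold_edges(rho, pv, cfg$edge_min_abs_corr, cfg$edge_alpha,
                        node_data = node_data)
      }
      out[[ct]] <- list(network = net, stats = network_stats(net))
    }
    out
  })

  ks <- stage("network_comparison", {
    cts <- names(networks)
    rows <- list()
    if (length(cts) >= 2L) {
      for (pair in utils::combn(cts, 2L, simplify = FALSE)) {
        a <- pair[1L]; b <- pair[2L]
        va <- networks[[a]]$stats[[cfg$ks_stat]]
        vb <- networks[[b]]$stats[[cfg$ks_stat]]
        if (!length(va) || !length(vb)) next
        r <- bootstrap_centrality_ks(va, vb, k = cfg$ks_k,
                                     n_reps = cfg$ks_reps,
                                     seed = derive_seed(cfg$seed,
                                                        paste("ks", a, b)))
        rows[[paste(a, b)]] <- data.frame(type_a = a, type_b = b,
                                          statistic = cfg$ks_stat,
                                          D = r$D, p = r$p,
                                          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  manifest <- list(
    config = cfg[setdiff(names(cfg), "procrustes_pairs")],
    seed = cfg$seed,
    n_features_input = nrow(bundle$counts),
    n_features_filtered = nrow(filtered),
    retained_read_fraction = retained_fraction,
    community_types = types_ok, skipped_types = skipped)

  report <- structure(list(
    alpha = alpha, ordinations = ordinations,
    procrustes = procrustes_grid, leave_one_out = loo,
    networks = networks, ks_comparisons = ks,
    filtered_counts = filtered, manifest = manifest),
    class = "study_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report\n")
  cat("  features after filter:", nrow(x$filtered_counts),
      sprintf("(%.1f%% of reads)\n",
              100 * x$manifest$retained_read_fraction))
  cat("  community types:", paste(x$manifest$community_types, collapse = ", "),
      "\n")
  if (!is.null(x$procrustes)) {
    cat("  Procrustes grid:\n")
    print(x$procrustes[, c("type_a", "type_b", "t0", "p")], row.names = FALSE)
  }
  if (!is.null(x$ks_comparisons) && nrow(x$ks_comparisons)) {
    cat("  network KS comparisons:\n")
    print(x$ks_comparisons, row.names = FALSE)
  }
  invisible(x)
}

#' Write a study report to a directory
#'
#' Emits the alpha-diversity, distance, score, Procrustes, leave-one-out,
#' network and KS tables as TSV plus `manifest.json`.
#'
#' @param report a `study_report`.
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(report$alpha, "alpha_diversity.tsv")
  for (ct in names(report$ordinations)) {
    write_distance_matrix(report$ordinations[[ct]]$distance,
                          file.path(out_dir, paste0("unifrac_", ct, ".tsv")))
    sc <- report$ordinations[[ct]]$ordination$scores
    wt(data.frame(sample_id = rownames(sc), sc), paste0("pcoa_", ct, ".tsv"))
  }
  if (!is.null(report$procrustes)) wt(report$procrustes, "procrustes.tsv")
  for (nm in names(report$leave_one_out)) {
    safe <- gsub(":", "_vs_", nm)
    wt(report$leave_one_out[[nm]]$phylum, paste0("loo_phylum_", safe, ".tsv"))
    wt(report$leave_one_out[[nm]]$order, paste0("loo_order_", safe, ".tsv"))
  }
  for (ct in names(report$networks)) {
    write_network(report$networks[[ct]]$network,
                  file.path(out_dir, paste0("network_", ct, ".tsv")),
                  "edge-tsv")
    st <- report$networks[[ct]]$stats
    wt(data.frame(node = names(st$degree), degree = st$degree,
                  betweenness = st$betweenness),
       paste0("network_nodes_", ct, ".tsv"))
  }
  if (!is.null(report$ks_comparisons))
    wt(report$ks_comparisons, "ks_comparisons.tsv")
  jsonlite::write_json(report$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(out_dir)
}
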