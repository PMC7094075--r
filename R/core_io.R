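# Domain types, readers/writers and cross-validation of the four input
# artifacts: ASV count table (TSV), rooted phylogeny (newick), taxonomy (TSV)
# and sample metadata (TSV).

TAXONOMY_RANKS <- c("phylum", "class", "order", "family", "genus")

# community-type codes and the species x organ combination each implies
COMMUNITY_TYPES <- data.frame(
  community_type = c("PL", "PR", "IL", "IIR", "IUR", "UL", "UR", "SOIL"),
  species = c("parasite", "parasite", "host", "host", "host", "host", "host",
              "soil"),
  organ = c("leaf", "root", "leaf", "root", "root", "leaf", "root", "soil"),
  stringsAsFactors = FALSE
)

#' Validate a feature table
#'
#' A feature table is a non-negative integer matrix of read counts with
#' features (ASVs) as rows and samples as columns; row and column names must
#' be unique and non-empty.
#'
#' @param counts matrix to validate.
#' @return the matrix, invisibly, with storage mode integer-compatible.
#' @export
validate_feature_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("feature table must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("feature table must have feature row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(counts))
    stop(sprintf("counts must be non-negative integers; first offending cell [%s, %s] = %s",
                 rownames(counts)[i[1L]], colnames(counts)[i[2L]], counts[bad[1L]]))
  }
  invisible(counts)
}

#' Read a feature (ASV) count table from TSV
#'
#' Expects features as rows and samples as columns, with a leading feature-id
#' column. Counts must be non-negative integers.
#'
#' @param path path to a tab-separated file.
#' @return integer matrix, features x samples.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("feature table needs an id column plus >=1 sample")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("feature table contains non-numeric entries")
  rownames(m) <- ids
  validate_feature_table(m)
  storage.mode(m) <- "double"
  m
}

#' Write a feature table to TSV
#' @param counts feature table matrix.
#' @param path output path.
#' @export
write_feature_table <- function(counts, path) {
  validate_feature_table(counts)
  df <- data.frame(feature_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ASV taxonomy table from TSV
#'
#' Requires a `feature_id` column plus the ranks phylum, class, order, family
#' and genus; missing assignments should be the string "unassigned".
#'
#' @param path path to a tab-separated file.
#' @return data.frame with rownames = feature ids.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!"feature_id" %in% names(df)) names(df)[1L] <- "feature_id"
  missing_ranks <- setdiff(TAXONOMY_RANKS, names(df))
  if (length(missing_ranks))
    stop("taxonomy missing rank columns: ", paste(missing_ranks, collapse = ", "))
  if (anyDuplicated(df$feature_id))
    stop("duplicate feature ids in taxonomy")
  for (r in TAXONOMY_RANKS) {
    df[[r]] <- as.character(df[[r]])
    df[[r]][is.na(df[[r]]) | !nzchar(df[[r]])] <- "unassigned"
  }
  rownames(df) <- df$feature_id
  df[, c("feature_id", TAXONOMY_RANKS)]
}

#' Write a taxonomy table to TSV
#' @param taxonomy data.frame as from [read_taxonomy()].
#' @param path output path.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Requires columns `sample_id`, `species` (host/parasite/soil), `organ`
#' (leaf/root/soil), `community_type` (PL, PR, IL, IIR, IUR, UL, UR, SOIL),
#' `site_id` and `specimen_id`; `total_usable_reads` is optional. The
#' community-type code is cross-checked against species x organ.
#'
#' @param path path to a tab-separated file.
#' @return data.frame with rownames = sample ids.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' Validate sample metadata
#' @param df metadata data.frame.
#' @return validated data.frame with rownames = sample ids.
#' @export
validate_metadata <- function(df) {
  req <- c("sample_id", "species", "organ", "community_type", "site_id",
           "specimen_id")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("metadata missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  unknown <- setdiff(df$community_type, COMMUNITY_TYPES$community_type)
  if (length(unknown))
    stop("unknown community types: ", paste(unique(unknown), collapse = ", "))
  expected <- COMMUNITY_TYPES[match(df$community_type,
                                    COMMUNITY_TYPES$community_type), ]
  bad <- which(df$species != expected$species | df$organ != expected$organ)
  if (length(bad))
    stop("community_type inconsistent with species x organ for samples: ",
         paste(df$sample_id[bad], collapse = ", "))
  rownames(df) <- df$sample_id
  df
}

#' Write sample metadata to TSV
#' @param metadata data.frame as from [read_metadata()].
#' @param path output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct and validate an analysis bundle
#'
#' Bundles the four id-aligned artifacts: feature table, rooted phylogeny,
#' taxonomy and sample metadata. Features absent from the tree or the
#' taxonomy are dropped (with a message); table samples must all appear in
#' the metadata. Retained feature order is the table's input order.
#'
#' @param counts feature table matrix (features x samples).
#' @param tree rooted `ape::phylo` whose tip labels cover the features.
#' @param taxonomy taxonomy data.frame.
#' @param metadata sample metadata data.frame.
#' @return object of class `analysis_bundle` with elements `counts`, `tree`,
#'   `taxonomy`, `metadata` and `dropped_features`.
#' @export
analysis_bundle <- function(counts, tree, taxonomy, metadata) {
  validate_feature_table(counts)
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree")
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)) ||
      any(tree$edge.length < 0))
    stop("tree branch lengths must be finite and >= 0")
  metadata <- validate_metadata(metadata)

  keep <- rownames(counts) %in% tree$tip.label &
    rownames(counts) %in% rownames(taxonomy)
  dropped <- rownames(counts)[!keep]
  report_dropped("features absent from tree or taxonomy", dropped)
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) == 0L) stop("no features left after tree/taxonomy alignment")

  missing_samples <- setdiff(colnames(counts), rownames(metadata))
  if (length(missing_samples))
    stop("samples missing from metadata: ", paste(missing_samples, collapse = ", "))
  metadata <- metadata[colnames(counts), , drop = FALSE]
  taxonomy <- taxonomy[rownames(counts), , drop = FALSE]
  tree <- ape::keep.tip(tree, rownames(counts))

  structure(list(counts = counts, tree = tree, taxonomy = taxonomy,
                 metadata = metadata, dropped_features = dropped),
            class = "analysis_bundle")
}

#' Read the four input artifacts into an analysis bundle
#'
#' @param table_path feature table TSV (features x samples, leading id column).
#' @param tree_path rooted newick tree whose tips are feature ids.
#' @param taxonomy_path taxonomy TSV.
#' @param metadata_path sample metadata TSV.
#' @return an `analysis_bundle`.
#' @export
read_bundle <- function(table_path, tree_path, taxonomy_path, metadata_path) {
  counts <- read_feature_table(table_path)
  tree <- ape::read.tree(tree_path)
  if (is.null(tree)) stop("could not parse newick tree at ", tree_path)
  taxonomy <- read_taxonomy(taxonomy_path)
  metadata <- read_metadata(metadata_path)
  analysis_bundle(counts, tree, taxonomy, metadata)
}

#' Write an analysis bundle to a directory
#'
#' Writes `table.tsv`, `tree.nwk`, `taxonomy.tsv` and `metadata.tsv`; the
#' files round-trip through [read_bundle()].
#'
#' @param bundle an `analysis_bundle`.
#' @param dir output directory (created if needed).
#' @return named character vector of the four paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "analysis_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(table = file.path(dir, "table.tsv"),
             tree = file.path(dir, "tree.nwk"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             metadata = file.path(dir, "metadata.tsv"))
  write_feature_table(bundle$counts, paths[["table"]])
  ape::write.tree(bundle$tree, paths[["tree"]])
  write_taxonomy(bundle$taxonomy, paths[["taxonomy"]])
  write_metadata(bundle$metadata, paths[["metadata"]])
  invisible(paths)
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat("analysis_bundle:", nrow(x$counts), "features x", ncol(x$counts),
      "samples\n")
  cat("  community types:",
      paste(sort(unique(x$metadata$community_type)), collapse = ", "), "\n")
  if (length(x$dropped_features))
    cat("  dropped at load:", length(x$dropped_features), "features\n")
  invisible(x)
}

#' Subset an analysis bundle by sample and/or feature ids
#'
#' Features whose counts become all-zero are retained (subsetting never
#' silently changes the feature universe); use the preprocessing filters to
#' drop them explicitly.
#'
#' @param bundle an `analysis_bundle`.
#' @param samples sample ids to keep (default all).
#' @param features feature ids to keep (default all).
#' @return an `analysis_bundle`.
#' @export
subset_bundle <- function(bundle, samples = NULL, features = NULL) {
  stopifnot(inherits(bundle, "analysis_bundle"))
  counts <- bundle$counts
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(counts))
    if (length(missing)) stop("unknown samples: ", paste(missing, collapse = ", "))
    counts <- counts[, samples, drop = FALSE]
  }
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(counts))
    if (length(missing)) stop("unknown features: ", paste(missing, collapse = ", "))
    counts <- counts[features, , drop = FALSE]
  }
  tree <- ape::keep.tip(bundle$tree, rownames(counts))
  structure(list(counts = counts, tree = tree,
                 taxonomy = bundle$taxonomy[rownames(counts), , drop = FALSE],
                 metadata = bundle$metadata[colnames(counts), , drop = FALSE],
                 dropped_features = character(0)),
            class = "analysis_bundle")
}

#' Write a labelled distance matrix to TSV
#'
#' @param dm symmetric numeric matrix with zero diagonal and dimnames.
#' @param path output path.
#' @export
write_distance_matrix <- function(dm, path) {
  validate_distance_matrix(dm)
  df <- data.frame(sample_id = rownames(dm),
                   format(dm, digits = 15, scientific = TRUE, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled distance matrix from TSV
#' @param path path written by [write_distance_matrix()].
#' @return symmetric numeric matrix.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  validate_distance_matrix(m)
  m
}

#' Validate a distance matrix
#' @param dm matrix to check.
#' @return the matrix, invisibly.
#' @export
validate_distance_matrix <- function(dm) {
  if (!is.matrix(dm) || !is.numeric(dm)) stop("distance matrix must be numeric")
  if (nrow(dm) == 0L) stop("distance matrix has no rows")
  if (is.null(rownames(dm)) || is.null(colnames(dm)) ||
      !identical(rownames(dm), colnames(dm)))
    stop("distance matrix needs identical row and column labels")
  if (any(!is.finite(dm))) stop("distance matrix has non-finite entries")
  if (any(dm < 0)) stop("distance matrix has negative entries")
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(abs(diag(dm)) > 1e-12)) stop("distance matrix diagonal is not zero")
  invisible(dm)
}
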