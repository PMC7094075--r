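# Shared phylogeny machinery: per-edge descendant-tip indicators, used by
# weighted UniFrac and Faith's PD.

# Returns list(edge_tip = logical [n_edge x n_tip] matrix, lengths, tips).
# edge_tip[e, t] is TRUE when tip t descends from (the child node of) edge e.
edge_descendants <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  nt <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  ne <- nrow(tr$edge)
  sets <- vector("list", nt + tr$Nnode)
  for (i in seq_len(nt)) sets[[i]] <- i
  M <- matrix(FALSE, ne, nt)
  for (k in seq_len(ne)) {
    child <- tr$edge[k, 2L]
    tips <- sets[[child]]
    M[k, tips] <- TRUE
    parent <- tr$edge[k, 1L]
    sets[[parent]] <- c(sets[[parent]], tips)
  }
  list(edge_tip = M, lengths = tr$edge.length, tips = tr$tip.label,
       tree = tr)
}

# Prune `tree` to the given tip labels, erroring on tips it does not contain.
prune_to <- function(tree, tips) {
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing))
    stop("features absent from tree: ", paste(missing, collapse = ", "))
  if (length(tips) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, tips)
}
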