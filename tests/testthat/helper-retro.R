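## Acceptance-measurement utilities for the retroposon criterion: observed
## marker conflict from simulated loci, and the gene-tree-based expectation
## (branch-length weighted, since insertion opportunity is proportional to
## branch length).

set_key <- function(x) paste(sort(x, method = "radix"), collapse = "|")

## focal-restricted clades (sizes 2-3) of an order-level topology: the only
## informative presence sets compatible with the species tree
retro_allowed_sets <- function(topology_id) {
  topo <- order_topologies()[[as.character(topology_id)]]
  keys <- character(0)
  ntip <- length(topo$tip.label)
  for (v in (ntip + 1L):(ntip + topo$Nnode)) {
    tips <- ape::extract.clade(topo, v)$tip.label
    if (length(tips) %in% 2:3) keys <- c(keys, set_key(tips))
  }
  unique(keys)
}

## tip sets per edge without per-edge ape calls
edge_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  out <- vector("list", nrow(tr$edge))
  for (e in seq_len(nrow(tr$edge))) {
    v <- tr$edge[e, 2]
    if (v > ntip && is.null(sets[[v]])) {
      kid_edges <- which(tr$edge[, 1] == v)
      sets[[v]] <- c(out[[kid_edges[1]]], out[[kid_edges[2]]])
    }
    out[[e]] <- sets[[v]]
  }
  list(edge = tr$edge, lengths = tr$edge.length, tips = out)
}

## observed informative/conflicting marker counts via the calling pipeline
marker_conflict_stats <- function(species_tree, config, allowed,
                                  focal = FOCAL_ORDERS) {
  loci <- simulate_retro_loci(species_tree, config)
  n_inf <- 0L; n_conf <- 0L
  for (lc in loci) {
    for (j in seq_len(nrow(lc$insertions))) {
      pat <- call_presence_absence(
        lc, c(lc$insertions$start_col[j], lc$insertions$end_col[j]),
        focal_species = focal)
      if (!pat$informative) next
      n_inf <- n_inf + 1L
      if (!(set_key(pat$present) %in% allowed)) n_conf <- n_conf + 1L
    }
  }
  list(n_informative = n_inf, n_conflicting = n_conf,
       frac_conflicting = if (n_inf) n_conf / n_inf else NA_real_)
}

## expectation from independently simulated gene trees: among the insertion
## opportunity (branch length) on informative branches, the share falling on
## branches whose focal clade conflicts with the species tree
expected_conflict_fraction <- function(species_tree, n_trees, seed, allowed,
                                       focal = FOCAL_ORDERS) {
  gts <- simulate_gene_trees(species_tree, n_trees, seed = seed)
  w_inf <- 0; w_conf <- 0
  for (gt in gts) {
    es <- edge_tip_sets(gt)
    for (e in seq_along(es$lengths)) {
      S <- intersect(es$tips[[e]], focal)
      if (!(length(S) %in% 2:3)) next
      w_inf <- w_inf + es$lengths[e]
      if (!(set_key(S) %in% allowed)) w_conf <- w_conf + es$lengths[e]
    }
  }
  w_conf / w_inf
}
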