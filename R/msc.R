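## Multispecies-coalescent gene-tree simulation.  Species trees carry branch
## lengths in coalescent units (2N generations); within each species-tree
## branch, the k lineages present coalesce at rate choose(k, 2), and the
## remaining lineages coalesce in the ancestral (root) population.

## node times (tip = 0) of an ultrametric-ish rooted tree, from branch lengths
.node_times <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tms <- numeric(nnode)
  tr <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(tr$edge))) {
    u <- tr$edge[i, 1]; v <- tr$edge[i, 2]
    tms[u] <- tms[v] + tr$edge.length[i]
  }
  tms
}

#' Simulate gene trees under the multispecies coalescent
#'
#' One haploid lineage is sampled per species-tree tip.  Within each branch
#' of the species tree (lengths in coalescent units) lineages coalesce at
#' rate `choose(k, 2)`; lineages entering the root population coalesce until
#' a single ancestor remains, so every gene-tree coalescence respects
#' species-tree containment.  With a rooted 3-taxon species tree
#' `((A,B),C)` and internal branch `t`, the probability that A and B are
#' sisters in the gene tree is the classic `1 - (2/3) exp(-t)`.
#'
#' @param species_tree rooted binary `phylo`, branch lengths in coalescent
#'   units
#' @param n_genes number of independent gene trees
#' @param seed optional integer seed (fixes the output)
#' @return list of rooted `phylo` gene trees with branch lengths in
#'   coalescent units
#' @export
simulate_gene_trees <- function(species_tree, n_genes, seed = NULL) {
  if (!.is_count(n_genes)) .stopf("n_genes must be a positive integer")
  .check_tree_for_lik(species_tree)
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(species_tree$tip.label)
  tms <- .node_times(species_tree)
  tr <- ape::reorder.phylo(species_tree, "postorder")
  E <- tr$edge; EL <- tr$edge.length
  root <- ntip + 1L
  ## children per node in postorder-completion order
  kids_of <- split(seq_len(nrow(E)), E[, 1])
  node_order <- as.integer(names(sort(vapply(kids_of, max, 0))))
  labels <- tr$tip.label
  pe_len <- numeric(ntip + tr$Nnode)
  pe_len[E[, 2]] <- EL

  sim_one <- function() {
    ## lineages per species-tree node: list of (gene subtree)
    ## each lineage: list(desc = tip indices, node = newick fragment, time)
    lin <- vector("list", ntip + tr$Nnode)
    for (i in seq_len(ntip))
      lin[[i]] <- list(list(nwk = labels[i], time = 0))
    coalesce_in <- function(lins, t_lo, t_hi) {
      k <- length(lins)
      t <- t_lo
      while (k > 1L) {
        t <- t + stats::rexp(1L, rate = k * (k - 1) / 2)
        if (t > t_hi) break
        ij <- sample.int(k, 2L)
        a <- lins[[ij[1]]]; b <- lins[[ij[2]]]
        merged <- list(
          nwk = paste0("(", a$nwk, ":", format(t - a$time, digits = 10),
                       ",", b$nwk, ":", format(t - b$time, digits = 10), ")"),
          time = t)
        lins[[ij[1]]] <- merged
        lins[[ij[2]]] <- NULL
        k <- k - 1L
      }
      lins
    }
    for (u in node_order) {
      er <- kids_of[[as.character(u)]]
      entering <- c(lin[[E[er[1], 2]]], lin[[E[er[2], 2]]])
      if (u == root) {
        lin[[u]] <- coalesce_in(entering, tms[u], Inf)
      } else {
        ## branch above u runs from time tms[u] to parent time
        lin[[u]] <- coalesce_in(entering, tms[u], tms[u] + pe_len[u])
      }
    }
    ape::read.tree(text = paste0(lin[[root]][[1]]$nwk, ";"))
  }
  lapply(seq_len(n_genes), function(i) sim_one())
}

#' Fraction of gene trees whose restriction matches the species tree
#'
#' Utility for calibration and discordance measurement: restricts each gene
#' tree to `taxa` (default: all species-tree tips) and compares the rooted
#' topology with the species tree's restriction.
#'
#' @param gene_trees list of `phylo`
#' @param species_tree rooted `phylo`
#' @param taxa tips to restrict to
#' @return proportion of matching gene trees
#' @export
concordance_fraction <- function(gene_trees, species_tree,
                                 taxa = species_tree$tip.label) {
  all_tips <- length(taxa) == length(species_tree$tip.label)
  restrict <- function(tr) if (all_tips && length(tr$tip.label) == length(taxa))
    tr else ape::keep.tip(tr, taxa)
  ref <- topology_key(restrict(species_tree))
  mean(vapply(gene_trees, function(g)
    topology_key(restrict(g)) == ref, logical(1)))
}
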