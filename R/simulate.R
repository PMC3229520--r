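## Synthetic-data generation: species trees over the four focal orders plus
## outgroups, sequence alignments evolved on (gene) trees, and the plumbing
## that maps coalescent units to substitutions/site.
##
## The species-tree scale is coalescent units (2N generations); a single
## scalar (`substitution_scale`, substitutions/site per coalescent unit)
## maps gene-tree branch lengths to sequence divergence, so the intensity of
## incomplete lineage sorting and the amount of sequence change can be tuned
## independently.

#' Specify a synthetic species tree
#'
#' @param topology_id integer 1-15 selecting an order-level rooted topology
#'   (see [order_topologies()])
#' @param internal_branch_lengths lengths (coalescent units) of the two
#'   internal branches of the order-level topology, assigned in preorder
#' @param within_order_subtrees named list: order -> character vector of
#'   species (a pectinate subtree is built), or NULL for one tip per order
#'   named after the order
#' @param outgroups 0-2 outgroup tip labels
#' @param ingroup_depth age (coalescent units) of the ingroup root
#' @param outgroup_depth age of the root joining ingroup and outgroups
#' @param substitution_scale expected substitutions/site per coalescent unit
#' @return object of class `species_tree_spec`
#' @export
species_tree_spec <- function(topology_id = 14L,
                              internal_branch_lengths = c(0.5, 0.5),
                              within_order_subtrees = NULL,
                              outgroups = c("Human", "Mouse"),
                              ingroup_depth = 6,
                              outgroup_depth = 9,
                              substitution_scale = 0.015) {
  if (!.is_count(topology_id) || topology_id > 15)
    .stopf("topology_id must be an integer in 1..15")
  if (any(internal_branch_lengths < 0)) .stopf("internal branch lengths must be >= 0")
  if (length(internal_branch_lengths) != 2L)
    .stopf("an order-level rooted 4-taxon tree has exactly 2 internal branches")
  if (sum(internal_branch_lengths) >= ingroup_depth)
    .stopf("internal branches do not fit within ingroup_depth")
  if (outgroup_depth <= ingroup_depth) .stopf("outgroup_depth must exceed ingroup_depth")
  tips <- unlist(within_order_subtrees) %||% character(0)
  if (anyDuplicated(c(tips, outgroups))) .stopf("duplicate tip labels")
  structure(list(topology_id = as.integer(topology_id),
                 internal_branch_lengths = internal_branch_lengths,
                 within_order_subtrees = within_order_subtrees,
                 outgroups = outgroups,
                 ingroup_depth = ingroup_depth,
                 outgroup_depth = outgroup_depth,
                 substitution_scale = substitution_scale),
            class = "species_tree_spec")
}

#' Build the species tree described by a spec
#'
#' The order-level topology is made ultrametric in coalescent units: the
#' ingroup root sits at `ingroup_depth`, each internal branch takes its
#' length from `internal_branch_lengths` (preorder), orders are expanded to
#' their subtrees (pectinate ladders, node ages evenly spaced below 60% of
#' the order's stem age), and outgroups attach at `outgroup_depth` (two
#' outgroups form a cherry at half that age).
#'
#' @param spec a `species_tree_spec`
#' @return rooted ultrametric `phylo`, branch lengths in coalescent units,
#'   with attributes `units = "coalescent"` and `substitution_scale`
#' @export
build_species_tree <- function(spec) {
  stopifnot(inherits(spec, "species_tree_spec"))
  topo <- order_topologies()[[as.character(spec$topology_id)]]
  ntip <- length(topo$tip.label)
  nnode <- ntip + topo$Nnode
  root <- ntip + 1L
  age <- rep(NA_real_, nnode)
  age[seq_len(ntip)] <- 0
  age[root] <- spec$ingroup_depth
  ## preorder assignment of internal branch lengths
  pre <- ape::reorder.phylo(topo, "cladewise")
  ib <- spec$internal_branch_lengths
  next_ib <- 1L
  for (i in seq_len(nrow(pre$edge))) {
    v <- pre$edge[i, 2]
    if (v > ntip) {
      age[v] <- age[pre$edge[i, 1]] - ib[next_ib]
      next_ib <- next_ib + 1L
    }
  }
  ## order-level newick with ages
  nest <- .phylo_to_nested(topo)
  node_id <- function(tipset) ape::getMRCA(topo, tipset)
  build <- function(nd, parent_age) {
    if (!is.list(nd)) {
      sub <- .order_subtree_newick(nd, spec$within_order_subtrees[[nd]], parent_age)
      return(sub)
    }
    tips_l <- unlist(nd)
    a <- age[node_id(tips_l)]
    l <- build(nd[[1]], a); r <- build(nd[[2]], a)
    paste0("(", l$nwk, ":", a - l$age, ",", r$nwk, ":", a - r$age, ")") -> nwk
    list(nwk = nwk, age = a)
  }
  ing <- build(nest, spec$ingroup_depth)
  ing$nwk <- ing$nwk  # ingroup root fragment, age = ingroup_depth
  og <- spec$outgroups
  D <- spec$outgroup_depth
  full <- if (length(og) == 0L) {
    list(nwk = ing$nwk, age = ing$age)
  } else if (length(og) == 1L) {
    list(nwk = paste0("(", ing$nwk, ":", D - ing$age, ",", og, ":", D, ")"),
         age = D)
  } else {
    cherry_age <- D / 2
    list(nwk = paste0("(", ing$nwk, ":", D - ing$age, ",(",
                      og[1], ":", cherry_age, ",", og[2], ":", cherry_age,
                      "):", D - cherry_age, ")"),
         age = D)
  }
  tree <- ape::read.tree(text = paste0(full$nwk, ";"))
  if (anyDuplicated(tree$tip.label)) .stopf("duplicate tip labels in species tree")
  attr(tree, "units") <- "coalescent"
  attr(tree, "substitution_scale") <- spec$substitution_scale
  tree
}

## pectinate ladder for one order; returns list(nwk, age of its root)
.order_subtree_newick <- function(order, species, parent_age) {
  if (is.null(species) || length(species) == 1L) {
    lab <- if (is.null(species)) order else species
    return(list(nwk = lab, age = 0))
  }
  k <- length(species)
  top_age <- 0.6 * parent_age
  nwk <- species[k]
  cur_age <- 0
  for (i in rev(seq_len(k - 1L))) {     # deepest node joins species[1]
    a <- top_age * (k - i) / (k - 1L)
    nwk <- paste0("(", species[i], ":", a, ",", nwk, ":", a - cur_age, ")")
    cur_age <- a
  }
  list(nwk = nwk, age = cur_age)
}

#' Convert a gene tree from coalescent units to substitutions/site
#' @param tree `phylo` in coalescent units
#' @param scale substitutions/site per coalescent unit
#' @export
scale_to_substitutions <- function(tree, scale) {
  tree$edge.length <- tree$edge.length * scale
  attr(tree, "units") <- "substitutions"
  tree
}

#' Simulate a gap-free alignment on a tree
#'
#' Sites evolve independently under the model's rate mixture: each site
#' draws an invariant/gamma-category rate, the root state comes from the
#' stationary frequencies (or `root_seq`), and states propagate down the
#' tree through the model's transition probabilities.
#'
#' @param gene_tree `phylo` with branch lengths in substitutions/site
#' @param model a `substitution_model`
#' @param length number of sites (columns)
#' @param seed optional integer seed
#' @param root_seq optional character vector of root states (length
#'   `length`) overriding the stationary draw
#' @param locus_id id for the resulting alignment
#' @return a `gene_alignment`
#' @export
simulate_alignment <- function(gene_tree, model, length, seed = NULL,
                               root_seq = NULL, locus_id = "sim") {
  if (!.is_count(length)) .stopf("length must be a positive integer")
  .check_tree_for_lik(gene_tree)
  if (!is.null(seed)) set.seed(seed)
  n <- model$nstates
  states <- model$states
  L <- as.integer(length)
  ## site rates: invariant class w.p. pinv, else a gamma category
  ncat_all <- model$ncat
  cat_idx <- sample.int(ncat_all, L, replace = TRUE)
  rate <- model$cat_rates[cat_idx]
  if (model$pinv > 0)
    rate[stats::runif(L) < model$pinv] <- 0
  root_states <- if (is.null(root_seq)) {
    sample.int(n, L, replace = TRUE, prob = model$freqs)
  } else {
    if (length(root_seq) != L) .stopf("root_seq must have %d states", L)
    m <- match(tolower(root_seq), states)
    if (anyNA(m)) .stopf("root_seq contains non-model states")
    m
  }
  ntip <- length(gene_tree$tip.label)
  tr <- ape::reorder.phylo(gene_tree, "cladewise")  # preorder
  seqs <- vector("list", ntip + tr$Nnode)
  seqs[[ntip + 1L]] <- root_states
  rate_groups <- split(seq_len(L), rate)
  for (i in seq_len(nrow(tr$edge))) {
    u <- tr$edge[i, 1]; v <- tr$edge[i, 2]; t <- tr$edge.length[i]
    parent <- seqs[[u]]
    child <- parent
    for (rg in names(rate_groups)) {
      r <- as.numeric(rg)
      if (r == 0 || t == 0) next
      idx <- rate_groups[[rg]]
      P <- .prob_matrix(model, t, r)
      for (s in seq_len(n)) {
        here <- idx[parent[idx] == s]
        if (length(here))
          child[here] <- sample.int(n, length(here), replace = TRUE, prob = P[s, ])
      }
    }
    seqs[[v]] <- child
  }
  rows <- vapply(seq_len(ntip), function(i)
    paste(states[seqs[[i]]], collapse = ""), character(1))
  names(rows) <- tr$tip.label
  gene_alignment(rows, if (n == 4L) "nucleotide" else "amino_acid", locus_id)
}

#' Configuration for the synthetic end-to-end study
#'
#' Defaults describe a desk-scale emulation of a multi-genome phylogenomic
#' dataset: a handful of species across four focal clades plus outgroups,
#' hundreds-to-thousands of coding sites per gene, GTR+G+I sequence
#' evolution, and LINE1-like insertions accumulating on gene trees.
#'
#' @param n_genes number of gene alignments
#' @param gene_length sites per gene (a single number or sampling function)
#' @param model a `substitution_model`
#' @param insertion_rate expected LINE1 insertions per intron per coalescent
#'   unit of gene-tree branch length
#' @param n_introns number of intron loci for the retroposon screen
#' @param intron_length_range min/max ancestral intron length (bp)
#' @param flank_length exon flank length (bp) on each side of an intron
#' @param seed master seed; every derived stream comes from it
#' @return object of class `synthetic_config`
#' @export
synthetic_config <- function(n_genes = 50L, gene_length = 999L,
                             model = gtr_model(alpha = 0.8, pinv = 0.2),
                             insertion_rate = 0.05, n_introns = 100L,
                             intron_length_range = c(400L, 1500L),
                             flank_length = 80L, seed = 1L) {
  stopifnot(.is_count(n_genes), .is_count(n_introns), .is_count(flank_length),
            insertion_rate >= 0, length(intron_length_range) == 2L,
            intron_length_range[1] > 0,
            intron_length_range[2] >= intron_length_range[1])
  structure(list(n_genes = as.integer(n_genes), gene_length = gene_length,
                 model = model, insertion_rate = insertion_rate,
                 n_introns = as.integer(n_introns),
                 intron_length_range = as.integer(intron_length_range),
                 flank_length = as.integer(flank_length),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}
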