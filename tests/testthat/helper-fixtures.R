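## Shared fixtures: tiny alignments, grafted topology sets, and random
## instances used across test files.

rand_alignment <- function(taxa, ncol, seed = 1, alphabet = "nucleotide",
                           locus_id = "t") {
  set.seed(seed)
  states <- if (alphabet == "nucleotide") c("a", "c", "g", "t")
            else strsplit("arndcqeghilkmfpstwyv", "")[[1]]
  rows <- vapply(taxa, function(x)
    paste(sample(states, ncol, TRUE), collapse = ""), character(1))
  gene_alignment(rows, alphabet, locus_id)
}

grafted_topologies <- function(outgroups = c("Human", "Mouse")) {
  subs <- as.list(stats::setNames(FOCAL_ORDERS, FOCAL_ORDERS))
  lapply(order_topologies(), function(t) graft(t, subs, outgroups))
}

sim_gene_alignment <- function(species_tree, model, length, seed,
                               scale = attr(species_tree, "substitution_scale"),
                               locus_id = "g") {
  gt <- simulate_gene_trees(species_tree, 1L, seed = seed)[[1]]
  simulate_alignment(scale_to_substitutions(gt, scale), model, length,
                     seed = seed + 1L, locus_id = locus_id)
}

expect_setequal_chr <- function(a, b) expect_true(setequal(a, b))
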