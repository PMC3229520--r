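test_that("two identical 1-site sequences at zero distance give log(1/4) under JC", {
  aln <- gene_alignment(c(a = "c", b = "c"), locus_id = "one")
  tr <- ape::read.tree(text = "(a:0,b:0);")
  ll <- log_likelihood(aln, tr, jc_model())
  expect_equal(ll$total, log(1 / 4), tolerance = 1e-12)
})

test_that("two-sequence JC likelihood matches the closed form", {
  ## P(same) = 1/4 + 3/4 e^{-4d/3}; P(diff, specific) = 1/4 - 1/4 e^{-4d/3}
  aln <- gene_alignment(c(a = "acgtt", b = "acgta"), locus_id = "two")
  for (d in c(0.05, 0.3, 1)) {
    tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", d / 2, d / 2))
    ll <- log_likelihood(aln, tr, jc_model())
    ps <- 1 / 4 + 3 / 4 * exp(-4 * d / 3)
    pdiff <- 1 / 4 - 1 / 4 * exp(-4 * d / 3)
    expect_equal(ll$total, 4 * log(ps / 4) + log(pdiff / 4), tolerance = 1e-10)
  }
})

test_that("pruning equals exhaustive ancestral-state summation (oracle)", {
  set.seed(31)
  for (rep in 1:4) {
    ntaxa <- sample(3:5, 1)
    tr <- ape::rtree(ntaxa, rooted = TRUE)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.01, 0.8)
    aln <- rand_alignment(tr$tip.label, 12, seed = rep)
    model <- switch(rep %% 3 + 1,
                    jc_model(),
                    gtr_model(rates = c(1, 2, 0.5, 1.5, 3, 1),
                              freqs = c(0.35, 0.15, 0.2, 0.3), alpha = 0.6),
                    gtr_model(alpha = 1.2, pinv = 0.25))
    expect_equal(log_likelihood(aln, tr, model)$total,
                 oracle_loglik(aln, tr, model), tolerance = 1e-10)
  }
  ## with gaps and ambiguity codes
  aln <- gene_alignment(c(a = "acg-ntrac", b = "acgtatgac", c = "ccgtatgtc"),
                        locus_id = "amb")
  tr <- ape::read.tree(text = "((a:0.1,b:0.2):0.15,c:0.3);")
  model <- gtr_model(alpha = 0.9, pinv = 0.1)
  expect_equal(log_likelihood(aln, tr, model)$total,
               oracle_loglik(aln, tr, model), tolerance = 1e-10)
})

test_that("pulley principle: re-rooting leaves the likelihood unchanged", {
  set.seed(5)
  tr <- ape::rtree(5, rooted = TRUE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.5)
  aln <- rand_alignment(tr$tip.label, 40, seed = 6)
  model <- gtr_model(rates = c(1, 2, 1, 1, 3, 1), freqs = c(0.3, 0.2, 0.2, 0.3),
                     alpha = 0.7, pinv = 0.1)
  base <- log_likelihood(aln, tr, model)$total
  for (tip in tr$tip.label[1:3]) {
    rr <- ape::root(ape::unroot(tr), outgroup = tip, resolve.root = TRUE)
    expect_equal(log_likelihood(aln, rr, model)$total, base,
                 tolerance = 1e-8 * abs(base))
  }
})

test_that("GTR with unit exchangeabilities and uniform frequencies equals JC", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.3):0.1,(c:0.2,d:0.4):0.2);")
  aln <- rand_alignment(letters[1:4], 30, seed = 7)
  expect_equal(log_likelihood(aln, tr, gtr_model(alpha = 0.5, pinv = 0.2))$total,
               log_likelihood(aln, tr, jc_model(alpha = 0.5, pinv = 0.2))$total,
               tolerance = 1e-12)
})

test_that("large alpha approaches rate homogeneity; pinv = 0 removes the class", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.3):0.1,c:0.25);")
  aln <- rand_alignment(letters[1:3], 50, seed = 8)
  hom <- log_likelihood(aln, tr, jc_model())$total
  big <- log_likelihood(aln, tr, jc_model(alpha = 1e6))$total
  expect_equal(big, hom, tolerance = 1e-4)
  expect_equal(log_likelihood(aln, tr, jc_model(alpha = 0.5, pinv = 0))$total,
               log_likelihood(aln, tr, jc_model(alpha = 0.5))$total,
               tolerance = 1e-12)
})

test_that("branch-length optimization ascends and handles identical sequences", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,c:0.1);")
  same <- gene_alignment(c(a = strrep("acgt", 10), b = strrep("acgt", 10),
                           c = strrep("acgt", 10)), locus_id = "same")
  fit <- optimize_branch_lengths(same, tr, jc_model())
  expect_true(all(fit$tree$edge.length <= 1e-6))
  expect_true(all(diff(c(-Inf, fit$trace)) > -1e-6))  # non-decreasing

  spec <- species_tree_spec(internal_branch_lengths = c(2, 2))
  st <- build_species_tree(spec)
  model <- gtr_model(alpha = 0.8, pinv = 0.2)
  aln <- sim_gene_alignment(st, model, 1500, seed = 99)
  topo <- grafted_topologies()[["14"]]
  fitC <- optimize_branch_lengths(aln, topo, model)
  fitR <- optimize_branch_lengths(aln, topo, model, method = "R")
  expect_equal(fitC$loglik$total, fitR$loglik$total, tolerance = 1e-3)
  expect_gte(fitC$loglik$total,
             log_likelihood(aln, fitC$tree, model)$total - 1e-6)
  ## per-site vector sums to the total
  expect_equal(sum(fitC$loglik$per_site), fitC$loglik$total, tolerance = 1e-8)
})

test_that("branch lengths are recovered on long simulated alignments", {
  ## pattern compression keeps 4-taxon x 1e5 sites cheap
  tr <- ape::read.tree(text = "((a:0.12,b:0.07):0.05,(c:0.09,d:0.15):0.08);")
  model <- gtr_model(rates = c(1, 2, 1, 1, 2.5, 1),
                     freqs = c(0.3, 0.2, 0.25, 0.25), alpha = 0.8)
  aln <- simulate_alignment(tr, model, 1e5, seed = 42)
  init <- tr
  init$edge.length <- rep(0.1, nrow(tr$edge))
  fit <- optimize_branch_lengths(aln, init, model)
  ## compare tip-to-tip path lengths (the two root edges are only jointly
  ## identifiable under a reversible model)
  ref <- ape::cophenetic.phylo(tr)
  est <- ape::cophenetic.phylo(fit$tree)[rownames(ref), colnames(ref)]
  expect_equal(est[lower.tri(est)], ref[lower.tri(ref)], tolerance = 0.1)
})
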