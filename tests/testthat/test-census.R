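test_that("tally applies the tie and rejection rules (hand-enumerated case)", {
  m <- rbind(g1 = c(-10, -11, -15), g2 = c(-20, -20, -25))
  colnames(m) <- c("A", "B", "C")
  ct <- tally(m, equal_tol = 0, reject_margin = 2, mode = "ML")
  expect_equal(ct$best_count, c(2L, 1L, 0L))
  expect_equal(ct$rejected_count, c(0L, 0L, 2L))
  ## summed-likelihood differences: best topology 0, others <= 0
  expect_equal(ct$delta_sum_logL, c(0, -1, -10))
})

test_that("tally degenerate and invariance properties hold", {
  m <- matrix(-5, 3, 4, dimnames = list(paste0("g", 1:3), paste0("t", 1:4)))
  ct <- tally(m, mode = "ML")
  expect_true(all(ct$best_count == 3L))
  expect_true(all(ct$rejected_count == 0L))
  expect_equal(sum(ct$delta_sum_logL == 0), 4L)

  set.seed(10)
  m2 <- matrix(rnorm(60, -100, 5), 12, 5,
               dimnames = list(paste0("g", 1:12), paste0("t", 1:5)))
  a <- tally(m2, mode = "ML")
  b <- tally(m2[sample(12), sample(5)], mode = "ML")
  b <- b[match(a$topology, b$topology), ]
  expect_equal(a$best_count, b$best_count)
  expect_equal(a$rejected_count, b$rejected_count)
  ## raising the margin never increases rejections
  for (rm2 in c(1, 2, 5, 10)) {
    r1 <- tally(m2, reject_margin = rm2, mode = "ML")$rejected_count
    r2 <- tally(m2, reject_margin = rm2 + 1, mode = "ML")$rejected_count
    expect_true(all(r2 <= r1))
  }
  ## mLogL defaults: 0.5 tie window, 10-unit rejection
  m3 <- rbind(g = c(0, -0.4, -0.6, -9.9, -10.1))
  colnames(m3) <- paste0("t", 1:5)
  ct3 <- tally(m3, mode = "mLogL")
  expect_equal(ct3$best_count, c(1L, 1L, 0L, 0L, 0L))
  expect_equal(ct3$rejected_count, c(0L, 0L, 0L, 0L, 1L))
  expect_error(tally(m2[0, , drop = FALSE]), "empty")
})

test_that("score_genes recovers the generating topology and logs failures", {
  spec <- species_tree_spec(internal_branch_lengths = c(2.5, 2.5))
  st <- build_species_tree(spec)
  model <- gtr_model(alpha = 0.8, pinv = 0.2)
  alns <- lapply(1:6, function(i)
    sim_gene_alignment(st, model, 1200, seed = 100 + i,
                       locus_id = sprintf("g%02d", i)))
  topos <- grafted_topologies()
  gsm <- score_genes(alns, topos, model)
  expect_equal(dim(gsm$scores), c(6L, 15L))
  ct <- tally(gsm)
  expect_equal(ct$topology[which.max(ct$best_count)], "14")
  expect_equal(ct$rejected_count[ct$topology == "14"], 0L)
  ## deterministic rescoring
  gsm2 <- score_genes(alns[1], topos[c("5", "14")], model)
  expect_equal(gsm2$scores[1, ], gsm$scores[1, c("5", "14")], tolerance = 1e-9)
  ## a gene missing a species is excluded with a reason, not fatal
  bad <- gene_alignment(c(Carnivora = "acgt"), locus_id = "bad")
  gsm3 <- score_genes(c(alns[1], list(bad)), topos, model)
  expect_equal(nrow(gsm3$scores), 1L)
  expect_match(gsm3$failures$reason, "lacks sequence")
})

test_that("SH test behaves at its fixed points", {
  ## identical per-site vectors: all pSH = 1
  s <- matrix(rnorm(200, -3), 100, 2)
  s[, 2] <- s[, 1]
  sh <- sh_test(s, 500, seed = 1)
  expect_equal(sh$pSH, c(1, 1))

  ## one topology better at every site: its pSH stays 1, others -> 0
  set.seed(2)
  base <- rnorm(5000, -3, 0.3)
  s2 <- cbind(best = base, worse = base - 0.1, bad = base - 0.2)
  sh2 <- sh_test(s2, 1000, seed = 3)
  expect_equal(sh2$pSH[1], 1)
  expect_lt(sh2$pSH[2], 0.01)
  expect_true(sh2$rejected[3])

  ## adding a common per-site constant to all topologies changes nothing
  shift <- rnorm(5000, 0, 0.5)
  s3 <- s2 + shift
  sh3 <- sh_test(s3, 1000, seed = 3)
  expect_equal(sh3$pSH, sh2$pSH)

  expect_error(sh_test(list(rnorm(5), rnorm(6))), "differ in length")
})
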