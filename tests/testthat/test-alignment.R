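test_that("FASTA round trip preserves rows; ragged input names the record", {
  aln <- rand_alignment(c("sp1", "sp2", "sp3"), 37, seed = 4)
  p <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_alignment(aln, p)
  back <- read_fasta_alignment(p)
  expect_identical(back$rows, aln$rows)
  expect_equal(back$alphabet, "nucleotide")

  writeLines(c(">a", "acgt", ">b", "acg"), p)
  expect_error(read_fasta_alignment(p), "ragged.*'b'")
  writeLines(character(0), p)
  expect_error(read_fasta_alignment(p), "empty")
})

test_that("back-translation expands columns 3x and inverts translation", {
  aa <- gene_alignment(c(A = "m-k", B = "mgk"), "amino_acid", "bt")
  nt <- back_translate(aa, c(A = "ATGAAA", B = "ATGGGCAAG"))
  expect_equal(nt$rows[["A"]], "atg---aaa")
  expect_equal(nt$n_columns, 3L * aa$n_columns)
  ## inverse property on the ungapped codons
  codons <- substring(nt$rows[["B"]], c(1, 4, 7), c(3, 6, 9))
  tr <- tolower(as.character(Biostrings::translate(
    Biostrings::DNAStringSet(toupper(codons)))))
  expect_equal(paste(tr, collapse = ""), "mgk")

  expect_error(back_translate(aa, c(A = "ATGAAAT", B = "ATGGGCAAG")), "length")
  expect_error(back_translate(aa, c(A = "ATGAAA", B = "ATGGGCCAG")),
               "translates to")
})

test_that("divergence filter applies the strict 30% rule with pairwise deletion", {
  identical2 <- gene_alignment(c(a = "acgtacgtac", b = "acgtacgtac"),
                               locus_id = "id")
  f <- divergence_filter(identical2)
  expect_true(f$keep)
  expect_equal(f$max_difference, 0)

  ## 10 shared columns, 4 differences -> 0.40 > 0.30: discard
  two <- gene_alignment(c(a = "acgtacgtac", b = "acgttttttc"), locus_id = "d")
  f2 <- divergence_filter(two)
  expect_equal(f2$max_difference, 0.4)
  expect_false(f2$keep)
  expect_true(divergence_filter(two, threshold = 1.0)$keep)

  ## gapped/ambiguous columns are excluded pairwise
  g <- gene_alignment(c(a = "acgt-cgtac", b = "acgtttntac"), locus_id = "g")
  pd <- p_distance_matrix(g)
  expect_equal(pd$shared[1, 2], 8)
  expect_equal(pd$distance[1, 2], 1 / 8)

  expect_error(divergence_filter(gene_alignment(c(x = "acgt"), locus_id = "x")),
               ">= 2")
})

test_that("p-distance is symmetric, bounded, and row-order invariant", {
  aln <- rand_alignment(letters[1:4], 60, seed = 9)
  d <- p_distance_matrix(aln)$distance
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
  perm <- gene_alignment(aln$rows[c(3, 1, 4, 2)], locus_id = "p")
  f1 <- divergence_filter(aln); f2 <- divergence_filter(perm)
  expect_equal(f1$keep, f2$keep)
  expect_equal(f1$max_difference, f2$max_difference)
})

test_that("concatenation pads missing species and reports coverage", {
  a1 <- gene_alignment(c(x = "acgtacgtac", y = "acgtacgtac"), locus_id = "l1")
  a2 <- gene_alignment(c(x = "tttttttttt", z = "cccccccccc"), locus_id = "l2")
  cc <- concatenate(list(a1, a2))
  expect_equal(cc$alignment$n_columns, 20L)
  cov <- cc$coverage
  expect_equal(cov$percent_coverage[cov$species == "x"], 100)
  expect_equal(cov$percent_coverage[cov$species == "y"], 50)
  expect_equal(cov$percent_coverage[cov$species == "z"], 50)
  ## order changes layout, not coverage
  cc2 <- concatenate(list(a2, a1))
  expect_equal(sort(cc2$coverage$percent_coverage),
               sort(cov$percent_coverage))
  expect_error(concatenate(list()), "empty")
  aa <- gene_alignment(c(x = "mk"), "amino_acid", "aa1")
  expect_error(concatenate(list(a1, aa)), "mixed")
})
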