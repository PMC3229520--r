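test_that("tree splits follow the n + (n-3) count for binary trees", {
  q <- ape::read.tree(text = "((a,b),(c,d));")
  expect_length(tree_splits(q), 5L)              # 4 trivial + 1 internal
  star <- ape::read.tree(text = "(a,b,c,d);")
  expect_length(tree_splits(star), 4L)           # trivial only
  six <- ape::read.tree(text = "(((a,b),(c,d)),(e,f));")
  expect_length(tree_splits(six), 9L)            # 6 + 3 internal
  ## splits from one tree are pairwise compatible
  taxa <- sort(six$tip.label)
  ss <- tree_splits(six)
  for (i in seq_along(ss)) for (j in seq_along(ss))
    expect_true(splits_compatible(ss[[i]], ss[[j]], taxa))
})

test_that("consensus splits threshold frequencies correctly", {
  one <- ape::read.tree(text = "((a,b),(c,d));")
  many <- rep(list(one), 100)
  cs <- consensus_splits(many, 0.9)
  expect_length(cs$sides, 5L)
  expect_true(all(cs$weights == 1))

  ## quartet resolutions at 40/35/25%: threshold 0.30 keeps 2 internal splits
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  t3 <- ape::read.tree(text = "((a,d),(b,c));")
  trees <- c(rep(list(t1), 40), rep(list(t2), 35), rep(list(t3), 25))
  ## on 4 taxa the non-trivial splits are exactly the 2-taxon sides
  cs2 <- consensus_splits(trees, 0.30)
  internal <- Filter(function(s) length(s) == 2, cs2$sides)
  expect_length(internal, 2L)
  ## threshold 0 keeps all observed splits; raising gives subsets
  all_s <- consensus_splits(trees, 0)
  expect_length(Filter(function(s) length(s) == 2, all_s$sides), 3L)
  keys <- function(x) vapply(x$sides, paste, "", collapse = "|")
  expect_true(all(keys(cs2) %in% keys(all_s)))
  ## majority-rule property: threshold > 0.5 gives compatible splits
  maj <- consensus_splits(trees, 0.51)
  for (i in seq_along(maj$sides)) for (j in seq_along(maj$sides))
    expect_true(splits_compatible(maj$sides[[i]], maj$sides[[j]], maj$taxa))
  expect_error(consensus_splits(list(t1, ape::read.tree(text = "((a,b),(c,e));"))),
               "inconsistent")
})

test_that("marker split networks carry raw counts and drop zero hypotheses", {
  taxa <- c(FOCAL_ORDERS, "Outgroup")
  counts <- c("Cetartiodactyla+Chiroptera+Carnivora" = 3,  # Perissodactyla first
              "Chiroptera+Perissodactyla+Carnivora" = 3,   # Cetartiodactyla first
              "Cetartiodactyla+Chiroptera+Perissodactyla" = 2,  # Carnivora first
              "Carnivora+Perissodactyla" = 2,
              "Carnivora+Chiroptera" = 1,
              "Cetartiodactyla+Perissodactyla" = 0)
  ms <- marker_split_network(counts, taxa)
  expect_length(ms$sides, 5L)
  expect_setequal_chr(ms$weights, c(3, 3, 2, 2, 1))
  single <- marker_split_network(c("Carnivora+Perissodactyla" = 4), taxa)
  expect_length(single$sides, 1L)
  empty <- marker_split_network(c("Carnivora+Chiroptera" = 0), taxa)
  expect_length(empty$sides, 0L)
  expect_error(marker_split_network(c("Carnivora" = -1), taxa), ">= 0")
})

test_that("SplitsTree NEXUS output round-trips with stable formatting", {
  taxa <- c(FOCAL_ORDERS, "Outgroup")
  ms <- marker_split_network(
    c("Cetartiodactyla+Chiroptera+Carnivora" = 3,
      "Carnivora+Perissodactyla" = 2,
      "Carnivora+Chiroptera" = 1), taxa)
  p <- withr::local_tempfile(fileext = ".nex")
  write_splits_nexus(ms, p)
  txt <- readLines(p)
  expect_true(any(grepl("BEGIN ST_SPLITS;", txt)))
  expect_equal(sum(grepl("^\\[", txt)), 3L)
  back <- read_splits_nexus(p)
  expect_identical(back$taxa, ms$taxa)
  k <- function(x) vapply(x$sides, paste, "", collapse = "|")
  expect_setequal_chr(k(back), k(ms))
  expect_equal(sort(back$weights), sort(ms$weights))
  ## byte-stable output
  p2 <- withr::local_tempfile(fileext = ".nex")
  write_splits_nexus(ms, p2)
  expect_identical(readLines(p), readLines(p2))
})
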