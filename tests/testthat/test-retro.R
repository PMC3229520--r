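test_that("intron harvesting applies strict bounds and flank rules", {
  set.seed(42)
  exon <- function(n) paste(sample(c("a", "c", "g", "t"), n, TRUE), collapse = "")
  mk_gene <- function(id, intron_len, strand = "+", lead = 100L) {
    e1 <- exon(lead); ic <- exon(intron_len); e2 <- exon(120)
    seqc <- paste0(e1, ic, e2)
    g <- list(gene_id = id, sequence = seqc,
              exons = data.frame(start = c(0L, lead + intron_len),
                                 end = c(lead, lead + intron_len + 120L)),
              strand = strand)
    if (strand == "-") {
      g$sequence <- revcomp(seqc)
      n <- nchar(seqc)
      g$exons <- data.frame(start = n - rev(g$exons$end),
                            end = n - rev(g$exons$start))
    }
    g
  }
  h <- harvest_introns(list(mk_gene("gA", 1000L)))
  expect_length(h$introns, 1L)
  expect_equal(nchar(h$introns[[1]]$sequence), 1000L)
  expect_equal(nchar(h$introns[[1]]$up_flank), 80L)
  ## boundary: exactly 300 is excluded (strict), 301 included
  expect_length(harvest_introns(list(mk_gene("gB", 300L)))$introns, 0L)
  expect_length(harvest_introns(list(mk_gene("gC", 301L)))$introns, 1L)
  expect_length(harvest_introns(list(mk_gene("gD", 3000L)))$introns, 0L)
  ## single exon: no introns
  single <- list(gene_id = "gE", sequence = exon(500),
                 exons = data.frame(start = 0L, end = 500L), strand = "+")
  expect_length(harvest_introns(list(single))$introns, 0L)
  ## flank truncated at the gene boundary: dropped and logged
  short <- mk_gene("gF", 800L, lead = 40L)
  h2 <- harvest_introns(list(short))
  expect_length(h2$introns, 0L)
  expect_match(h2$dropped$reason, "flank truncated")
  ## minus-strand genes are normalized to gene orientation
  plus <- mk_gene("gG", 900L); minus <- plus; minus$strand <- "-"
  minus$sequence <- revcomp(plus$sequence)
  n <- nchar(plus$sequence)
  minus$exons <- data.frame(start = n - rev(plus$exons$end),
                            end = n - rev(plus$exons$start))
  hp <- harvest_introns(list(plus)); hm <- harvest_introns(list(minus))
  expect_equal(hm$introns[[1]]$sequence, hp$introns[[1]]$sequence)
})

test_that("RepeatMasker parsing keeps LINE1 rows and converts coordinates", {
  p <- withr::local_tempfile(fileext = ".out")
  writeLines(c(
    "   SW   perc perc perc  query  position in query  matching repeat class  pos  ID",
    "score   div. del. ins.  sequence begin end (left) repeat  class/family  b e (l) ID",
    "",
    " 1000  10.0  0.0  0.0  q1     11     40  (60)  + L1MA4    LINE/L1       1 30 (0)  1",
    "  900  12.0  0.0  0.0  q1     50     80  (20)  C L1PB     LINE/L1       1 31 (0)  2",
    "  800   8.0  0.0  0.0  q2     10     35  (65)  + AluY     SINE/Alu      1 26 (0)  3",
    "  700   9.0  0.0  0.0  q2     40     70  (30)  + MIR      SINE/MIR      1 31 (0)  4",
    " 1100  11.0  0.0  0.0  q3      5     90  (10)  + L1ME     LINE/L1       1 86 (0)  5",
    "this line is malformed"), p)
  ann <- suppressWarnings(parse_repeat_annotations(p))
  expect_equal(nrow(ann), 3L)
  expect_true(all(grepl("^LINE/L1", ann$repeat_class)))
  expect_equal(ann$start[1], 10L)      # 1-based inclusive -> 0-based half-open
  expect_equal(ann$end[1], 40L)
  expect_equal(ann$strand[2], "-")
  expect_equal(attr(ann, "skipped"), 1L)
  ## empty file
  p2 <- withr::local_tempfile(fileext = ".out")
  writeLines(character(0), p2)
  expect_equal(nrow(parse_repeat_annotations(p2)), 0L)
})

test_that("synthetic annotations round-trip through the .out parser", {
  st <- build_species_tree(species_tree_spec(internal_branch_lengths = c(2, 2)))
  cfg <- synthetic_config(n_introns = 12, insertion_rate = 0.15, seed = 8)
  loci <- simulate_retro_loci(st, cfg)
  d <- withr::local_tempdir()
  write_retro_loci(loci, d)
  ann <- parse_repeat_annotations(file.path(d, "repeats.out"))
  truth <- utils::read.table(file.path(d, "insertion_truth.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  expect_gt(nrow(ann), 0L)
  ## lengths recorded in the truth table appear among parsed interval sizes
  expect_setequal_chr(unique(ann$end - ann$start), unique(truth$length))
  ## parsed intervals point at the inserted segment in each carrier's
  ## ungapped sequence (compare against alignment-derived truth columns)
  for (i in seq_len(min(nrow(ann), 25))) {
    q <- strsplit(ann$query[i], "|", fixed = TRUE)[[1]]
    lc <- loci[[match(q[1], vapply(loci, `[[`, "", "locus_id"))]]
    row <- as_char_matrix(lc$alignment)[q[2], ]
    ung <- row[row != "-"]
    tt <- lc$insertions[lc$insertions$length == ann$end[i] - ann$start[i] &
                          grepl(q[2], lc$insertions$carriers, fixed = TRUE), ]
    expect_gte(nrow(tt), 1L)
    seg_aln <- row[(tt$start_col[1] + 1):tt$end_col[1]]
    expect_identical(paste(ung[(ann$start[i] + 1):ann$end[i]], collapse = ""),
                     paste(seg_aln, collapse = ""))
  }
})

test_that("orthologous introns are recovered by flank anchoring", {
  set.seed(77)
  base <- paste(sample(c("a", "c", "g", "t"), 1200, TRUE), collapse = "")
  up <- substr(base, 101, 180); intron <- substr(base, 181, 900)
  dn <- substr(base, 901, 980)
  ref <- list(up_flank = up, sequence = intron, down_flank = dn)
  mut <- phyloconflict:::.mutate_seq(base, 0.05)
  hit <- anchor_orthologous_intron(ref, mut)
  expect_true(hit$found)
  expect_equal(hit$start, 180, tolerance = 3)
  expect_equal(hit$end, 900, tolerance = 3)
  ## reverse-complement target is recovered after strand normalization
  rc <- anchor_orthologous_intron(ref, revcomp(mut))
  expect_true(rc$found)
  expect_equal(rc$strand, "-")
  expect_equal(rc$end - rc$start, hit$end - hit$start, tolerance = 6)
  ## absent flank: not found
  none <- anchor_orthologous_intron(ref, paste(rep("acgt", 100), collapse = ""))
  expect_false(none$found)
})

test_that("presence/absence calls follow the explicit thresholds", {
  ## internal branches of 8 coalescent units: discordance ~ (2/3)e^-8, so
  ## effectively no ILS and informative markers cannot conflict
  st <- build_species_tree(species_tree_spec(internal_branch_lengths = c(8, 8),
                                             ingroup_depth = 20,
                                             outgroup_depth = 24))
  cfg <- synthetic_config(n_introns = 40, insertion_rate = 0.12, seed = 15)
  loci <- simulate_retro_loci(st, cfg)
  found_informative <- FALSE
  for (lc in loci) {
    for (j in seq_len(nrow(lc$insertions))) {
      pat <- call_presence_absence(
        lc, c(lc$insertions$start_col[j], lc$insertions$end_col[j]),
        focal_species = FOCAL_ORDERS)
      carriers <- strsplit(lc$insertions$carriers[j], "|", fixed = TRUE)[[1]]
      focal_carriers <- intersect(carriers, FOCAL_ORDERS)
      ## calls match the generating truth (no noise in this regime)
      expect_setequal_chr(pat$present, focal_carriers)
      if (pat$informative) {
        found_informative <- TRUE
        expect_true(length(pat$present) %in% 2:3)
        ## no ILS here: informative patterns never conflict
        expect_false(lc$insertions$conflicts_species_tree[j])
      }
    }
  }
  expect_true(found_informative)
  ## an N-run over the interval makes the carrier ambiguous
  lc <- NULL
  for (l in loci) if (nrow(l$insertions)) { lc <- l; break }
  j <- 1L
  iv <- c(lc$insertions$start_col[j], lc$insertions$end_col[j])
  carrier <- strsplit(lc$insertions$carriers[j], "|", fixed = TRUE)[[1]][1]
  rows <- lc$alignment$rows
  substr(rows[[carrier]], iv[1] + 1L, iv[2]) <-
    strrep("n", iv[2] - iv[1])
  noisy <- gene_alignment(rows, "nucleotide", lc$locus_id)
  pat <- call_presence_absence(noisy, iv)
  expect_equal(unname(pat$calls[carrier]), "ambiguous")
  expect_error(call_presence_absence(noisy, c(-1, 10)), "outside")
})

test_that("hypothesis tallies count implied splits with the 3-marker rule", {
  mk_pat <- function(present, absent, id = "p") {
    calls <- c(stats::setNames(rep("present", length(present)), present),
               stats::setNames(rep("absent", length(absent)), absent))
    structure(list(locus_id = id, calls = calls,
                   informative = length(present) %in% 2:3 &&
                     length(present) + length(absent) == 4,
                   present = present, absent = absent),
              class = "presence_pattern")
  }
  taxa <- c("Cow", "Dolphin", "Dog", "Horse")
  hyp <- list("Dolphin-Cow" = c("Cow", "Dolphin"),
              "Dog-Horse" = c("Dog", "Horse"))
  pats <- c(rep(list(mk_pat(c("Cow", "Dolphin"), c("Dog", "Horse"))), 7),
            rep(list(mk_pat(c("Cow", "Dolphin", "Dog"), "Horse")), 2))
  tl <- tally_support(pats, hyp, taxa = taxa)
  ## 7 cow+dolphin markers: significant; the complement split also counts
  ## for Dolphin-Cow?  no: a 3-present pattern implies the 3-clade
  expect_equal(tl$count[tl$hypothesis == "Dolphin-Cow"], 7L)
  expect_true(tl$significant[tl$hypothesis == "Dolphin-Cow"])
  ## the 2+2 split Dolphin-Cow equals its complement Dog-Horse
  expect_equal(tl$count[tl$hypothesis == "Dog-Horse"], 7L)
  two <- tally_support(pats[8:9], hyp, taxa = taxa)
  expect_false(any(two$significant))
  zero <- tally_support(list(), hyp, taxa = taxa)
  expect_true(all(zero$count == 0L))
})
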