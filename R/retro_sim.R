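## Synthetic retroposon (LINE1-like) insertion loci.  Each intron locus
## draws its own gene tree under the multispecies coalescent; insertions are
## Poisson events on gene-tree branches, inherited by all descendant species
## and never lost (Dollo), so a marker's presence set is always a gene-tree
## clade -- which may conflict with the species tree under incomplete
## lineage sorting (hemiplasy).

## fixed LINE1-like consensus chunk; repeated/truncated to the drawn length
.L1_CONSENSUS <- paste0(
  "ggaggagccaagatggccgaataggaacagctccggtctacagctcccagcgtgagcgac",
  "gcagaagacgggtgatttctgcatttccatctgaggtaccgggttcatctcactagggag",
  "tgccagacagtgggcgcaggccagtgtgtgtgcgcaccgtgcgcgagccgaagcagggcg",
  "aggcattgcctcacctgggaagcgcaaggggtcagggagttccctttccgagtcaaagaa")

.random_dna <- function(n) paste(sample(c("a", "c", "g", "t"), n, TRUE), collapse = "")

.mutate_seq <- function(seq, divergence) {
  ch <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(ch)) < divergence
  if (any(hit))
    ch[hit] <- vapply(ch[hit], function(s)
      sample(setdiff(c("a", "c", "g", "t"), s), 1L), character(1))
  paste(ch, collapse = "")
}

#' Simulate retroposon insertion loci
#'
#' For each of `config$n_introns` loci: a gene tree is drawn under the MSC
#' on `species_tree`; the intron plus `flank_length`-bp exon flanks evolve
#' along the gene tree (JC, scaled by the species tree's substitution
#' scale); LINE1-like insertions arise as Poisson events on gene-tree
#' branches (rate `insertion_rate` per coalescent unit), are inserted at a
#' uniform intron position, and are inherited by every descendant tip.  The
#' locus alignment places gap columns in non-carrier species, so loci come
#' out pre-aligned, and a truth table records each insertion's branch of
#' origin.
#'
#' @param species_tree rooted `phylo` in coalescent units (see
#'   [build_species_tree()]); its `substitution_scale` attribute maps
#'   coalescent units to substitutions/site
#' @param config a `synthetic_config`
#' @return list of `retro_locus` objects: each has `locus_id`, `alignment`
#'   (a `gene_alignment` with flanks and insertions), `flank_cols` (columns
#'   of the two exon flanks), `insertions` (data.frame: id, position
#'   columns, length, carriers, conflicts_species_tree), `gene_tree`, and
#'   `annotations` (RepeatMasker-style rows for carrier species)
#' @export
simulate_retro_loci <- function(species_tree, config) {
  stopifnot(inherits(config, "synthetic_config"))
  scale <- attr(species_tree, "substitution_scale") %||% 0.015
  sp_splits <- .clade_sets(species_tree)
  lapply(seq_len(config$n_introns), function(i) {
    set.seed(.child_seed(config$seed, i))
    .simulate_one_locus(species_tree, config, scale, sp_splits,
                        sprintf("intron%04d", i))
  })
}

## all clades (tip-label sets) of a rooted tree, as sorted key strings
.clade_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  out <- character(0)
  for (v in (ntip + 1L):(ntip + tree$Nnode)) {
    tips <- ape::extract.clade(tree, v)$tip.label
    out <- c(out, paste(sort(tips, method = "radix"), collapse = "|"))
  }
  c(out, tree$tip.label)
}

.simulate_one_locus <- function(species_tree, config, scale, sp_splits, id) {
  flank <- config$flank_length
  ilen <- sample(seq.int(config$intron_length_range[1],
                         config$intron_length_range[2]), 1L)
  gt <- simulate_gene_trees(species_tree, 1L)[[1]]
  gt_sub <- scale_to_substitutions(gt, scale)
  total_len <- as.integer(2L * flank + ilen)
  base <- simulate_alignment(gt_sub, jc_model(), total_len, locus_id = id)

  ## Poisson insertions on gene-tree branches (coalescent-unit lengths)
  ntip <- length(gt$tip.label)
  ins <- list()
  if (config$insertion_rate > 0) {
    for (e in seq_len(nrow(gt$edge))) {
      n_ins <- stats::rpois(1L, config$insertion_rate * gt$edge.length[e])
      if (n_ins == 0) next
      v <- gt$edge[e, 2]
      carriers <- if (v <= ntip) gt$tip.label[v]
                  else ape::extract.clade(gt, v)$tip.label
      for (j in seq_len(n_ins)) {
        len <- sample(100:500, 1L)
        l1 <- substring(strrep(.L1_CONSENSUS, len %/% nchar(.L1_CONSENSUS) + 1L),
                        1L, len)
        l1 <- .mutate_seq(l1, stats::runif(1L, 0.05, 0.15))
        pos <- sample.int(ilen - 1L, 1L)  # position within the intron
        ins[[length(ins) + 1L]] <- list(pos = flank + pos, len = len,
                                        seq = l1, carriers = carriers)
      }
    }
  }

  species <- names(base$rows)
  if (length(ins) == 0L) {
    insertions <- data.frame(insertion_id = character(0), start_col = integer(0),
                             end_col = integer(0), length = integer(0),
                             carriers = character(0),
                             conflicts_species_tree = logical(0))
    ann <- .annotate_insertions(base, insertions, flank)
    return(structure(list(locus_id = id, alignment = base,
                          flank_cols = c(flank, total_len - flank),
                          insertions = insertions, gene_tree = gt,
                          annotations = ann),
                     class = "retro_locus"))
  }

  ## splice insertion blocks into the base alignment, deepest position first
  ord <- order(vapply(ins, `[[`, 0, "pos"))
  ins <- ins[ord]
  rows <- lapply(stats::setNames(species, species),
                 function(sp) strsplit(base$rows[[sp]], "")[[1]])
  offset <- 0L
  meta <- list()
  for (j in seq_along(ins)) {
    x <- ins[[j]]
    at <- x$pos + offset           # 0-based: insert after column `at`
    blk <- strsplit(x$seq, "")[[1]]
    gap <- rep("-", x$len)
    for (sp in species) {
      piece <- if (sp %in% x$carriers) blk else gap
      rows[[sp]] <- append(rows[[sp]], piece, after = at)
    }
    key <- paste(sort(x$carriers, method = "radix"), collapse = "|")
    meta[[j]] <- data.frame(
      insertion_id = sprintf("%s_L1_%d", id, j),
      start_col = at, end_col = at + x$len,   # 0-based, half-open
      length = x$len,
      carriers = key,
      conflicts_species_tree = !(key %in% sp_splits))
    offset <- offset + x$len
  }
  aln <- gene_alignment(vapply(rows, paste, character(1), collapse = ""),
                        "nucleotide", id)
  insertions <- do.call(rbind, meta)
  ann <- .annotate_insertions(aln, insertions, flank)
  structure(list(locus_id = id, alignment = aln,
                 flank_cols = c(flank, aln$n_columns - flank),
                 insertions = insertions, gene_tree = gt, annotations = ann),
            class = "retro_locus")
}

## RepeatMasker-style annotation rows (one per carrier species per
## insertion), with coordinates in each species' ungapped sequence
.annotate_insertions <- function(aln, insertions, flank) {
  rows <- list()
  m <- if (nrow(insertions)) as_char_matrix(aln) else NULL
  for (j in seq_len(nrow(insertions))) {
    x <- insertions[j, ]
    carriers <- strsplit(x$carriers, "|", fixed = TRUE)[[1]]
    for (sp in carriers) {
      notgap <- m[sp, ] != "-"
      ung <- cumsum(notgap)
      start0 <- if (x$start_col == 0) 0L else ung[x$start_col]  # 0-based
      end0 <- ung[x$end_col]
      rows[[length(rows) + 1L]] <- data.frame(
        score = 2000L, divergence = 10.0, deletion = 0.0, insertion = 0.0,
        query = sprintf("%s|%s", aln$locus_id, sp),
        qbegin = start0 + 1L, qend = end0,   # RepeatMasker: 1-based inclusive
        qleft = sprintf("(%d)", sum(notgap) - end0),
        strand = "+", repeat_name = "L1_synth",
        repeat_class = "LINE/L1", rbegin = "1", rend = as.character(x$length),
        rleft = "(0)", rm_id = length(rows) + 1L)
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame()
}

#' Write a list of retro loci to disk
#'
#' Emits, per locus, a FASTA alignment; plus one RepeatMasker-.out-style
#' annotation table and one TSV truth table for the whole set.
#'
#' @param loci list of `retro_locus`
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_retro_loci <- function(loci, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  ann <- list(); truth <- list()
  for (lc in loci) {
    p <- file.path(dir, paste0(lc$locus_id, ".fasta"))
    write_fasta_alignment(lc$alignment, p)
    paths <- c(paths, p)
    if (nrow(lc$annotations)) ann[[length(ann) + 1L]] <- lc$annotations
    if (nrow(lc$insertions)) {
      tt <- lc$insertions
      tt$locus_id <- lc$locus_id
      truth[[length(truth) + 1L]] <- tt
    }
  }
  annp <- file.path(dir, "repeats.out")
  write_repeatmasker_out(if (length(ann)) do.call(rbind, ann) else data.frame(),
                         annp)
  tp <- file.path(dir, "insertion_truth.tsv")
  tdf <- if (length(truth)) do.call(rbind, truth) else
    data.frame(insertion_id = character(0))
  utils::write.table(tdf, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, annp, tp))
}

#' Write repeat annotations in RepeatMasker .out layout
#' @param ann annotation data.frame as produced by the locus simulator
#' @param path output path
#' @export
write_repeatmasker_out <- function(ann, path) {
  hdr <- c(
    "   SW   perc perc perc  query      position in query           matching       repeat              position in repeat",
    "score   div. del. ins.  sequence   begin  end        (left)    repeat         class/family      begin  end    (left)     ID",
    "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  for (j in seq_len(nrow(ann))) {
    x <- ann[j, ]
    writeLines(sprintf(
      "%5d %6.1f %4.1f %4.1f  %s %7d %7d %9s %s %-14s %-17s %6s %6s %9s %5d",
      x$score, x$divergence, x$deletion, x$insertion, x$query, x$qbegin,
      x$qend, x$qleft, x$strand, x$repeat_name, x$repeat_class, x$rbegin,
      x$rend, x$rleft, x$rm_id), con)
  }
  invisible(path)
}
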