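## In-silico retroposon presence/absence screen: intron harvesting with
## exon-flank anchors, RepeatMasker annotation intake restricted to LINE1,
## orthologous-intron anchoring by local flank alignment, explicit
## presence/absence calling on small multi-species alignments, and
## hypothesis tallies with the three-insertion significance convention.

#' Harvest introns from gene models
#'
#' Keeps introns with `min_len < length < max_len` (strict bounds) together
#' with fixed-length exon flanks; loci whose flank would run past the gene
#' are dropped and logged.  Minus-strand genes are normalized to gene
#' orientation.
#'
#' @param gene_models list of gene models: each a list with `gene_id`,
#'   `sequence` (the genomic span, gene orientation applied by `strand`),
#'   `exons` (matrix/data.frame of 0-based half-open `start`,`end` in
#'   plus-strand coordinates of `sequence`), `strand` ("+"/"-")
#' @param min_len,max_len strict intron length bounds (bp)
#' @param flank_len exon flank length (bp)
#' @return list with `introns` (each: gene_id, intron_index, up_flank,
#'   sequence, down_flank) and `dropped` (data.frame gene/reason)
#' @export
harvest_introns <- function(gene_models, min_len = 300L, max_len = 3000L,
                            flank_len = 80L) {
  introns <- list(); dropped <- list()
  note <- function(g, why) dropped[[length(dropped) + 1L]] <<-
    data.frame(gene = g, reason = why)
  for (gm in gene_models) {
    seqc <- tolower(gm$sequence)
    if (identical(gm$strand, "-")) seqc <- tolower(revcomp(seqc))
    ex <- as.matrix(as.data.frame(gm$exons)[, c("start", "end")])
    if (identical(gm$strand, "-")) {
      n <- nchar(seqc)
      ex <- cbind(start = n - ex[, "end"], end = n - ex[, "start"])
      ex <- ex[order(ex[, "start"]), , drop = FALSE]
    }
    if (nrow(ex) < 2L) next
    if (any(diff(ex[, "start"]) <= 0) || any(ex[, "end"] <= ex[, "start"]) ||
        any(ex[-1, "start"] < ex[-nrow(ex), "end"])) {
      note(gm$gene_id, "exons out of order"); next
    }
    for (i in seq_len(nrow(ex) - 1L)) {
      i_start <- ex[i, "end"]; i_end <- ex[i + 1L, "start"]
      ilen <- i_end - i_start
      if (!(ilen > min_len && ilen < max_len)) next
      if (i_start - flank_len < 0 || i_end + flank_len > nchar(seqc)) {
        note(gm$gene_id, sprintf("intron %d: flank truncated at gene boundary", i))
        next
      }
      introns[[length(introns) + 1L]] <- list(
        gene_id = gm$gene_id, intron_index = i,
        up_flank = substr(seqc, i_start - flank_len + 1L, i_start),
        sequence = substr(seqc, i_start + 1L, i_end),
        down_flank = substr(seqc, i_end + 1L, i_end + flank_len))
    }
  }
  list(introns = introns,
       dropped = if (length(dropped)) do.call(rbind, dropped)
                 else data.frame(gene = character(0), reason = character(0)))
}

#' Reverse complement
#' @param seq character string of nucleotides
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Parse RepeatMasker .out annotations, keeping LINE1 elements
#'
#' Standard .out column layout (score, divergence, deletions, insertions,
#' query, begin, end, left, strand, repeat name, class/family, ...).  Rows
#' whose class/family does not match LINE/L1 are discarded; coordinates are
#' converted from 1-based inclusive to 0-based half-open.  Malformed lines
#' are skipped and counted in the `skipped` attribute.
#'
#' @param path .out file path
#' @param family regular expression for the class/family filter
#' @return data.frame: query, start, end (0-based half-open), strand,
#'   repeat_name, repeat_class, score, divergence
#' @export
parse_repeat_annotations <- function(path, family = "^LINE/L1") {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  lines <- lines[!grepl("^\\s*(SW|score|There were no)", lines)]
  rows <- list(); skipped <- 0L
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    ok <- length(f) >= 11L && !is.na(suppressWarnings(as.integer(f[1]))) &&
      !is.na(suppressWarnings(as.integer(f[6]))) &&
      !is.na(suppressWarnings(as.integer(f[7])))
    if (!ok) { skipped <- skipped + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      query = f[5], start = as.integer(f[6]) - 1L, end = as.integer(f[7]),
      strand = if (f[9] %in% c("C", "-")) "-" else "+",
      repeat_name = f[10], repeat_class = f[11],
      score = as.integer(f[1]), divergence = as.numeric(f[2]))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query = character(0), start = integer(0), end = integer(0),
               strand = character(0), repeat_name = character(0),
               repeat_class = character(0), score = integer(0),
               divergence = numeric(0))
  if (skipped) .warnf("parse_repeat_annotations: skipped %d malformed line(s)", skipped)
  out <- out[grepl(family, out$repeat_class), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Anchor an orthologous intron in a target sequence
#'
#' Locally aligns the reference intron's upstream and downstream exon flanks
#' against the target (both strands; the better combined score wins); the
#' orthologous intron is the span between the upstream flank's end and the
#' downstream flank's start.  A flank placement is accepted when its local
#' alignment reaches `min_identity` over at least `min_len` aligned bases.
#'
#' @param ref list with `up_flank` and `down_flank` (see [harvest_introns()])
#' @param target_seq target gene sequence (plus strand)
#' @param min_identity flank identity threshold (default 0.7)
#' @param min_len minimum aligned flank length (default 60)
#' @param match,mismatch,gap_open,gap_extend local alignment scoring
#' @return list with `found` (logical), and when found: `start`, `end`
#'   (0-based half-open intron span in the returned orientation), `strand`,
#'   `sequence`
#' @export
anchor_orthologous_intron <- function(ref, target_seq, min_identity = 0.7,
                                      min_len = 60L, match = 1, mismatch = -1,
                                      gap_open = 5, gap_extend = 2) {
  target_seq <- tolower(target_seq)
  score_flank <- function(flank, subject) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(toupper(flank)),
      Biostrings::DNAString(toupper(subject)),
      type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = match, mismatch = mismatch, baseOnly = FALSE),
      gapOpening = gap_open, gapExtension = gap_extend)
    len <- Biostrings::nchar(al)
    ident <- Biostrings::pid(al) / 100
    list(score = Biostrings::score(al),
         ok = len >= min_len && ident >= min_identity,
         start = Biostrings::start(Biostrings::subject(al)) - 1L,
         end = Biostrings::end(Biostrings::subject(al)))
  }
  try_strand <- function(subject) {
    up <- score_flank(ref$up_flank, subject)
    dn <- score_flank(ref$down_flank, subject)
    list(up = up, dn = dn, score = up$score + dn$score)
  }
  fwd <- try_strand(target_seq)
  rev <- try_strand(revcomp(target_seq))
  pick <- if (rev$score > fwd$score) rev else fwd
  strand <- if (rev$score > fwd$score) "-" else "+"
  subject <- if (strand == "-") revcomp(target_seq) else target_seq
  if (!pick$up$ok || !pick$dn$ok) return(list(found = FALSE, reason = "flank below threshold"))
  i_start <- pick$up$end; i_end <- pick$dn$start
  if (i_end <= i_start) return(list(found = FALSE, reason = "flanks misordered"))
  list(found = TRUE, start = i_start, end = i_end, strand = strand,
       sequence = substr(subject, i_start + 1L, i_end))
}

#' Call retroposon presence/absence on a locus alignment
#'
#' For each species over the annotated LINE1 column interval: `present`
#' when at least `min_overlap` unambiguous bases fill the interval;
#' `absent` when at most `max_gap` non-gap characters intervene and the
#' flanking alignment continues on both sides (contiguous alignment across
#' the insertion point); `ambiguous` otherwise (e.g. N-runs).  The pattern
#' is informative when 2 or 3 of the focal species are present and the rest
#' absent.
#'
#' @param locus a `retro_locus` or `gene_alignment`
#' @param interval 0-based half-open column interval of the L1 element
#' @param focal_species species to call (default: all rows)
#' @param min_overlap bp of sequence required for presence (default 60)
#' @param max_gap residual bp allowed within the interval for absence
#'   (default 10)
#' @param flank_window bp window checked on each side for absence support
#' @return object of class `presence_pattern`: locus_id, calls (named
#'   character), informative, present, absent
#' @export
call_presence_absence <- function(locus, interval, focal_species = NULL,
                                  min_overlap = 60L, max_gap = 10L,
                                  flank_window = 20L) {
  aln <- if (inherits(locus, "retro_locus")) locus$alignment else locus
  id <- if (inherits(locus, "retro_locus")) locus$locus_id else aln$locus_id
  if (interval[1] < 0 || interval[2] > aln$n_columns || interval[2] <= interval[1])
    .stopf("interval [%d,%d) outside alignment (%d columns)",
           interval[1], interval[2], aln$n_columns)
  focal_species <- focal_species %||% names(aln$rows)
  m <- as_char_matrix(aln)
  cols <- (interval[1] + 1L):interval[2]
  calls <- vapply(focal_species, function(sp) {
    r <- m[sp, cols]
    solid <- sum(r %in% NT_STATES)
    filled <- sum(r != "-")
    if (solid >= min(min_overlap, length(cols))) return("present")
    if (filled <= max_gap && interval[1] > 0 && interval[2] < aln$n_columns) {
      left <- m[sp, max(1L, interval[1] - flank_window + 1L):interval[1]]
      right <- m[sp, (interval[2] + 1L):min(aln$n_columns, interval[2] + flank_window)]
      if (any(left != "-") && any(right != "-")) return("absent")
    }
    "ambiguous"
  }, character(1))
  n_pres <- sum(calls == "present"); n_abs <- sum(calls == "absent")
  informative <- n_pres %in% c(2L, 3L) && n_pres + n_abs == length(calls)
  structure(list(locus_id = id, calls = calls, informative = informative,
                 present = names(calls)[calls == "present"],
                 absent = names(calls)[calls == "absent"]),
            class = "presence_pattern")
}

#' Tally marker support for grouping hypotheses
#'
#' Each informative pattern increments every hypothesis whose split it
#' implies: the pattern's present set must equal the hypothesis side or its
#' complement within the focal taxon set.  A hypothesis is flagged
#' significant when supported by at least `sig_count` insertions (the
#' classic three-insertion criterion).
#'
#' @param patterns list of `presence_pattern`
#' @param hypotheses named list of character vectors (one side of each
#'   hypothesis split, in focal-taxon terms)
#' @param taxa the focal taxon set (default: union over patterns)
#' @param sig_count significance threshold (default 3)
#' @return data.frame (class `hypothesis_tally`): hypothesis, count,
#'   significant
#' @export
tally_support <- function(patterns, hypotheses, taxa = NULL, sig_count = 3L) {
  taxa <- taxa %||% sort(unique(unlist(lapply(patterns, function(p)
    names(p$calls)))), method = "radix")
  setequal_ <- function(a, b) length(a) == length(b) && setequal(a, b)
  counts <- stats::setNames(integer(length(hypotheses)), names(hypotheses))
  for (p in patterns) {
    if (!p$informative) next
    unknown <- setdiff(names(p$calls), taxa)
    if (length(unknown)) .stopf("pattern '%s' names unknown taxa: %s",
                                p$locus_id, paste(unknown, collapse = ", "))
    for (h in names(hypotheses)) {
      side <- hypotheses[[h]]
      if (setequal_(p$present, side) ||
          setequal_(p$present, setdiff(taxa, side)))
        counts[h] <- counts[h] + 1L
    }
  }
  out <- data.frame(hypothesis = names(counts), count = as.integer(counts),
                    significant = counts >= sig_count, row.names = NULL)
  class(out) <- c("hypothesis_tally", "data.frame")
  out
}
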