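## GeneAlignment: one locus's gapped sequences keyed by species.  Sequences
## are stored as lower-case character strings of equal length; the alphabet
## tag distinguishes nucleotide from amino-acid data.

#' Create a gene alignment
#'
#' @param rows named character vector, one gapped sequence per species
#' @param alphabet `"nucleotide"` or `"amino_acid"`
#' @param locus_id identifier used in reports and logs
#' @return an object of class `gene_alignment`
#' @export
gene_alignment <- function(rows, alphabet = c("nucleotide", "amino_acid"),
                           locus_id = "locus") {
  alphabet <- match.arg(alphabet)
  if (length(rows) == 0L) .stopf("alignment '%s' has no sequences", locus_id)
  if (is.null(names(rows)) || anyDuplicated(names(rows)))
    .stopf("alignment '%s': species names must be present and unique", locus_id)
  rows <- vapply(rows, tolower, character(1))
  len <- nchar(rows)
  if (length(unique(len)) != 1L)
    .stopf("alignment '%s' is ragged: '%s' has %d columns, expected %d",
           locus_id, names(rows)[which(len != len[1])[1]],
           len[which(len != len[1])[1]], len[1])
  structure(list(locus_id = locus_id, rows = rows, alphabet = alphabet,
                 n_columns = unname(len[1])),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("gene_alignment '%s': %d species x %d %s columns\n",
              x$locus_id, length(x$rows), x$n_columns, x$alphabet))
  invisible(x)
}

#' Split an alignment into a character matrix (species x columns)
#' @param aln a `gene_alignment`
#' @export
as_char_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  rownames(m) <- names(aln$rows)
  m
}

#' Read / write a FASTA alignment
#'
#' Reading enforces equal sequence lengths and names the offending record
#' otherwise; writing wraps sequences at 70 columns.  Round-tripping is the
#' identity up to line wrapping and case.
#'
#' @param path file path
#' @param alphabet `"nucleotide"`, `"amino_acid"` or `"auto"` (guess from
#'   residue composition)
#' @param locus_id locus identifier; defaults to the file name
#' @return `read_fasta_alignment`: a `gene_alignment`
#' @export
read_fasta_alignment <- function(path, alphabet = "auto", locus_id = NULL) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) .stopf("empty FASTA file: %s", path)
  rows <- stats::setNames(tolower(as.character(ss)),
                          sub("\\s.*$", "", names(ss)))
  if (identical(alphabet, "auto")) {
    resid <- unique(strsplit(paste(rows, collapse = ""), "")[[1]])
    resid <- setdiff(resid, c("-", "?", ".", "n", "x"))
    alphabet <- if (all(resid %in% names(NT_AMBIG))) "nucleotide" else "amino_acid"
  }
  len <- nchar(rows)
  if (length(unique(len)) != 1L) {
    bad <- names(rows)[which(len != len[1])[1]]
    .stopf("ragged alignment in %s: record '%s' has %d characters, expected %d",
           path, bad, nchar(rows[bad]), len[1])
  }
  gene_alignment(rows, alphabet,
                 locus_id = locus_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_fasta_alignment
#' @param aln a `gene_alignment`
#' @export
write_fasta_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in names(aln$rows)) {
    writeLines(paste0(">", sp), con)
    seq <- aln$rows[[sp]]
    starts <- seq.int(1L, nchar(seq), by = 70L)
    writeLines(substring(seq, starts, pmin(starts + 69L, nchar(seq))), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Back-translate an amino-acid alignment to nucleotides
#'
#' Each amino-acid column becomes three nucleotide columns; alignment gaps
#' become three-column gaps.  Every species' ungapped coding sequence must
#' translate (standard code) to its amino-acid row.
#'
#' @param aa_alignment amino-acid `gene_alignment`
#' @param cds named character vector of ungapped coding sequences
#' @return nucleotide `gene_alignment`
#' @export
back_translate <- function(aa_alignment, cds) {
  stopifnot(inherits(aa_alignment, "gene_alignment"),
            aa_alignment$alphabet == "amino_acid")
  out <- character(length(aa_alignment$rows))
  names(out) <- names(aa_alignment$rows)
  for (sp in names(aa_alignment$rows)) {
    if (is.null(cds[[sp]])) .stopf("no coding sequence for species '%s'", sp)
    aa <- strsplit(aa_alignment$rows[[sp]], "")[[1]]
    dna <- tolower(gsub("[^a-zA-Z]", "", cds[[sp]]))
    n_res <- sum(aa != "-")
    if (nchar(dna) != 3L * n_res)
      .stopf("species '%s': CDS length %d != 3 x %d aligned residues",
             sp, nchar(dna), n_res)
    codons <- substring(dna, seq(1L, nchar(dna), 3L), seq(3L, nchar(dna), 3L))
    tr <- tolower(as.character(Biostrings::translate(
      Biostrings::DNAStringSet(toupper(codons)), no.init.codon = TRUE)))
    ref <- aa[aa != "-"]
    bad <- which(tr != ref & ref != "x" & tr != "x")
    if (length(bad))
      .stopf("species '%s': codon %d ('%s') translates to '%s', alignment has '%s'",
             sp, bad[1], codons[bad[1]], tr[bad[1]], ref[bad[1]])
    pieces <- character(length(aa))
    pieces[aa == "-"] <- "---"
    pieces[aa != "-"] <- codons
    out[[sp]] <- paste(pieces, collapse = "")
  }
  gene_alignment(out, "nucleotide", locus_id = aa_alignment$locus_id)
}

## residues that count as determined for distance computation
.unambiguous <- function(m, alphabet) {
  if (alphabet == "nucleotide") m %in% NT_STATES else m %in% AA_STATES
}

#' Uncorrected pairwise distances
#'
#' p-distance for every species pair over columns where both sequences carry
#' an unambiguous residue (pairwise deletion), or over columns unambiguous
#' in all species (complete deletion).
#'
#' @param aln a `gene_alignment`
#' @param deletion `"pairwise"` (default) or `"complete"`
#' @return list with `distance` and `shared` (column-count) matrices
#' @export
p_distance_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- as_char_matrix(aln)
  ok <- matrix(.unambiguous(m, aln$alphabet), nrow = nrow(m))
  if (deletion == "complete") {
    keep <- colSums(ok) == nrow(m)
    m <- m[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- sh <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    both <- ok[i, ] & ok[j, ]
    sh[i, j] <- sh[j, i] <- sum(both)
    d[i, j] <- d[j, i] <- if (any(both)) mean(m[i, both] != m[j, both]) else NA_real_
  }
  list(distance = d, shared = sh)
}

#' Maximum-pairwise-divergence filter
#'
#' Discards an alignment when any species pair differs at more than
#' `threshold` of their shared unambiguous columns (default 30%).  Pairs
#' with no shared columns are ignored.
#'
#' @param aln a `gene_alignment` with at least 2 rows
#' @param threshold proportion in `[0, 1]`
#' @param deletion gap handling passed to [p_distance_matrix()]
#' @return list with `keep` (logical), `max_difference`, and `worst_pair`
#' @export
divergence_filter <- function(aln, threshold = 0.30,
                              deletion = c("pairwise", "complete")) {
  if (length(aln$rows) < 2L)
    .stopf("alignment '%s': divergence filter needs >= 2 sequences", aln$locus_id)
  pd <- p_distance_matrix(aln, deletion = match.arg(deletion))
  d <- pd$distance
  d[upper.tri(d, diag = TRUE)] <- NA
  if (all(is.na(d))) return(list(keep = TRUE, max_difference = NA_real_,
                                 worst_pair = c(NA, NA)))
  mx <- max(d, na.rm = TRUE)
  ij <- which(d == mx, arr.ind = TRUE)[1, ]
  list(keep = mx <= threshold, max_difference = mx,
       worst_pair = c(rownames(d)[ij[1]], colnames(d)[ij[2]]))
}

#' Concatenate loci into a supermatrix with a coverage report
#'
#' Species missing from a locus are padded with gaps.  Coverage counts
#' non-gap characters (ambiguity codes such as n/x count as covered).
#'
#' @param alignments list of `gene_alignment` objects sharing one alphabet
#' @return list with `alignment` (the supermatrix) and `coverage`
#'   (data.frame: species, percent non-gap, plus the overall mean as an
#'   attribute `mean_coverage`)
#' @export
concatenate <- function(alignments) {
  if (length(alignments) == 0L) .stopf("concatenate: empty alignment list")
  alpha <- unique(vapply(alignments, `[[`, "", "alphabet"))
  if (length(alpha) != 1L) .stopf("concatenate: mixed alphabets %s",
                                  paste(alpha, collapse = ", "))
  species <- unique(unlist(lapply(alignments, function(a) names(a$rows))))
  parts <- lapply(alignments, function(a) {
    pad <- strrep("-", a$n_columns)
    vapply(species, function(sp)
      if (sp %in% names(a$rows)) a$rows[[sp]] else pad, character(1))
  })
  rows <- do.call(paste0, parts)
  names(rows) <- species
  cat_aln <- gene_alignment(rows, alpha, locus_id = "concatenated")
  gapchars <- c("-", "?", ".")
  m <- as_char_matrix(cat_aln)
  cov <- 100 * apply(m, 1L, function(r) mean(!(r %in% gapchars)))
  coverage <- data.frame(species = species, percent_coverage = unname(cov))
  attr(coverage, "mean_coverage") <- mean(cov)
  list(alignment = cat_aln, coverage = coverage)
}
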