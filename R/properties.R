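## Influence of alignment properties on the favored topology: five per-gene
## properties, a median split into low/high groups, sole-best topology
## counts among the most likely trees, and 2xK chi-square tests of
## independence.

.STOP_CODONS <- c("taa", "tag", "tga")

#' Per-gene alignment properties
#'
#' Computes, per nucleotide alignment: alignment length (columns), longest
#' pairwise p-distance, sum of all pairwise p-distances, and the Euclidean
#' deviation of the gene's codon (61 sense codons) and nucleotide (4)
#' frequency vectors from the across-gene mean vectors.
#'
#' @param alignments list of nucleotide `gene_alignment`s; column counts
#'   must be multiples of 3 for the codon metric
#' @return data.frame: gene, alignment_length, longest_pairwise_distance,
#'   sum_pairwise_distances, codon_usage_deviation,
#'   nucleotide_usage_deviation
#' @export
compute_properties <- function(alignments) {
  if (!length(alignments)) .stopf("no alignments")
  codons <- apply(expand.grid(NT_STATES, NT_STATES, NT_STATES,
                              stringsAsFactors = FALSE)[, 3:1], 1L,
                  paste, collapse = "")
  sense <- setdiff(codons, .STOP_CODONS)
  per_gene <- lapply(alignments, function(aln) {
    if (aln$alphabet != "nucleotide") .stopf("'%s': nucleotide alignment required",
                                             aln$locus_id)
    if (aln$n_columns %% 3L != 0L)
      .stopf("'%s': column count %d is not a codon multiple",
             aln$locus_id, aln$n_columns)
    pd <- p_distance_matrix(aln)$distance
    d <- pd[lower.tri(pd)]
    d <- d[!is.na(d)]
    ## nucleotide frequencies over unambiguous residues
    m <- as_char_matrix(aln)
    resid <- m[m %in% NT_STATES]
    ntf <- tabulate(match(resid, NT_STATES), 4L)
    ntf <- ntf / sum(ntf)
    ## codon frequencies: ungapped, unambiguous codons pooled over species
    cod <- unlist(lapply(seq_len(nrow(m)), function(i) {
      s <- m[i, ]
      grp <- matrix(s, nrow = 3L)
      ok <- colSums(matrix(grp %in% NT_STATES, nrow = 3L)) == 3L
      apply(grp[, ok, drop = FALSE], 2L, paste, collapse = "")
    }))
    cod <- cod[!(cod %in% .STOP_CODONS)]
    cf <- tabulate(match(cod, sense), length(sense))
    cf <- if (sum(cf)) cf / sum(cf) else rep(0, length(sense))
    list(gene = aln$locus_id, len = aln$n_columns,
         longest = if (length(d)) max(d) else 0,
         sumd = if (length(d)) sum(d) else 0, ntf = ntf, cf = cf)
  })
  nt_mean <- rowMeans(vapply(per_gene, `[[`, numeric(4), "ntf"))
  cf_mean <- rowMeans(vapply(per_gene, `[[`, numeric(length(sense)), "cf"))
  data.frame(
    gene = vapply(per_gene, `[[`, "", "gene"),
    alignment_length = vapply(per_gene, `[[`, 0, "len"),
    longest_pairwise_distance = vapply(per_gene, `[[`, 0, "longest"),
    sum_pairwise_distances = vapply(per_gene, `[[`, 0, "sumd"),
    codon_usage_deviation = vapply(per_gene, function(x)
      sqrt(sum((x$cf - cf_mean)^2)), 0),
    nucleotide_usage_deviation = vapply(per_gene, function(x)
      sqrt(sum((x$ntf - nt_mean)^2)), 0),
    row.names = NULL)
}

#' Median split into equal-sized low/high groups
#'
#' Genes are ordered by value with ties broken by id (stable, documented
#' tie-break); the first half (extra member on the low side for odd counts)
#' forms the low group.
#'
#' @param values numeric vector
#' @param ids identifiers aligned with `values` (default: index)
#' @return list with `low` and `high` id vectors
#' @export
median_split <- function(values, ids = as.character(seq_along(values))) {
  if (length(values) < 2L) .stopf("median split needs >= 2 values")
  ord <- order(values, ids, method = "radix")
  n_low <- ceiling(length(values) / 2)
  list(low = ids[ord[seq_len(n_low)]],
       high = ids[ord[(n_low + 1L):length(values)]])
}

#' Sole-best topology counts within a gene group
#'
#' Counts, for each topology in `top_trees`, the genes (restricted to
#' `group`) where that topology is the unique maximum over ALL topologies
#' (uniqueness within `equal_tol`).  Genes with a tie at the top contribute
#' to no topology.
#'
#' @param matrix a `gene_score_matrix` or genes x topologies matrix
#' @param group gene ids forming the group
#' @param top_trees topology ids to report (the most likely trees)
#' @param equal_tol uniqueness tolerance
#' @return named integer vector of counts, one per `top_trees` entry
#' @export
sole_best_counts <- function(matrix, group, top_trees, equal_tol = 0.01) {
  if (inherits(matrix, "gene_score_matrix")) matrix <- matrix$scores
  if (!length(group)) .stopf("empty group")
  miss <- setdiff(as.character(top_trees), colnames(matrix))
  if (length(miss)) .stopf("unknown topologies: %s", paste(miss, collapse = ", "))
  sub <- matrix[rownames(matrix) %in% group, , drop = FALSE]
  counts <- stats::setNames(integer(length(top_trees)), as.character(top_trees))
  for (g in seq_len(nrow(sub))) {
    row <- sub[g, ]
    top <- which(row >= max(row) - equal_tol)
    if (length(top) == 1L) {
      id <- colnames(sub)[top]
      if (id %in% names(counts)) counts[id] <- counts[id] + 1L
    }
  }
  counts
}

#' Pearson chi-square test on a 2 x K contingency table
#'
#' Plain Pearson statistic of independence with no continuity correction;
#' df = K - 1 for two rows.
#'
#' @param table 2 x K matrix of non-negative counts
#' @return list (class `chi_square_result`): statistic, df, p_value
#' @export
chi_square_2xk <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 2L) .stopf("need exactly 2 rows")
  if (any(table < 0)) .stopf("negative counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    .stopf("degenerate margins (zero row or column sum)")
  E <- outer(rowSums(table), colSums(table)) / sum(table)
  stat <- sum((table - E)^2 / E)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("chi-square = %.4f, df = %d, p = %.4g\n", x$statistic, x$df,
              x$p_value))
  invisible(x)
}

#' Full property-influence analysis
#'
#' For each of the five properties: median-split the genes, count sole-best
#' topologies among `top_trees` in the low and high groups, and test the
#' two count distributions for independence with a 2xK chi-square.
#'
#' @param alignments list of nucleotide `gene_alignment`s
#' @param matrix a `gene_score_matrix` over the same genes
#' @param top_trees topology ids to compare (the most likely trees)
#' @param equal_tol uniqueness tolerance for "sole best"
#' @return data.frame: property, group, one column per topology, chi_square,
#'   df, p_value
#' @export
property_influence <- function(alignments, matrix, top_trees,
                               equal_tol = 0.01) {
  props <- compute_properties(alignments)
  measures <- c("alignment_length", "longest_pairwise_distance",
                "sum_pairwise_distances", "codon_usage_deviation",
                "nucleotide_usage_deviation")
  rows <- list()
  for (ms in measures) {
    grp <- median_split(props[[ms]], props$gene)
    lo <- sole_best_counts(matrix, grp$low, top_trees, equal_tol)
    hi <- sole_best_counts(matrix, grp$high, top_trees, equal_tol)
    tab <- rbind(lo, hi)
    chi <- tryCatch(chi_square_2xk(tab), error = function(e) NULL)
    for (side in c("low", "high")) {
      cnt <- if (side == "low") lo else hi
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(property = ms, group = side),
        as.data.frame(as.list(cnt), check.names = FALSE),
        data.frame(chi_square = chi$statistic %||% NA_real_,
                   df = chi$df %||% NA_integer_,
                   p_value = chi$p_value %||% NA_real_))
    }
  }
  do.call(rbind, rows)
}
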