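## Weighted split systems: splits harvested from gene-tree sets (threshold
## consensus networks) or from retroposon marker tallies, exported in the
## SplitsTree4 ST_SPLITS NEXUS dialect for network drawing.

#' Create a split system
#'
#' Splits are canonicalized as the side NOT containing the reference taxon
#' (the alphabetically first), which prevents duplicate orientations.
#'
#' @param taxa character vector of taxon names
#' @param sides list of character vectors (one side of each split)
#' @param weights numeric weights (frequencies or raw counts), same length
#' @return object of class `split_system`
#' @export
split_system <- function(taxa, sides = list(), weights = numeric()) {
  taxa <- sort(unique(as.character(taxa)), method = "radix")
  if (length(sides) != length(weights)) .stopf("sides/weights length mismatch")
  canon <- lapply(sides, .canon_split, taxa = taxa)
  keys <- vapply(canon, paste, "", collapse = "|")
  if (anyDuplicated(keys)) .stopf("duplicate splits")
  if (any(weights <= 0)) .stopf("split weights must be positive")
  structure(list(taxa = taxa, sides = canon, weights = as.numeric(weights)),
            class = "split_system")
}

.canon_split <- function(side, taxa) {
  side <- unique(as.character(side))
  if (!all(side %in% taxa)) .stopf("split names taxa outside the taxon set: %s",
                                   paste(setdiff(side, taxa), collapse = ", "))
  if (length(side) == 0L || length(side) == length(taxa))
    .stopf("a split must be a proper bipartition")
  if (taxa[1] %in% side) side <- setdiff(taxa, side)
  sort(side, method = "radix")
}

#' @export
print.split_system <- function(x, ...) {
  cat(sprintf("split_system: %d taxa, %d splits\n", length(x$taxa),
              length(x$sides)))
  invisible(x)
}

#' Splits displayed by a tree
#'
#' One split per edge under the unrooted interpretation (the two root edges
#' of a rooted tree yield the same split and are merged).
#'
#' @param tree leaf-labelled `phylo`
#' @return list of canonical split sides (character vectors)
#' @export
tree_splits <- function(tree) {
  taxa <- sort(tree$tip.label, method = "radix")
  ntip <- length(taxa)
  sides <- list()
  keys <- character(0)
  for (i in seq_len(nrow(tree$edge))) {
    v <- tree$edge[i, 2]
    tips <- if (v <= ntip) tree$tip.label[v]
            else ape::extract.clade(tree, v)$tip.label
    if (length(tips) == ntip) next
    side <- .canon_split(tips, taxa)
    key <- paste(side, collapse = "|")
    if (!(key %in% keys)) { sides[[length(sides) + 1L]] <- side; keys <- c(keys, key) }
  }
  sides
}

#' Threshold consensus splits from a set of gene trees
#'
#' Split frequency = fraction of input trees displaying the split; splits
#' with frequency >= `threshold` are retained (8% is the conventional
#' display threshold for heavily conflicting gene-tree sets).
#'
#' @param trees list of `phylo` on the same leaf set
#' @param threshold frequency threshold in `[0, 1]`
#' @return a `split_system` with frequency weights
#' @export
consensus_splits <- function(trees, threshold = 0.08) {
  if (!length(trees)) .stopf("no trees")
  if (threshold < 0 || threshold > 1) .stopf("threshold must be in [0,1]")
  taxa <- sort(trees[[1]]$tip.label, method = "radix")
  for (tr in trees)
    if (!identical(sort(tr$tip.label, method = "radix"), taxa))
      .stopf("trees have inconsistent leaf sets")
  counts <- new.env(parent = emptyenv())
  for (tr in trees) {
    for (side in tree_splits(tr)) {
      key <- paste(side, collapse = "|")
      counts[[key]] <- (counts[[key]] %||% 0) + 1
    }
  }
  keys <- ls(counts)
  freq <- vapply(keys, function(k) counts[[k]] / length(trees), numeric(1))
  keep <- freq >= threshold & freq > 0
  split_system(taxa,
               sides = lapply(keys[keep], function(k)
                 strsplit(k, "|", fixed = TRUE)[[1]]),
               weights = freq[keep])
}

#' Split network from retroposon marker tallies
#'
#' Each supported grouping hypothesis becomes a split weighted by its raw
#' marker count (the display convention where branch lengths equal the
#' number of insertions supporting each topology); zero-count hypotheses
#' are omitted.
#'
#' @param tallies named numeric vector; names are split sides with taxa
#'   joined by `+` (e.g. `"Carnivora+Perissodactyla"`)
#' @param taxa the full taxon set of the network
#' @return a `split_system` with count weights
#' @export
marker_split_network <- function(tallies, taxa) {
  if (any(tallies < 0)) .stopf("marker counts must be >= 0")
  keep <- tallies > 0
  sides <- lapply(names(tallies)[keep], function(nm)
    strsplit(nm, "+", fixed = TRUE)[[1]])
  split_system(taxa, sides = sides, weights = unname(tallies[keep]))
}

#' Are two splits compatible?
#' @param a,b split sides (character vectors)
#' @param taxa full taxon set
#' @export
splits_compatible <- function(a, b, taxa) {
  A1 <- a; A2 <- setdiff(taxa, a); B1 <- b; B2 <- setdiff(taxa, b)
  !length(intersect(A1, B1)) || !length(intersect(A1, B2)) ||
    !length(intersect(A2, B1)) || !length(intersect(A2, B2))
}

#' Write / read a split system in SplitsTree4 NEXUS format
#'
#' Writes TAXA and ST_SPLITS blocks; weights serialized to 6 decimals in a
#' stable (radix key) order, so output is deterministic and round-trips
#' through `read_splits_nexus`.
#'
#' @param system a `split_system`
#' @param path file path
#' @export
write_splits_nexus <- function(system, path) {
  if (!length(system$taxa)) .stopf("empty taxon set")
  keys <- vapply(system$sides, paste, "", collapse = "|")
  ord <- order(keys, method = "radix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines(sprintf("BEGIN TAXA;\nDIMENSIONS NTAX=%d;\nTAXLABELS",
                     length(system$taxa)), con)
  writeLines(paste0("\t'", system$taxa, "'"), con)
  writeLines(";\nEND;", con)
  writeLines(sprintf(
    "BEGIN ST_SPLITS;\nDIMENSIONS NTAX=%d NSPLITS=%d;\nFORMAT LABELS=NO WEIGHTS=YES;\nMATRIX",
    length(system$taxa), length(system$sides)), con)
  for (i in seq_along(ord)) {
    j <- ord[i]
    idx <- match(system$sides[[j]], system$taxa)
    writeLines(sprintf("[%d]\t%.6f\t%s,", i, system$weights[j],
                       paste(sort(idx), collapse = " ")), con)
  }
  writeLines(";\nEND;", con)
  invisible(path)
}

#' @rdname write_splits_nexus
#' @export
read_splits_nexus <- function(path) {
  lines <- readLines(path)
  tx_start <- grep("^TAXLABELS", lines)
  if (!length(tx_start)) .stopf("no TAXLABELS block in %s", path)
  taxa <- character(0)
  i <- tx_start + 1L
  while (!grepl("^;", lines[i])) {
    taxa <- c(taxa, gsub("^\\s*'|'\\s*$", "", trimws(lines[i])))
    i <- i + 1L
  }
  mx <- grep("^MATRIX", lines)
  if (!length(mx)) .stopf("no MATRIX in %s", path)
  sides <- list(); weights <- numeric(0)
  i <- mx + 1L
  while (i <= length(lines) && !grepl("^;", lines[i])) {
    ln <- trimws(sub(",\\s*$", "", lines[i]))
    parts <- strsplit(ln, "\\s+")[[1]]
    parts <- parts[!grepl("^\\[", parts)]
    w <- as.numeric(parts[1])
    idx <- as.integer(parts[-1])
    sides[[length(sides) + 1L]] <- taxa[idx]
    weights <- c(weights, w)
    i <- i + 1L
  }
  split_system(taxa, sides, weights)
}
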