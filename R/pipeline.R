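## End-to-end orchestration: one configuration object drives simulation,
## filtering, scoring, census, SH testing, networks, property influence,
## retroposon screening and dating, writing TSV/NEXUS/Newick artifacts and
## a run manifest with per-stage exclusion logs.

#' Pipeline configuration
#'
#' All thresholds of the analysis live here with their conventional
#' defaults: the 30% divergence filter, census tie/reject margins, SH
#' replicate count, the 8% network threshold, the presence/absence calling
#' thresholds and the three-insertion significance rule.
#'
#' @param species_tree a [species_tree_spec()]
#' @param synthetic a [synthetic_config()]
#' @param stages character vector of stages to run (default: all)
#' @param divergence_threshold max pairwise difference (default 0.30)
#' @param equal_tol,reject_margin census rules (ML defaults)
#' @param sh_replicates RELL replicates for the SH test
#' @param network_threshold consensus-network split frequency threshold
#' @param marker_sig_count markers needed for significance (default 3)
#' @param min_overlap,max_gap presence/absence calling thresholds
#' @param fixed_root_age root age (Ma) for the dating stage
#' @param seed master seed
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(species_tree = species_tree_spec(),
                            synthetic = synthetic_config(),
                            stages = c("simulate", "filter", "score",
                                       "census", "shtest", "network",
                                       "properties", "retro", "date"),
                            divergence_threshold = 0.30,
                            equal_tol = 0.01, reject_margin = 2,
                            sh_replicates = 10000L,
                            network_threshold = 0.08,
                            marker_sig_count = 3L,
                            min_overlap = 60L, max_gap = 10L,
                            fixed_root_age = 92,
                            seed = 1L) {
  stopifnot(divergence_threshold >= 0, divergence_threshold <= 1,
            network_threshold >= 0, network_threshold <= 1,
            reject_margin >= 0, equal_tol >= 0)
  structure(list(species_tree = species_tree, synthetic = synthetic,
                 stages = stages,
                 divergence_threshold = divergence_threshold,
                 equal_tol = equal_tol, reject_margin = reject_margin,
                 sh_replicates = as.integer(sh_replicates),
                 network_threshold = network_threshold,
                 marker_sig_count = as.integer(marker_sig_count),
                 min_overlap = as.integer(min_overlap),
                 max_gap = as.integer(max_gap),
                 fixed_root_age = fixed_root_age,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration (JSON)
#' @param config a `pipeline_config`
#' @param path file path
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$species_tree <- unclass(x$species_tree)
  syn <- unclass(x$synthetic)
  syn$model <- list(kind = syn$model$kind,
                    rates = syn$model$exchangeabilities[
                      lower.tri(syn$model$exchangeabilities)],
                    freqs = syn$model$freqs, alpha = syn$model$alpha,
                    pinv = syn$model$pinv, ncat = syn$model$ncat)
  if (syn$model$kind != "GTR") syn$model$rates <- NULL
  x$synthetic <- syn
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- x$species_tree
  ## within_order_subtrees may come back as a list of vectors or NULL/empty
  wos <- st$within_order_subtrees
  if (!is.null(wos) && !length(wos)) wos <- NULL
  spec <- species_tree_spec(st$topology_id, st$internal_branch_lengths,
                            wos, st$outgroups, st$ingroup_depth,
                            st$outgroup_depth, st$substitution_scale)
  m <- x$synthetic$model
  model <- switch(m$kind,
                  JC = jc_model(m$alpha, m$pinv, m$ncat),
                  WAG = wag_model(m$alpha, m$pinv, m$ncat),
                  gtr_model(m$rates, m$freqs, m$alpha, m$pinv, m$ncat))
  syn <- synthetic_config(x$synthetic$n_genes, x$synthetic$gene_length,
                          model, x$synthetic$insertion_rate,
                          x$synthetic$n_introns,
                          x$synthetic$intron_length_range,
                          x$synthetic$flank_length, x$synthetic$seed)
  pipeline_config(spec, syn, x$stages, x$divergence_threshold, x$equal_tol,
                  x$reject_margin, x$sh_replicates, x$network_threshold,
                  x$marker_sig_count, x$min_overlap, x$max_gap,
                  x$fixed_root_age, x$seed)
}

#' Run the full synthetic analysis pipeline
#'
#' Deterministic given the configuration seed.  Emits per-stage artifacts
#' under `out_dir` (TSV tables, NEXUS split networks, Newick trees, FASTA
#' loci) plus `manifest.json` recording thresholds, seeds, stage status and
#' every exclusion with its reason.
#'
#' @param config a `pipeline_config`
#' @param out_dir output directory
#' @return invisibly, a list of in-memory stage results
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  res <- list()
  manifest <- list(package_version = as.character(utils::packageVersion("phyloconflict")),
                   seed = config$seed,
                   thresholds = list(
                     divergence = config$divergence_threshold,
                     equal_tol = config$equal_tol,
                     reject_margin = config$reject_margin,
                     sh_replicates = config$sh_replicates,
                     network_threshold = config$network_threshold,
                     marker_sig_count = config$marker_sig_count,
                     min_overlap = config$min_overlap,
                     max_gap = config$max_gap),
                   stages = list(), exclusions = list())
  fail <- function(stage, msg) .stopf("pipeline stage '%s' failed: %s", stage, msg)

  sp_tree <- build_species_tree(config$species_tree)
  ape::write.tree(sp_tree, file.path(out_dir, "species_tree.nwk"))
  model <- config$synthetic$model
  scale <- config$species_tree$substitution_scale

  ## simulate -----------------------------------------------------------
  if ("simulate" %in% stages) {
    syn <- config$synthetic
    gts <- simulate_gene_trees(sp_tree, syn$n_genes,
                               seed = .child_seed(config$seed, 1L))
    alns <- vector("list", syn$n_genes)
    for (i in seq_len(syn$n_genes)) {
      glen <- if (is.function(syn$gene_length)) syn$gene_length() else syn$gene_length
      alns[[i]] <- simulate_alignment(scale_to_substitutions(gts[[i]], scale),
                                      model, glen,
                                      seed = .child_seed(config$seed, 1000L + i),
                                      locus_id = sprintf("gene%04d", i))
    }
    gene_dir <- file.path(out_dir, "genes")
    dir.create(gene_dir, showWarnings = FALSE)
    for (a in alns) write_fasta_alignment(a, file.path(gene_dir, paste0(a$locus_id, ".fasta")))
    writeLines(vapply(gts, function(g) ape::write.tree(g), ""),
               file.path(out_dir, "gene_trees.nwk"))
    res$gene_trees <- gts; res$alignments <- alns
    manifest$stages$simulate <- list(status = "done", n_genes = syn$n_genes)
  } else manifest$stages$simulate <- list(status = "skipped")

  ## filter --------------------------------------------------------------
  if ("filter" %in% stages && !is.null(res$alignments)) {
    keep <- logical(length(res$alignments))
    log_lines <- character(0)
    for (i in seq_along(res$alignments)) {
      f <- divergence_filter(res$alignments[[i]], config$divergence_threshold)
      keep[i] <- f$keep
      if (!f$keep) {
        log_lines <- c(log_lines, sprintf(
          "%s\tdiscarded\tmax pairwise difference %.4f > %.2f (%s vs %s)",
          res$alignments[[i]]$locus_id, f$max_difference,
          config$divergence_threshold, f$worst_pair[1], f$worst_pair[2]))
        manifest$exclusions[[length(manifest$exclusions) + 1L]] <-
          list(stage = "filter", id = res$alignments[[i]]$locus_id,
               reason = "divergence_filter")
      }
    }
    writeLines(log_lines, file.path(out_dir, "filter.log"))
    res$alignments <- res$alignments[keep]
    res$gene_trees <- res$gene_trees[keep]
    manifest$stages$filter <- list(status = "done", kept = sum(keep),
                                   discarded = sum(!keep))
  } else manifest$stages$filter <- list(status = "skipped")

  ## score ---------------------------------------------------------------
  topo_set <- lapply(order_topologies(), function(t)
    graft(t, as.list(stats::setNames(FOCAL_ORDERS, FOCAL_ORDERS)),
          config$species_tree$outgroups))
  if ("score" %in% stages && length(res$alignments)) {
    gsm <- score_genes(res$alignments, topo_set, model)
    utils::write.table(
      data.frame(gene = rownames(gsm$scores), gsm$scores, check.names = FALSE),
      file.path(out_dir, "gene_scores.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    for (i in seq_len(nrow(gsm$failures)))
      manifest$exclusions[[length(manifest$exclusions) + 1L]] <-
        list(stage = "score", id = gsm$failures$gene[i],
             reason = gsm$failures$reason[i])
    res$scores <- gsm
    manifest$stages$score <- list(status = "done",
                                  n_genes = nrow(gsm$scores),
                                  n_failures = nrow(gsm$failures))
  } else manifest$stages$score <- list(status = "skipped")

  ## census --------------------------------------------------------------
  if ("census" %in% stages && !is.null(res$scores)) {
    ct <- tally(res$scores, config$equal_tol, config$reject_margin)
    utils::write.table(ct, file.path(out_dir, "census.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res$census <- ct
    manifest$stages$census <- list(status = "done")
  } else manifest$stages$census <- list(status = "skipped")

  ## shtest --------------------------------------------------------------
  if ("shtest" %in% stages && length(res$alignments)) {
    cc <- concatenate(res$alignments)
    concat <- cc$alignment
    utils::write.table(cc$coverage, file.path(out_dir, "coverage.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pdc <- .pattern_data(concat, model,
                         sort(topo_set[[1]]$tip.label, method = "radix"))
    sll <- lapply(topo_set, function(tp) {
      tp$edge.length <- rep(0.1, nrow(tp$edge))
      .run_cpp_engine(tp, model, pdc)$loglik$per_site
    })
    sh <- sh_test(sll, config$sh_replicates,
                  seed = .child_seed(config$seed, 7L))
    utils::write.table(sh, file.path(out_dir, "sh_test.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res$sh <- sh
    manifest$stages$shtest <- list(status = "done")
  } else manifest$stages$shtest <- list(status = "skipped")

  ## network -------------------------------------------------------------
  if ("network" %in% stages && !is.null(res$scores)) {
    best_trees <- best_tree_per_gene(res$scores, topo_set)
    ns <- consensus_splits(best_trees, config$network_threshold)
    write_splits_nexus(ns, file.path(out_dir, "consensus_network.nex"))
    res$network <- ns
    manifest$stages$network <- list(status = "done", n_splits = length(ns$sides))
  } else manifest$stages$network <- list(status = "skipped")

  ## properties ----------------------------------------------------------
  if ("properties" %in% stages && !is.null(res$scores) &&
      length(res$alignments)) {
    sums <- colSums(res$scores$scores)
    top5 <- names(sort(sums, decreasing = TRUE))[1:5]
    pi_tab <- property_influence(res$alignments, res$scores, top5,
                                 config$equal_tol)
    utils::write.table(pi_tab, file.path(out_dir, "property_influence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$properties <- pi_tab
    manifest$stages$properties <- list(status = "done", top_trees = top5)
  } else manifest$stages$properties <- list(status = "skipped")

  ## retro ---------------------------------------------------------------
  if ("retro" %in% stages) {
    loci <- simulate_retro_loci(sp_tree, config$synthetic)
    retro_dir <- file.path(out_dir, "retro")
    write_retro_loci(loci, retro_dir)
    focal <- .focal_tips(config$species_tree)
    patterns <- list()
    for (lc in loci) {
      for (j in seq_len(nrow(lc$insertions))) {
        patterns[[length(patterns) + 1L]] <- call_presence_absence(
          lc, c(lc$insertions$start_col[j], lc$insertions$end_col[j]),
          focal_species = focal, min_overlap = config$min_overlap,
          max_gap = config$max_gap)
      }
    }
    hyps <- .default_hypotheses(focal)
    tally_df <- tally_support(patterns, hyps, taxa = focal,
                              sig_count = config$marker_sig_count)
    utils::write.table(tally_df, file.path(out_dir, "retro_tally.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts <- stats::setNames(tally_df$count,
                              vapply(hyps, paste, "", collapse = "+"))
    if (any(counts > 0)) {
      mn <- marker_split_network(counts, c(focal, "Outgroup"))
      write_splits_nexus(mn, file.path(out_dir, "retro_network.nex"))
    }
    res$retro <- list(loci = loci, patterns = patterns, tally = tally_df)
    manifest$stages$retro <- list(status = "done", n_loci = length(loci),
                                  n_informative = sum(vapply(patterns,
                                    `[[`, TRUE, "informative")))
  } else manifest$stages$retro <- list(status = "skipped")

  ## date ----------------------------------------------------------------
  if ("date" %in% stages && length(res$alignments)) {
    concat <- concatenate(res$alignments)$alignment
    best_topo <- if (!is.null(res$scores)) {
      topo_set[[which.max(colSums(res$scores$scores))]]
    } else topo_set[["14"]]
    fit <- optimize_branch_lengths(concat, best_topo, model)
    chrono <- nprs_log_date(fit$tree, fixed_root_age = config$fixed_root_age,
                            seed = .child_seed(config$seed, 9L))
    ape::write.tree(chrono$tree, file.path(out_dir, "chronogram.nwk"))
    res$chronogram <- chrono
    manifest$stages$date <- list(status = "done",
                                 root_age = config$fixed_root_age)
  } else manifest$stages$date <- list(status = "skipped")

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(res)
}

## focal species: one representative per order (first subtree tip)
.focal_tips <- function(spec) {
  if (is.null(spec$within_order_subtrees)) return(FOCAL_ORDERS)
  vapply(FOCAL_ORDERS, function(o)
    (spec$within_order_subtrees[[o]] %||% o)[1], character(1))
}

## the standard grouping hypotheses over 4 focal taxa: each singleton
## ("X first divergence") and each of the three 2+2 groupings
.default_hypotheses <- function(focal) {
  h <- as.list(stats::setNames(focal, paste0(focal, "_first")))
  pairs <- utils::combn(focal[-1], 2, simplify = FALSE)  # pairs excluding first
  for (p in pairs) h[[paste(p, collapse = "+")]] <- p
  h
}

#' Best-scoring grafted tree per gene
#' @param gsm a `gene_score_matrix`
#' @param topo_set named list of grafted topologies matching the columns
#' @export
best_tree_per_gene <- function(gsm, topo_set) {
  scores <- gsm$scores
  lapply(seq_len(nrow(scores)), function(g) {
    topo_set[[which.max(scores[g, ])]]  # ties: lowest topology id (documented)
  })
}
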