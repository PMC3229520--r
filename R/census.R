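## Per-gene "separate" analysis: score every candidate topology on every
## gene, tally how often each topology is among the best and how often it is
## rejected, sum log-likelihood differences, and run the
## Shimodaira-Hasegawa test with RELL resampling on concatenated data.

#' Score genes against a set of candidate topologies
#'
#' Optimizes branch lengths for every (gene, topology) pair and records the
#' maximized log-likelihood.  Genes failing optimization are excluded from
#' the matrix and logged with a reason, mirroring how failed optimizations
#' are dropped rather than imputed.
#'
#' @param alignments list of `gene_alignment` objects
#' @param topologies named list of `phylo` topologies (tips must be present
#'   in every alignment)
#' @param model a `substitution_model`
#' @param engine `"internal"` (this package's optimizer) or `"phangorn"`
#' @param optimize_model re-estimate model parameters per gene (slow)
#' @param per_site keep per-site log-likelihood vectors (needed for SH)
#' @return object of class `gene_score_matrix`: list with `scores` (genes x
#'   topologies), `mode = "ML"`, `site_logliks` (optional), `failures`
#'   (data.frame gene/reason)
#' @export
score_genes <- function(alignments, topologies, model,
                        engine = c("internal", "phangorn"),
                        optimize_model = FALSE, per_site = FALSE) {
  engine <- match.arg(engine)
  if (is.null(names(topologies)))
    names(topologies) <- as.character(seq_along(topologies))
  gene_ids <- vapply(alignments, `[[`, "", "locus_id")
  if (anyDuplicated(gene_ids)) .stopf("duplicate locus ids")
  scores <- matrix(NA_real_, length(alignments), length(topologies),
                   dimnames = list(gene_ids, names(topologies)))
  site_ll <- if (per_site) vector("list", length(alignments)) else NULL
  failures <- list()
  taxa <- sort(topologies[[1]]$tip.label, method = "radix")
  for (g in seq_along(alignments)) {
    aln <- alignments[[g]]
    res <- tryCatch({
      pd <- .pattern_data(aln, model, taxa)
      row <- numeric(length(topologies))
      sll <- if (per_site) vector("list", length(topologies)) else NULL
      for (t in seq_along(topologies)) {
        topo <- topologies[[t]]
        if (is.null(topo$edge.length))
          topo$edge.length <- rep(0.1, nrow(topo$edge))
        fit <- if (engine == "phangorn") {
          .phangorn_fit(aln, topo, model, optimize_model)
        } else if (optimize_model) {
          optimize_branch_lengths(aln, topo, model, optimize_model = TRUE,
                                  method = "R")
        } else {
          .run_cpp_engine(topo, model, pd)
        }
        row[t] <- fit$loglik$total
        if (per_site) sll[[t]] <- fit$loglik$per_site
      }
      list(row = row, sll = sll)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(gene = gene_ids[g], reason = conditionMessage(res))
    } else {
      scores[g, ] <- res$row
      if (per_site) site_ll[[g]] <- res$sll
    }
  }
  keep <- !apply(scores, 1L, anyNA)
  structure(list(scores = scores[keep, , drop = FALSE], mode = "ML",
                 site_logliks = if (per_site) site_ll[keep] else NULL,
                 failures = if (length(failures)) do.call(rbind, failures)
                            else data.frame(gene = character(0),
                                            reason = character(0))),
            class = "gene_score_matrix")
}

## phangorn-backed scoring engine (optional alternative)
.phangorn_fit <- function(aln, topo, model, optimize_model) {
  m <- as_char_matrix(aln)
  type <- if (model$nstates == 4L) "DNA" else "AA"
  dat <- phangorn::phyDat(m, type = type)
  Q <- model$exchangeabilities[lower.tri(model$exchangeabilities)]
  fit <- phangorn::pml(ape::unroot(topo), dat, bf = model$freqs, Q = Q,
                       k = if (is.null(model$alpha)) 1L else model$ncat,
                       shape = model$alpha %||% 1, inv = model$pinv)
  fit <- phangorn::optim.pml(fit, optEdge = TRUE, optGamma = optimize_model,
                             optInv = optimize_model, optBf = optimize_model,
                             optQ = optimize_model && model$kind == "GTR",
                             control = phangorn::pml.control(trace = 0))
  list(loglik = list(total = fit$logLik,
                     per_site = fit$siteLik %||% NULL))
}

#' Census of per-gene topology support
#'
#' For each topology: `best_count` = genes where its score is within
#' `equal_tol` of the gene's maximum (exact ties are counted for every tied
#' topology); `rejected_count` = genes where its score falls more than
#' `reject_margin` log-likelihood units below the gene's best;
#' `delta_sum_logL` = the topology's summed score minus the best topology's
#' summed score (the best topology gets 0).
#'
#' Defaults depend on the score mode: maximized log-likelihoods use
#' `equal_tol = 0.01` (absorbing optimizer round-off; set 0 for the strict
#' rule) and `reject_margin = 2`; marginal log-likelihoods (`mode =
#' "mLogL"`) use `equal_tol = 0.5` and `reject_margin = 10`.
#'
#' @param matrix a `gene_score_matrix`, or a plain genes x topologies matrix
#' @param equal_tol tie tolerance in log-likelihood units
#' @param reject_margin rejection threshold in log-likelihood units
#' @param mode `"ML"` or `"mLogL"`; taken from the score matrix when absent
#' @return data.frame (class `census_table`): topology, best_count,
#'   rejected_count, delta_sum_logL
#' @export
tally <- function(matrix, equal_tol = NULL, reject_margin = NULL, mode = NULL) {
  if (inherits(matrix, "gene_score_matrix")) {
    mode <- mode %||% matrix$mode
    matrix <- matrix$scores
  }
  mode <- mode %||% "ML"
  if (!nrow(matrix)) .stopf("empty score matrix")
  if (any(!is.finite(matrix))) .stopf("scores must be finite")
  equal_tol <- equal_tol %||% if (mode == "mLogL") 0.5 else 0.01
  reject_margin <- reject_margin %||% if (mode == "mLogL") 10 else 2
  best <- apply(matrix, 1L, max)
  best_count <- colSums(matrix >= best - equal_tol)
  rejected_count <- colSums(matrix < best - reject_margin)
  sums <- colSums(matrix)
  delta <- sums - max(sums)
  out <- data.frame(topology = colnames(matrix) %||% as.character(seq_len(ncol(matrix))),
                    best_count = as.integer(best_count),
                    rejected_count = as.integer(rejected_count),
                    delta_sum_logL = delta, row.names = NULL)
  class(out) <- c("census_table", "data.frame")
  out
}

#' Shimodaira-Hasegawa test with RELL resampling
#'
#' Tests every topology against the maximum-likelihood one using per-site
#' log-likelihood vectors on a single (typically concatenated) alignment.
#' Bootstrap replicates resample sites (RELL: no re-optimization), replicate
#' scores are centered per topology, and each topology's observed deficit to
#' the ML topology is compared with the null distribution of its deficit to
#' the replicate-wise maximum.  The ML topology has pSH = 1 by construction.
#'
#' @param site_logliks sites x topologies numeric matrix (or list of
#'   equal-length per-site vectors)
#' @param n_replicates RELL bootstrap replicates (default 10000)
#' @param seed optional integer seed
#' @param level rejection level (default 0.05)
#' @return data.frame (class `sh_result`): topology, pSH, rejected
#' @export
sh_test <- function(site_logliks, n_replicates = 10000L, seed = NULL,
                    level = 0.05) {
  if (is.list(site_logliks)) {
    len <- lengths(site_logliks)
    if (length(unique(len)) != 1L) .stopf("per-site vectors differ in length")
    site_logliks <- do.call(cbind, site_logliks)
  }
  if (ncol(site_logliks) < 2L) .stopf("need >= 2 topologies")
  if (!is.null(seed)) set.seed(seed)
  nsite <- nrow(site_logliks)
  L <- colSums(site_logliks)
  delta <- max(L) - L                       # observed deficits
  ## RELL replicates: multinomial site weights
  B <- as.integer(n_replicates)
  bs <- 1000L                               # replicate blocks to bound memory
  done <- 0L
  all_R <- matrix(NA_real_, B, ncol(site_logliks))
  while (done < B) {
    nb <- min(bs, B - done)
    W <- stats::rmultinom(nb, nsite, rep(1 / nsite, nsite))
    all_R[done + seq_len(nb), ] <- t(crossprod(site_logliks, W))
    done <- done + nb
  }
  Rc <- sweep(all_R, 2L, colMeans(all_R))   # center per topology
  Dstar <- apply(Rc, 1L, max) - Rc          # replicate deficits to the max
  pSH <- vapply(seq_len(ncol(site_logliks)), function(t)
    mean(Dstar[, t] >= delta[t]), numeric(1))
  out <- data.frame(topology = colnames(site_logliks) %||%
                      as.character(seq_len(ncol(site_logliks))),
                    pSH = pSH, rejected = pSH < level, row.names = NULL)
  class(out) <- c("sh_result", "data.frame")
  out
}
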