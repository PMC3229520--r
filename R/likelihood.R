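## Felsenstein-pruning likelihood with a 4-category discrete-gamma plus
## invariant-sites rate mixture, per-node scaling against underflow, site
## pattern compression, and coordinate-ascent branch-length optimization
## (exact Gauss-Seidel sweeps: partials are refreshed along the traversal so
## every one-dimensional optimization sees current values).

## ---- site patterns & tip partials ------------------------------------------

## Compress alignment columns into unique patterns for the taxa in tip_order.
## Returns tip partial matrices (nstates x npat per taxon), pattern weights,
## and the pattern index of every original column.
.pattern_data <- function(aln, model, tip_order) {
  miss <- setdiff(tip_order, names(aln$rows))
  if (length(miss)) .stopf("alignment '%s' lacks sequence for: %s",
                           aln$locus_id, paste(miss, collapse = ", "))
  m <- as_char_matrix(aln)[tip_order, , drop = FALSE]
  key <- apply(m, 2L, paste, collapse = "")
  upat <- !duplicated(key)
  pat_of_col <- match(key, key[upat])
  mp <- m[, upat, drop = FALSE]
  w <- tabulate(pat_of_col, nbins = ncol(mp))

  n <- model$nstates
  lookup <- matrix(0, nrow = n, ncol = 0)
  if (model$nstates == 4L) {
    syms <- names(NT_AMBIG)
    lookup <- vapply(syms, function(s) as.numeric(NT_STATES %in% NT_AMBIG[[s]]),
                     numeric(4))
  } else {
    syms <- c(AA_STATES, "x", "-", "?", ".", "*", "b", "z", "j", "u", "o")
    lookup <- vapply(syms, function(s) {
      if (s %in% AA_STATES) as.numeric(AA_STATES == s) else rep(1, 20)
    }, numeric(20))
  }
  colnames(lookup) <- syms
  tips <- lapply(seq_along(tip_order), function(i) {
    ch <- mp[i, ]
    bad <- !(ch %in% syms)
    if (any(bad)) .stopf("alignment '%s', species '%s': illegal symbol '%s'",
                         aln$locus_id, tip_order[i], ch[bad][1])
    lookup[, ch, drop = FALSE]
  })
  names(tips) <- tip_order
  list(tips = tips, weights = w, pat_of_col = pat_of_col, npat = ncol(mp))
}

## ---- plain pruning likelihood ----------------------------------------------

.check_tree_for_lik <- function(tree) {
  if (is.null(tree$edge.length)) .stopf("tree has no branch lengths")
  if (any(tree$edge.length < 0)) .stopf("negative branch length")
  kids <- tabulate(tree$edge[, 1], nbins = max(tree$edge))
  if (any(kids[kids > 0] != 2L)) .stopf("tree must be rooted and binary")
}

## per-category pruning over patterns for a fixed tree; returns
## list(loglik = npat x ncat matrix of log site-pattern likelihoods per
## category (scalers folded in), partials/logsc if keep = TRUE)
.prune_all <- function(tree, model, pd, keep = FALSE) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  E <- tr$edge; EL <- tr$edge.length
  root <- ntip + 1L
  ncat <- model$ncat
  out <- matrix(0, pd$npat, ncat)
  keepP <- if (keep) vector("list", ncat) else NULL
  for (k in seq_len(ncat)) {
    rate <- model$cat_rates[k]
    partial <- vector("list", nnode)
    logsc <- vector("list", nnode)
    for (i in seq_len(ntip)) {
      partial[[i]] <- pd$tips[[tr$tip.label[i]]]
      logsc[[i]] <- numeric(pd$npat)
    }
    kids_of <- split(seq_len(nrow(E)), E[, 1])
    node_order <- as.integer(names(sort(vapply(kids_of, max, 0))))
    for (u in node_order) {
      er <- kids_of[[as.character(u)]]
      v1 <- E[er[1], 2L]; v2 <- E[er[2], 2L]
      P1 <- .prob_matrix(model, EL[er[1]], rate)
      P2 <- .prob_matrix(model, EL[er[2]], rate)
      M <- (P1 %*% partial[[v1]]) * (P2 %*% partial[[v2]])
      sc <- apply(M, 2L, max)
      sc[sc <= 0] <- 1
      partial[[u]] <- M / rep(sc, each = nrow(M))
      logsc[[u]] <- logsc[[v1]] + logsc[[v2]] + log(sc)
    }
    lik <- colSums(model$freqs * partial[[root]])
    out[, k] <- log(lik) + logsc[[root]]
    if (keep) keepP[[k]] <- list(partial = partial, logsc = logsc)
  }
  list(loglik = out, state = keepP, tree = tr)
}

## invariant-class pattern log-likelihood: depends only on tip states
.invariant_loglik <- function(model, pd) {
  prod <- Reduce(`*`, pd$tips)
  log(colSums(model$freqs * prod))
}

## combine per-category pattern log-likelihoods into site log-likelihoods
.mix_loglik <- function(model, cat_ll, inv_ll) {
  parts <- cat_ll + rep(log(model$cat_weights), each = nrow(cat_ll))
  if (model$pinv > 0) parts <- cbind(parts, log(model$pinv) + inv_ll)
  .row_logsumexp(parts)
}

#' Phylogenetic log-likelihood (pruning algorithm)
#'
#' Computes the log-likelihood of an alignment on a rooted binary tree under
#' the given substitution model, mixing 4 discrete-gamma rate categories and
#' an invariant-site class.  Gaps and ambiguity codes contribute a partial
#' likelihood of 1 for every compatible state.
#'
#' @param aln a `gene_alignment` containing every tree tip
#' @param tree `phylo` with branch lengths in substitutions/site
#' @param model a `substitution_model`
#' @return object of class `site_loglik`: list with `per_site` (length
#'   `n_columns`), `total`, and `n_patterns`
#' @export
log_likelihood <- function(aln, tree, model) {
  .check_tree_for_lik(tree)
  pd <- .pattern_data(aln, model, tree$tip.label)
  pr <- .prune_all(tree, model, pd)
  inv <- if (model$pinv > 0) .invariant_loglik(model, pd) else NULL
  ll_pat <- .mix_loglik(model, pr$loglik, inv)
  per_site <- ll_pat[pd$pat_of_col]
  structure(list(per_site = per_site, total = sum(per_site),
                 n_patterns = pd$npat),
            class = "site_loglik")
}

#' @export
print.site_loglik <- function(x, ...) {
  cat(sprintf("site_loglik: total %.4f over %d sites (%d patterns)\n",
              x$total, length(x$per_site), x$n_patterns))
  invisible(x)
}

## ---- branch-length optimization --------------------------------------------

## Edge-factorized likelihood machinery.  For an edge (u -> v):
##   site L_k = sum_s U_k[v](s) * (P_k(t) %*% D_k[v])(s)
## with D the usual "below" partial and U the complement partial carrying the
## stationary frequencies.  Both sides keep per-pattern log scalers.

#' Optimize branch lengths on a fixed topology
#'
#' Coordinate ascent: each branch in turn is optimized by Brent's method on
#' `[min_bl, max_bl]` while all others are held fixed, with subtree partials
#' refreshed along the traversal so every one-dimensional problem is exact.
#' Cycles repeat until the total log-likelihood improves by less than `tol`.
#' Optionally, model parameters (GTR exchangeabilities, frequencies, gamma
#' shape, invariant proportion) are re-estimated between branch cycles.
#'
#' @param aln a `gene_alignment`
#' @param topology rooted binary `phylo`; existing branch lengths are used
#'   as a starting point, otherwise 0.1 per branch
#' @param model a `substitution_model`
#' @param optimize_model also estimate free model parameters (default FALSE)
#' @param max_cycles maximum optimization cycles
#' @param tol logL convergence tolerance
#' @param min_bl,max_bl branch-length box constraints
#' @param method `"cpp"` (compiled kernel, default) or `"R"` (reference
#'   implementation); both produce the same results and are cross-checked in
#'   the test suite
#' @return list with `tree` (optimized lengths), `loglik` (a `site_loglik`),
#'   `model` (possibly updated), `cycles`, `converged`, and `trace` (total
#'   logL after each cycle, non-decreasing)
#' @export
optimize_branch_lengths <- function(aln, topology, model,
                                    optimize_model = FALSE,
                                    max_cycles = 25L, tol = 1e-3,
                                    min_bl = 1e-8, max_bl = 20,
                                    method = c("cpp", "R")) {
  method <- match.arg(method)
  tree <- topology
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  tree$edge.length <- pmin(pmax(tree$edge.length, min_bl), max_bl)
  .check_tree_for_lik(tree)
  pd <- .pattern_data(aln, model, tree$tip.label)

  if (method == "cpp" && !optimize_model) {
    res <- .run_cpp_engine(tree, model, pd, min_bl, max_bl, tol, max_cycles,
                           optimize = TRUE)
    if (!res$converged)
      .warnf("branch-length optimization: no convergence after %d cycles (best logL returned)",
             max_cycles)
    return(res)
  }

  cur <- .total_loglik_pd(tree, model, pd)
  trace <- numeric(0)
  converged <- FALSE
  for (cyc in seq_len(max_cycles)) {
    tree <- .sweep_branches(tree, model, pd, min_bl, max_bl)
    if (optimize_model) {
      model <- .optimize_model_params(tree, model, pd)
    }
    new <- .total_loglik_pd(tree, model, pd)
    if (new < cur - 1e-6)  # should not happen; keep the contract honest
      .warnf("logL decreased by %.3g during cycle %d", cur - new, cyc)
    trace <- c(trace, new)
    if (new - cur < tol && cyc > 1L) { cur <- max(cur, new); converged <- TRUE; break }
    cur <- max(cur, new)
  }
  if (!converged)
    .warnf("branch-length optimization: no convergence after %d cycles (best logL returned)",
           max_cycles)
  inv <- if (model$pinv > 0) .invariant_loglik(model, pd) else NULL
  pr <- .prune_all(tree, model, pd)
  ll_pat <- .mix_loglik(model, pr$loglik, inv)
  per_site <- ll_pat[pd$pat_of_col]
  list(tree = tree,
       loglik = structure(list(per_site = per_site, total = sum(per_site),
                               n_patterns = pd$npat), class = "site_loglik"),
       model = model, cycles = length(trace), converged = converged,
       trace = trace)
}

## drive the compiled kernel on a (tree, model, pattern-data) triple
.run_cpp_engine <- function(tree, model, pd, min_bl = 1e-8, max_bl = 20,
                            tol = 1e-3, max_cycles = 25L, optimize = TRUE) {
  tr <- ape::reorder.phylo(tree, "postorder")
  inv_lik <- if (model$pinv > 0)
    model$pinv * exp(.invariant_loglik(model, pd)) else numeric(0)
  res <- .cpp_optimize_branches(
    tr$edge, length(tr$tip.label), pd$tips[tr$tip.label],
    as.numeric(pd$weights), model$eigen$left, model$eigen$values,
    model$eigen$right, model$freqs, model$cat_rates, model$cat_weights,
    model$pinv, inv_lik, tr$edge.length, min_bl, max_bl, tol,
    as.integer(max_cycles), optimize)
  tr$edge.length <- res$edge_length
  out <- tree
  key_in <- paste(tree$edge[, 1], tree$edge[, 2])
  key_tr <- paste(tr$edge[, 1], tr$edge[, 2])
  out$edge.length[match(key_tr, key_in)] <- tr$edge.length
  per_site <- res$pattern_loglik[pd$pat_of_col]
  list(tree = out,
       loglik = structure(list(per_site = per_site, total = sum(per_site),
                               n_patterns = pd$npat), class = "site_loglik"),
       model = model, cycles = res$cycles, converged = res$converged,
       trace = res$trace)
}

.total_loglik_pd <- function(tree, model, pd) {
  pr <- .prune_all(tree, model, pd)
  inv <- if (model$pinv > 0) .invariant_loglik(model, pd) else NULL
  sum(.mix_loglik(model, pr$loglik, inv)[pd$pat_of_col])
}

## one exact Gauss-Seidel sweep over all edges
.sweep_branches <- function(tree, model, pd, min_bl, max_bl) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  ncat <- model$ncat
  w <- pd$weights
  inv_term <- if (model$pinv > 0)
    model$pinv * exp(.invariant_loglik(model, pd)) else 0

  E <- tr$edge
  kids_of <- split(seq_len(nrow(E)), E[, 1])  # node -> its two child edge rows

  ## mutable state in this environment
  D <- vector("list", ntip + tr$Nnode)     # D[[v]]: list over cats: list(mat, ls)
  for (i in seq_len(ntip))
    D[[i]] <- lapply(seq_len(ncat), function(k)
      list(mat = pd$tips[[tr$tip.label[i]]], ls = numeric(pd$npat)))

  Pm <- function(t) lapply(seq_len(ncat), function(k)
    .prob_matrix(model, t, model$cat_rates[k]))

  update_D <- function(u) {
    er <- kids_of[[as.character(u)]]
    v1 <- E[er[1], 2]; v2 <- E[er[2], 2]
    P1 <- Pm(tr$edge.length[er[1]]); P2 <- Pm(tr$edge.length[er[2]])
    D[[u]] <<- lapply(seq_len(ncat), function(k) {
      M <- (P1[[k]] %*% D[[v1]][[k]]$mat) * (P2[[k]] %*% D[[v2]][[k]]$mat)
      sc <- apply(M, 2L, max); sc[sc <= 0] <- 1
      list(mat = M / rep(sc, each = nrow(M)),
           ls = D[[v1]][[k]]$ls + D[[v2]][[k]]$ls + log(sc))
    })
  }
  ## initial postorder fill (parents after all edges of their subtrees)
  for (u in as.integer(names(sort(vapply(kids_of, max, 0))))) update_D(u)

  logw <- log(model$cat_weights)
  edge_negll <- function(t, Uv, Dv) {
    P <- Pm(t)
    parts <- vapply(seq_len(ncat), function(k) {
      v <- colSums(Uv[[k]]$mat * (P[[k]] %*% Dv[[k]]$mat))
      v[v <= 0] <- .Machine$double.xmin
      log(v) + Uv[[k]]$ls + Dv[[k]]$ls + logw[k]
    }, numeric(pd$npat))
    if (is.null(dim(parts))) parts <- matrix(parts, nrow = pd$npat)
    m <- .row_logsumexp(parts)
    sitell <- if (length(inv_term) > 1L || any(inv_term != 0))
      log(exp(m) + inv_term) else m
    -sum(w * sitell)
  }
  opt_edge <- function(erow, Uv) {
    v <- E[erow, 2]
    o <- stats::optimize(edge_negll, c(min_bl, max_bl), Uv = Uv, Dv = D[[v]],
                         tol = 1e-6)
    cur <- edge_negll(tr$edge.length[erow], Uv, D[[v]])
    if (o$objective < cur) tr$edge.length[erow] <<- o$minimum
  }
  scale_U <- function(U) lapply(U, function(u) {
    sc <- apply(u$mat, 2L, max); sc[sc <= 0] <- 1
    list(mat = u$mat / rep(sc, each = nrow(u$mat)), ls = u$ls + log(sc))
  })

  descend <- function(erow, Uv) {
    ## optimize this edge, then recurse into the child's subtree
    opt_edge(erow, Uv)
    v <- E[erow, 2]
    if (v <= ntip) return(invisible())
    er <- kids_of[[as.character(v)]]
    Pv <- Pm(tr$edge.length[erow])
    base <- lapply(seq_len(ncat), function(k)
      list(mat = crossprod(Pv[[k]], Uv[[k]]$mat), ls = Uv[[k]]$ls))
    for (j in 1:2) {
      other <- er[if (j == 1) 2 else 1]
      ov <- E[other, 2]
      Po <- Pm(tr$edge.length[other])
      Uc <- scale_U(lapply(seq_len(ncat), function(k)
        list(mat = base[[k]]$mat * (Po[[k]] %*% D[[ov]][[k]]$mat),
             ls = base[[k]]$ls + D[[ov]][[k]]$ls)))
      descend(er[j], Uc)  # ends by refreshing D at its subtree root
    }
    update_D(v)
  }

  ## root: its two child edges
  er <- kids_of[[as.character(root)]]
  for (j in 1:2) {
    other <- er[if (j == 1) 2 else 1]
    ov <- E[other, 2]
    Po <- Pm(tr$edge.length[other])
    Uc <- scale_U(lapply(seq_len(ncat), function(k)
      list(mat = model$freqs * (Po[[k]] %*% D[[ov]][[k]]$mat),
           ls = D[[ov]][[k]]$ls)))
    descend(er[j], Uc)
  }

  out <- tree
  ## map optimized lengths back to the caller's edge order
  key_in <- paste(tree$edge[, 1], tree$edge[, 2])
  key_tr <- paste(tr$edge[, 1], tr$edge[, 2])
  out$edge.length[match(key_tr, key_in)] <- tr$edge.length
  out
}

## joint model-parameter update (Nelder-Mead on transformed parameters) with
## branch lengths held fixed; used when optimize_model = TRUE
.optimize_model_params <- function(tree, model, pd) {
  kind <- model$kind
  free_rates <- kind == "GTR"
  free_freqs <- kind == "GTR"
  has_gamma <- !is.null(model$alpha)
  theta <- c(
    if (free_rates) log(model$exchangeabilities[lower.tri(model$exchangeabilities)][-6]),
    if (free_freqs) log(model$freqs[-model$nstates] / model$freqs[model$nstates]),
    if (has_gamma) log(model$alpha),
    stats::qlogis(min(max(model$pinv, 1e-4), 0.6))
  )
  rebuild <- function(th) {
    i <- 0L
    rates <- rep(1, 6); freqs <- model$freqs
    if (free_rates) { rates <- c(exp(th[1:5]), 1); i <- 5L }
    if (free_freqs) {
      lf <- c(exp(th[i + 1:3]), 1); freqs <- lf / sum(lf); i <- i + 3L
    }
    alpha <- model$alpha
    if (has_gamma) { alpha <- exp(th[i + 1L]); i <- i + 1L }
    pinv <- stats::plogis(th[i + 1L])
    substitution_model(kind, rates = rates, freqs = freqs, alpha = alpha,
                       pinv = pinv, ncat = if (has_gamma) model$ncat else 4L)
  }
  negll <- function(th) {
    m <- tryCatch(rebuild(th), error = function(e) NULL)
    if (is.null(m)) return(1e10)
    -.total_loglik_pd(tree, m, pd)
  }
  o <- stats::optim(theta, negll, method = "Nelder-Mead",
                    control = list(maxit = 200))
  new <- rebuild(o$par)
  if (.total_loglik_pd(tree, new, pd) >= .total_loglik_pd(tree, model, pd))
    new else model
}
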