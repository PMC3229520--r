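## Independent likelihood oracle: exhaustive summation over all ancestral
## state assignments, with transition probabilities from ape::matexpo (a
## different route than the package's eigen-decomposition) and gamma rates
## from phangorn::discrete.gamma.  Usable for <= 5 taxa, <= ~20 sites.

oracle_loglik <- function(aln, tree, model) {
  m <- as_char_matrix(aln)
  n <- model$nstates
  states <- model$states
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  E <- tree$edge; EL <- tree$edge.length
  internal <- (ntip + 1L):nnode
  rates <- if (is.null(model$alpha)) 1 else
    phangorn::discrete.gamma(model$alpha, model$ncat)
  if (model$pinv > 0) rates <- rates / (1 - model$pinv)
  wk <- rep((1 - model$pinv) / length(rates), length(rates))

  tip_prob <- function(ch, s) {
    if (n == 4L) {
      comp <- phyloconflict:::NT_AMBIG[[ch]]
      as.numeric(states[s] %in% comp)
    } else {
      if (ch %in% states) as.numeric(states[s] == ch) else 1
    }
  }
  site_lik <- function(col) {
    total <- 0
    for (k in seq_along(rates)) {
      P <- lapply(seq_len(nrow(E)), function(e)
        ape::matexpo(model$Q * EL[e] * rates[k]))
      ## enumerate internal states
      grid <- as.matrix(expand.grid(rep(list(seq_len(n)), length(internal))))
      lk <- 0
      for (g in seq_len(nrow(grid))) {
        assign_state <- integer(nnode)
        assign_state[internal] <- grid[g, ]
        p <- model$freqs[assign_state[ntip + 1L]]
        for (e in seq_len(nrow(E))) {
          u <- E[e, 1]; v <- E[e, 2]
          if (v <= ntip) {
            pr <- sum(P[[e]][assign_state[u], ] *
                        vapply(seq_len(n), function(s) tip_prob(col[v], s), 0))
          } else {
            pr <- P[[e]][assign_state[u], assign_state[v]]
          }
          p <- p * pr
          if (p == 0) break
        }
        lk <- lk + p
      }
      total <- total + wk[k] * lk
    }
    if (model$pinv > 0) {
      inv <- sum(vapply(seq_len(n), function(s)
        model$freqs[s] * prod(vapply(seq_len(ntip), function(i)
          tip_prob(col[i], s), 0)), 0))
      total <- total + model$pinv * inv
    }
    log(total)
  }
  ## columns indexed by tip id order (rows of m follow aln row order)
  m <- m[tree$tip.label, , drop = FALSE]
  sum(vapply(seq_len(ncol(m)), function(j) site_lik(m[, j]), 0))
}
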