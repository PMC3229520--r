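## Substitution models: GTR / WAG / JC with discrete-gamma rate variation and
## a proportion of invariant sites.  Rate matrices are normalized to one
## expected substitution per site at stationarity (taking the rate mixture
## into account), the convention used by the common ML programs.

NT_STATES <- c("a", "c", "g", "t")
AA_STATES <- c("a","r","n","d","c","q","e","g","h","i","l","k","m","f","p","s","t","w","y","v")

## IUPAC nucleotide ambiguity -> compatible states (used for partial likelihoods)
NT_AMBIG <- list(
  a = "a", c = "c", g = "g", t = "t", u = "t",
  r = c("a","g"), y = c("c","t"), s = c("c","g"), w = c("a","t"),
  k = c("g","t"), m = c("a","c"),
  b = c("c","g","t"), d = c("a","g","t"), h = c("a","c","t"), v = c("a","c","g"),
  n = c("a","c","g","t"), "-" = c("a","c","g","t"), "?" = c("a","c","g","t"),
  x = c("a","c","g","t"), "." = c("a","c","g","t")
)

#' Discrete-gamma rate categories (mean of equal-probability bins)
#'
#' Standard discretization of a Gamma(alpha, alpha) rate distribution into
#' `ncat` equal-probability categories, each represented by its conditional
#' mean, so the category mean rates average to 1.
#'
#' @param alpha gamma shape (> 0)
#' @param ncat number of categories
#' @return numeric vector of `ncat` category rates
#' @export
discrete_gamma_rates <- function(alpha, ncat = 4L) {
  stopifnot(is.numeric(alpha), alpha > 0, .is_count(ncat))
  if (ncat == 1L) return(1)
  q <- stats::qgamma(seq_len(ncat - 1L) / ncat, shape = alpha, rate = alpha)
  p <- c(0, stats::pgamma(q, shape = alpha + 1, rate = alpha), 1)
  ncat * diff(p)
}

#' Construct a substitution model
#'
#' @param kind one of `"GTR"`, `"WAG"`, `"JC"`
#' @param rates for GTR, the 6 exchangeabilities in order ac, ag, at, cg, ct,
#'   gt (any positive scale); ignored for JC and WAG
#' @param freqs stationary frequencies (length 4 or 20, summing to 1);
#'   defaults to uniform (JC/GTR) or the WAG empirical frequencies
#' @param alpha gamma shape for among-site rate variation, or `NULL` for
#'   rate homogeneity
#' @param pinv proportion of invariant sites in `[0, 1)`
#' @param ncat number of discrete gamma categories (4 in all analyses here)
#' @return an object of class `substitution_model`
#' @export
substitution_model <- function(kind = c("GTR", "WAG", "JC"), rates = NULL,
                               freqs = NULL, alpha = NULL, pinv = 0, ncat = 4L) {
  kind <- match.arg(kind)
  if (kind == "WAG") {
    wag <- .wag_data()
    ex <- wag$R
    states <- AA_STATES
    if (is.null(freqs)) freqs <- wag$bf
  } else {
    states <- NT_STATES
    if (is.null(freqs)) freqs <- rep(0.25, 4)
    if (kind == "JC") {
      rates <- rep(1, 6)
      freqs <- rep(0.25, 4)
    }
    if (is.null(rates)) rates <- rep(1, 6)
    if (length(rates) != 6L || any(rates <= 0))
      .stopf("GTR needs 6 positive exchangeabilities")
    ex <- matrix(0, 4, 4)
    ex[lower.tri(ex)] <- rates
    ex <- ex + t(ex)
  }
  n <- length(states)
  if (length(freqs) != n || any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-6)
    .stopf("frequencies must be %d positive values summing to 1", n)
  freqs <- freqs / sum(freqs)
  if (!is.null(alpha) && (!is.numeric(alpha) || alpha <= 0))
    .stopf("alpha must be positive or NULL")
  if (!is.numeric(pinv) || pinv < 0 || pinv > 1) .stopf("pinv must be in [0,1]")

  Q <- ex * rep(freqs, each = n)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))          # expected rate of the unscaled matrix
  Q <- Q / mu                          # 1 substitution/site at stationarity

  gr <- if (is.null(alpha)) 1 else discrete_gamma_rates(alpha, ncat)
  ## with invariant sites, variable-site rates are inflated so the overall
  ## expected rate (including the zero-rate class) stays 1; pinv = 1 is the
  ## degenerate all-invariant model (gamma classes get zero weight)
  if (pinv > 0 && pinv < 1) gr <- gr / (1 - pinv)
  w <- rep((1 - pinv) / length(gr), length(gr))

  obj <- list(kind = kind, states = states, nstates = n,
              exchangeabilities = ex, freqs = freqs,
              alpha = alpha, pinv = pinv, ncat = length(gr),
              Q = Q, cat_rates = gr, cat_weights = w)
  obj$eigen <- .model_eigen(Q, freqs)
  class(obj) <- "substitution_model"
  obj
}

#' @rdname substitution_model
#' @export
jc_model <- function(alpha = NULL, pinv = 0, ncat = 4L)
  substitution_model("JC", alpha = alpha, pinv = pinv, ncat = ncat)

#' @rdname substitution_model
#' @export
gtr_model <- function(rates = rep(1, 6), freqs = rep(0.25, 4), alpha = NULL,
                      pinv = 0, ncat = 4L)
  substitution_model("GTR", rates = rates, freqs = freqs, alpha = alpha,
                     pinv = pinv, ncat = ncat)

#' @rdname substitution_model
#' @export
wag_model <- function(alpha = NULL, pinv = 0, ncat = 4L, freqs = NULL)
  substitution_model("WAG", freqs = freqs, alpha = alpha, pinv = pinv, ncat = ncat)

## WAG (Whelan & Goldman 2001) exchangeabilities and frequencies, taken from
## phangorn's built-in model table (lower-triangle order, states AA_STATES)
.wag_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      wag <- get(".WAG", envir = asNamespace("phangorn"))
      R <- matrix(0, 20, 20)
      R[lower.tri(R)] <- wag$Q
      R <- R + t(R)
      bf <- as.numeric(wag$bf)
      cache <<- list(R = R, bf = bf / sum(bf))
    }
    cache
  }
})

## eigendecomposition of the reversible rate matrix via the symmetrizing
## similarity transform; gives fast transition matrices P(t)
.model_eigen <- function(Q, freqs) {
  d <- sqrt(freqs)
  S <- Q * rep(d, times = length(d)) / rep(d, each = length(d))  # diag(d) Q diag(1/d)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(values = e$values,
       left = e$vectors / d,            # diag(1/d) %*% U
       right = t(e$vectors * d))        # t(U) %*% diag(d)
}

## P(t) for one branch length and rate multiplier; clamped at 0
.prob_matrix <- function(model, t, rate = 1) {
  eg <- model$eigen
  P <- eg$left %*% (exp(eg$values * (t * rate)) * eg$right)
  P[P < 0] <- 0
  P
}

#' @export
print.substitution_model <- function(x, ...) {
  cat(sprintf("substitution_model: %s (%d states), %s gamma categories, pinv = %g\n",
              x$kind, x$nstates,
              if (is.null(x$alpha)) "no" else sprintf("%d (alpha = %g)", x$ncat, x$alpha),
              x$pinv))
  invisible(x)
}
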