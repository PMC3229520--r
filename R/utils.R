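#' @keywords internal
#' @useDynLib phyloconflict, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

## log(sum(exp(x))) along rows of a matrix, guarding -Inf columns
.row_logsumexp <- function(m) {
  M <- apply(m, 1L, max)
  out <- M + log(rowSums(exp(m - M)))
  out[!is.finite(M)] <- -Inf
  out
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## derive a 32-bit safe child seed from a master seed and an index
.child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 95279) %% 2147483647)
}

.is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 1 && x == floor(x)
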