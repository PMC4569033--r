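#' Gelman-Rubin potential scale reduction factor
#'
#' Computes the PSRF for one scalar quantity monitored across parallel
#' chains: with `W` the mean within-chain variance and `B` the
#' between-chain variance of the chain means (times `n`), the statistic is
#' `sqrt(((n - 1)/n * W + B/n) / W)`. Values near 1 indicate the chains
#' are sampling the same distribution; the conventional convergence flag
#' is 1.1.
#'
#' @param chains numeric matrix, one column per chain (equal lengths,
#'   at least 10 iterations), or a list of equal-length numeric vectors.
#' @return The potential scale reduction factor (scalar).
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) {
    len <- unique(lengths(chains))
    if (length(len) != 1L) stop("chains must have equal lengths")
    chains <- do.call(cbind, chains)
  }
  stopifnot(is.matrix(chains))
  m <- ncol(chains)
  n <- nrow(chains)
  if (m < 2L) stop("at least 2 chains are required")
  if (n < 10L) stop("chains must have at least 10 iterations")
  W <- mean(apply(chains, 2, var))
  B <- n * var(colMeans(chains))
  if (W == 0) return(if (B == 0) 1 else Inf)
  v_hat <- (n - 1) / n * W + B / n
  sqrt(v_hat / W)
}
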