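#' Latin hypercube sample on the unit hypercube
#'
#' Classic stratified design: each of the `k` columns is an independent random
#' permutation of the `n` strata with a uniform jitter inside each stratum, so
#' every margin is sampled exactly once per 1/n slice.
#'
#' @param n number of samples (rows).
#' @param k number of dimensions (columns).
#' @return an `n x k` matrix in (0, 1).
#' @keywords internal
latin_hypercube <- function(n, k) {
  stopifnot(n >= 1, k >= 1)
  u <- matrix(stats::runif(n * k), n, k)
  perm <- replicate(k, sample.int(n))
  (perm - u) / n
}
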