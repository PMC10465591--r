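#' Partial credit model category probabilities
#'
#' Probability of each ordinal category `h = 1..H` for a subject with
#' latent value `x` rated by a grader with discrimination `alpha` and step
#' thresholds `delta` (length `H - 1`):
#' `p(h)` is proportional to `exp(sum_{m < h} alpha (x - delta_m))`, with
#' the empty sum equal to 0 for `h = 1`.  With `alpha = 0` the
#' distribution is uniform.
#'
#' @param x latent subject value (scalar or vector).
#' @param alpha grader discrimination, finite.
#' @param delta numeric vector of `H - 1` step thresholds.
#' @return For scalar `x`, a probability vector of length `H`; for vector
#'   `x`, a matrix with one row per subject.  Rows sum to 1 and all
#'   entries are strictly positive.
#' @examples
#' pcm_probabilities(0.3, 1.5, c(-1, -0.2, 0.4, 1.1))
#' @export
pcm_probabilities <- function(x, alpha, delta) {
  if (length(alpha) != 1L || !is.finite(alpha))
    stop("'alpha' must be a single finite value")
  delta <- as.numeric(delta)
  if (length(delta) < 1L || any(!is.finite(delta)))
    stop("'delta' must be a finite vector of H - 1 thresholds")
  H <- length(delta) + 1L
  x <- as.numeric(x)
  # eta[, h] = sum_{m < h} alpha (x - delta_m)
  steps <- alpha * (outer(x, rep(1, H - 1L)) -
                      matrix(delta, length(x), H - 1L, byrow = TRUE))
  tri <- upper.tri(matrix(0, H - 1L, H - 1L), diag = TRUE)
  eta <- cbind(0, steps %*% tri)
  eta <- eta - apply(eta, 1L, max)
  p <- exp(eta)
  p <- p / rowSums(p)
  if (length(x) == 1L) as.numeric(p) else p
}

#' Point repeatability measure of a grader
#'
#' The probability that two independent ratings of the same subject by
#' grader `j` coincide, averaged over subjects:
#' `RM = (1/n) sum_i sum_h p(y_i = h | x_i, alpha, delta)^2`.
#' Bounded between `1/H` (uniform, `alpha = 0`) and 1 (deterministic
#' rater).
#'
#' @param x vector of latent subject values.
#' @param alpha grader discrimination.
#' @param delta step thresholds, length `H - 1`.
#' @return Numeric scalar in `[1/H, 1]`.
#' @export
rm_hat <- function(x, alpha, delta) {
  if (length(x) == 0L) stop("empty subject list")
  p <- pcm_probabilities(x, alpha, delta)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  mean(rowSums(p^2))
}

#' Draw ordinal scores from a partial credit model
#'
#' @param x vector of latent subject values.
#' @param alpha,delta grader parameters as in [pcm_probabilities()].
#' @return Integer scores on the internal 1..H scale.
#' @export
rpcm <- function(x, alpha, delta) {
  p <- pcm_probabilities(x, alpha, delta)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  vapply(seq_len(nrow(p)),
         function(i) sample.int(ncol(p), 1L, prob = p[i, ]),
         integer(1))
}
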