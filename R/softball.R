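#' Softball (mollified uniform ball) log density
#'
#' Prior over latent vectors: uniform on a ball of radius `spread`, with the
#' hard boundary replaced by a logistic roll-off of steepness `sharpness`,
#' \deqn{\log p(z) = \log V^{-1}(D, spread) -
#'   \log\left(1 + e^{sharpness\,(\|z\|_2/spread - 1)}\right),}
#' where \eqn{V(D, a)} is the volume of the \eqn{D}-ball of radius \eqn{a}.
#' The normalizer treats the mollified ball as the uniform ball, which is
#' exact in the sharp limit; it is a constant offset and does not affect
#' optimization. The density depends on `z` only through its norm and is
#' non-increasing in \eqn{\|z\|}.
#'
#' @param z Latent vector, or a matrix with one vector per row.
#' @param spread Ball radius (> 0).
#' @param sharpness Boundary steepness (> 0).
#' @return Log density (one value per row of `z`).
#' @export
softball_log_density <- function(z, spread = 7, sharpness = 10) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  if (any(!is.finite(z))) stop_dgd("'z' must be finite")
  if (spread <= 0 || sharpness <= 0) stop_dgd("'spread' and 'sharpness' must be positive")
  d <- ncol(z)
  nrm <- sqrt(rowSums(z^2))
  ball_log_volume <- (d / 2) * log(pi) - lgamma(d / 2 + 1) + d * log(spread)
  -ball_log_volume - log1pexp(sharpness * (nrm / spread - 1))
}

# gradient of softball_log_density w.r.t. each row of z (matrix in, matrix out)
softball_grad <- function(z, spread, sharpness) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  nrm <- sqrt(rowSums(z^2))
  sig <- 1 / (1 + exp(-sharpness * (nrm / spread - 1)))
  coef <- ifelse(nrm > 0, -sig * sharpness / (spread * nrm), 0)
  z * coef
}
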