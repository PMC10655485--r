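#' Negative binomial log probability mass
#'
#' Log of the negative binomial pmf in its mean/dispersion parameterization,
#' \deqn{NB(k; m, r) = \frac{\Gamma(k+r)}{k!\,\Gamma(r)}
#'   \left(\frac{r}{r+m}\right)^r \left(\frac{m}{r+m}\right)^k,}
#' the observation model for gene counts: \eqn{m} is the expected count and
#' \eqn{r} the gene-specific dispersion (variance \eqn{m + m^2/r}; large
#' \eqn{r} approaches Poisson). Evaluated entirely in log space via
#' [lgamma()] so it stays finite for counts up to at least \eqn{10^7}.
#'
#' @param k Non-negative integer count(s).
#' @param m Positive mean(s).
#' @param r Positive dispersion(s).
#' @return Log probability mass, vectorized with the usual recycling.
#' @examples
#' nb_log_pmf(0, 2, 2)   # log(0.25)
#' nb_log_pmf(5, 10, 1)  # geometric special case
#' @export
nb_log_pmf <- function(k, m, r) {
  if (!is_count_vector(k)) stop_dgd("'k' must contain non-negative integers")
  if (any(!is.finite(m)) || any(m <= 0)) stop_dgd("'m' must be positive and finite")
  if (any(!is.finite(r)) || any(r <= 0)) stop_dgd("'r' must be positive and finite")
  lgamma(k + r) - lgamma(k + 1) - lgamma(r) +
    r * (log(r) - log(r + m)) + k * (log(m) - log(r + m))
}

# d log NB / d m, same recycling rules as nb_log_pmf
nb_dlogpmf_dm <- function(k, m, r) {
  k / m - (k + r) / (r + m)
}

# d log NB / d log(r): gradient for the unconstrained dispersion parameter
nb_dlogpmf_dlogr <- function(k, m, r) {
  r * (digamma(k + r) - digamma(r) + log(r) - log(r + m) + 1 - (k + r) / (r + m))
}
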