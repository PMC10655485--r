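# Internal numerics shared across the package.

# log(1 + exp(t)) without overflow; t may be any real vector
log1pexp <- function(t) {
  out <- t
  small <- t <= 30
  out[small] <- log1p(exp(t[small]))
  out
}

# row-wise log(sum(exp(x))) for a matrix, stabilized
logsumexp_rows <- function(x) {
  mx <- apply(x, 1L, max)
  mx + log(rowSums(exp(x - mx)))
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

is_count_vector <- function(k) {
  is.numeric(k) && all(is.finite(k)) && all(k >= 0) && all(k == floor(k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dgd <- function(...) stop(..., call. = FALSE)
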