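# Minimal Adam optimizer over (possibly nested) lists of numeric arrays.
# Each parameter group in training gets its own instance, mirroring the
# training recipe of one optimizer per group.

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

# Gradient *descent* step: params <- params - lr * mhat / (sqrt(vhat) + eps)
adam_step <- function(params, grads, state, lr, betas = c(0.5, 0.9), eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1L]; b2 <- betas[2L]; t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      res <- Map(upd, p, g, m, v)
      return(list(p = lapply(res, `[[`, "p"),
                  m = lapply(res, `[[`, "m"),
                  v = lapply(res, `[[`, "v")))
    }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^t)
    vhat <- v / (1 - b2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  res <- upd(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = t))
}
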