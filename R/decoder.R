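# Feed-forward decoder: latent D -> hidden layers -> G genes, ReLU after
# every layer including the output. Plain list of weight matrices and bias
# vectors; forward/backward are hand-rolled matrix ops (the network is the
# model's own contribution, not an off-the-shelf fit).

# widths: c(D, hidden..., G)
decoder_init <- function(widths, hidden_bias = 0.5, output_bias = 1) {
  n_layers <- length(widths) - 1L
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    fan_in <- widths[l]
    lim <- 1 / sqrt(fan_in)
    W[[l]] <- matrix(stats::runif(fan_in * widths[l + 1L], -lim, lim),
                     fan_in, widths[l + 1L])
    # biases start positive so every ReLU unit is active at the zero
    # initialization of the representations (dead units receive no gradient)
    b[[l]] <- rep(if (l == n_layers) output_bias else hidden_bias, widths[l + 1L])
  }
  structure(list(W = W, b = b, widths = widths), class = "dgd_decoder")
}

# Z: N x D matrix. Returns list(output = N x G, cache for backward).
decoder_forward <- function(decoder, Z) {
  n_layers <- length(decoder$W)
  acts <- vector("list", n_layers + 1L)
  acts[[1L]] <- Z
  for (l in seq_len(n_layers)) {
    pre <- sweep(acts[[l]] %*% decoder$W[[l]], 2L, decoder$b[[l]], `+`)
    acts[[l + 1L]] <- pmax(pre, 0)                 # ReLU everywhere, output too
  }
  list(output = acts[[n_layers + 1L]], acts = acts)
}

# dY: gradient of the objective w.r.t. the (post-ReLU) output.
# Returns gradients for W, b and the input Z.
decoder_backward <- function(decoder, cache, dY) {
  n_layers <- length(decoder$W)
  dW <- vector("list", n_layers)
  db <- vector("list", n_layers)
  delta <- dY
  for (l in rev(seq_len(n_layers))) {
    delta <- delta * (cache$acts[[l + 1L]] > 0)    # ReLU mask (grad 0 at 0)
    dW[[l]] <- crossprod(cache$acts[[l]], delta)
    db[[l]] <- colSums(delta)
    delta <- delta %*% t(decoder$W[[l]])
  }
  list(W = dW, b = db, dZ = delta)
}
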