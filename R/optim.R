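# Adam optimizer over a named list of parameter matrices.
# Weight decay is L2 regularisation folded into the gradient (classic Adam
# behaviour), matching the training recipe the model defaults encode.

adam_new <- function(params, lr = 5e-4, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weight_decay = 1e-7) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2
  st$eps <- eps; st$weight_decay <- weight_decay
  st$t <- 0L
  st$m <- lapply(params, function(p) matrix(0, nrow(p), ncol(p)))
  st$v <- lapply(params, function(p) matrix(0, nrow(p), ncol(p)))
  st
}

adam_step <- function(st, params, grads) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  bc1 <- 1 - b1^st$t
  bc2 <- 1 - b2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (st$weight_decay > 0) g <- g + st$weight_decay * params[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    mhat <- st$m[[nm]] / bc1
    vhat <- st$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - st$lr * mhat / (sqrt(vhat) + st$eps)
  }
  params
}

adam_state_snapshot <- function(st) {
  list(lr = st$lr, beta1 = st$beta1, beta2 = st$beta2, eps = st$eps,
       weight_decay = st$weight_decay, t = st$t, m = st$m, v = st$v)
}

adam_state_restore <- function(snap) {
  st <- new.env(parent = emptyenv())
  for (nm in names(snap)) assign(nm, snap[[nm]], envir = st)
  st
}

# Glorot-uniform initialisation; biases start at zero.
init_weight <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

init_bias <- function(n_out) matrix(0, 1L, n_out)
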