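# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every differentiable value is a node: an environment holding `value` (a
# base matrix), `grad` (accumulated during the backward sweep) and a
# `backward` closure that routes the node's gradient to its inputs. Nodes
# are recorded on a tape in creation order; reverse iteration over the tape
# is a valid reverse-topological order, so one sweep computes all gradients.
# Plain numeric matrices passed to ops are treated as constants (no grad).
#
# The engine is internal; user-facing functions never expose nodes.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL

ag_tape_begin <- function(capacity = 1024L) {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", capacity)
  t$n <- 0L
  .ag$tape <- t
  invisible(t)
}

ag_tape_end <- function() {
  .ag$tape <- NULL
  invisible(NULL)
}

ag_is_node <- function(x) is.environment(x)

ag_value <- function(x) if (is.environment(x)) x$value else x

# Leaf or interior node. `backward` receives the node's accumulated gradient.
ag_node <- function(value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  t <- .ag$tape
  if (!is.null(t)) {
    n <- t$n + 1L
    if (n > length(t$nodes)) t$nodes <- c(t$nodes, vector("list", length(t$nodes)))
    t$nodes[[n]] <- nd
    t$n <- n
  }
  nd
}

ag_leaf <- function(value) ag_node(value)

ag_accum <- function(x, g) {
  if (is.environment(x)) {
    x$grad <- if (is.null(x$grad)) g else x$grad + g
  }
  invisible(NULL)
}

ag_backward <- function(node) {
  t <- .ag$tape
  stopifnot(!is.null(t))
  for (i in seq_len(t$n)) t$nodes[[i]]$grad <- NULL
  v <- node$value
  node$grad <- matrix(1, nrow(v), ncol(v))
  for (i in rev(seq_len(t$n))) {
    nd <- t$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

## ---- primitive operations -------------------------------------------------

ag_mm <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  ag_node(va %*% vb, function(g) {
    if (is.environment(a)) ag_accum(a, tcrossprod(g, vb))
    if (is.environment(b)) ag_accum(b, crossprod(va, g))
  })
}

# Fused affine map x %*% W + b (b broadcast over rows).
ag_affine <- function(x, W, b) {
  vx <- ag_value(x); vW <- ag_value(W); vb <- ag_value(b)
  out <- vx %*% vW
  out <- out + rep(vb[1L, ], each = nrow(out))
  ag_node(out, function(g) {
    if (is.environment(x)) ag_accum(x, tcrossprod(g, vW))
    if (is.environment(W)) ag_accum(W, crossprod(vx, g))
    if (is.environment(b)) ag_accum(b, matrix(colSums(g), 1L))
  })
}

# Fused same-length 1D convolution (see .conv1d_same for the indexing
# convention): unfolds the zero-padded input into a p x (k*d_in) matrix and
# applies the stacked kernel in one matrix product.
ag_conv1d <- function(x, W, b, k) {
  vx <- ag_value(x); vW <- ag_value(W); vb <- ag_value(b)
  p <- nrow(vx); d_in <- ncol(vx)
  pad <- (k - 1L) %/% 2L
  xp <- matrix(0, p + 2L * pad, d_in)
  xp[(pad + 1L):(pad + p), ] <- vx
  # column block t+1 of U holds rows (1+t):(p+t) of xp, i.e. kernel index k-t
  U <- matrix(0, p, k * d_in)
  for (t in 0:(k - 1L)) {
    U[, (t * d_in + 1L):((t + 1L) * d_in)] <- xp[(1L + t):(p + t), , drop = FALSE]
  }
  # reorder W so its blocks match U's layout (block t+1 = K(k-t))
  perm <- as.vector(vapply(0:(k - 1L), function(t) ((k - t - 1L) * d_in + 1L):((k - t) * d_in),
                           integer(d_in)))
  Wp <- vW[perm, , drop = FALSE]
  out <- U %*% Wp
  out <- out + rep(vb[1L, ], each = p)
  ag_node(out, function(g) {
    dWp <- crossprod(U, g)
    dW <- matrix(0, nrow(vW), ncol(vW))
    dW[perm, ] <- dWp
    ag_accum(W, dW)
    ag_accum(b, matrix(colSums(g), 1L))
    if (is.environment(x)) {
      dU <- tcrossprod(g, Wp)
      dxp <- matrix(0, p + 2L * pad, d_in)
      for (t in 0:(k - 1L)) {
        dxp[(1L + t):(p + t), ] <- dxp[(1L + t):(p + t), , drop = FALSE] +
          dU[, (t * d_in + 1L):((t + 1L) * d_in), drop = FALSE]
      }
      ag_accum(x, dxp[(pad + 1L):(pad + p), , drop = FALSE])
    }
  })
}

# Elementwise add; `b` may also be a 1-row matrix broadcast over rows of `a`.
ag_add <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  if (nrow(vb) == nrow(va)) {
    ag_node(va + vb, function(g) {
      ag_accum(a, g)
      ag_accum(b, g)
    })
  } else if (nrow(vb) == 1L) {
    ag_node(va + rep(vb[1L, ], each = nrow(va)), function(g) {
      ag_accum(a, g)
      ag_accum(b, matrix(colSums(g), 1L))
    })
  } else if (nrow(va) == 1L) {
    ag_add(b, a)
  } else {
    stop("ag_add: incompatible shapes")
  }
}

ag_mul <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  stopifnot(all(dim(va) == dim(vb)))
  ag_node(va * vb, function(g) {
    ag_accum(a, g * vb)
    ag_accum(b, g * va)
  })
}

ag_scale <- function(a, s) {
  va <- ag_value(a)
  ag_node(va * s, function(g) ag_accum(a, g * s))
}

ag_shift <- function(a, s) {
  va <- ag_value(a)
  ag_node(va + s, function(g) ag_accum(a, g))
}

ag_relu <- function(a) {
  va <- ag_value(a)
  keep <- va > 0
  ag_node(va * keep, function(g) ag_accum(a, g * keep))
}

ag_leaky_relu <- function(a, slope = 0.2) {
  va <- ag_value(a)
  fac <- 1 + (slope - 1) * (va <= 0)
  ag_node(va * fac, function(g) ag_accum(a, g * fac))
}

ag_square <- function(a) {
  va <- ag_value(a)
  ag_node(va * va, function(g) ag_accum(a, 2 * va * g))
}

ag_t <- function(a) {
  va <- ag_value(a)
  ag_node(t(va), function(g) ag_accum(a, t(g)))
}

.row_max <- function(z) z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]

# Row-wise softmax with an optional additive mask (0 for allowed entries,
# -Inf for forbidden ones). Rows must keep at least one allowed entry.
ag_softmax_rows <- function(a, mask = NULL) {
  va <- ag_value(a)
  z <- if (is.null(mask)) va else va + mask
  e <- exp(z - .row_max(z))
  e[is.na(e)] <- 0 # exp(-Inf - -Inf) guards
  s <- e / rowSums(e)
  ag_node(s, function(g) {
    inner <- rowSums(g * s)
    ag_accum(a, s * (g - inner))
  })
}

# Fused GAT attention: alpha = softmax_rows(mask(LeakyReLU(f1 (+) f2^T))),
# where (+) is the outer sum of the two p x 1 logit halves and the softmax
# support is the logical neighbourhood matrix (self-loops included).
ag_gat_attention <- function(f1, f2, support, slope = 0.2) {
  v1 <- as.numeric(ag_value(f1)); v2 <- as.numeric(ag_value(f2))
  p <- length(v1)
  E <- outer(v1, v2, "+")
  fac <- 1 + (slope - 1) * (E <= 0)
  L <- E * fac
  L[!support] <- -Inf
  s <- exp(L - .row_max(L))
  s <- s / rowSums(s)
  ag_node(s, function(g) {
    dL <- s * (g - rowSums(g * s))
    dE <- dL * fac # zero outside support since s is zero there
    ag_accum(f1, matrix(rowSums(dE), p, 1L))
    ag_accum(f2, matrix(colSums(dE), p, 1L))
  })
}

ag_row_means <- function(a) {
  va <- ag_value(a)
  n <- nrow(va)
  ag_node(matrix(colMeans(va), 1L), function(g) {
    ag_accum(a, matrix(rep(g / n, each = n), n))
  })
}

ag_mean_all <- function(a) {
  va <- ag_value(a)
  n <- length(va)
  ag_node(matrix(mean(va), 1L, 1L), function(g) {
    ag_accum(a, matrix(g[1L] / n, nrow(va), ncol(va)))
  })
}

ag_sum_all <- function(a) {
  va <- ag_value(a)
  ag_node(matrix(sum(va), 1L, 1L), function(g) {
    ag_accum(a, matrix(g[1L], nrow(va), ncol(va)))
  })
}

# Row selection; duplicated indices accumulate gradient (embedding lookup).
ag_rows <- function(a, idx) {
  va <- ag_value(a)
  idx <- as.integer(idx)
  if (!is.environment(a)) return(ag_node(va[idx, , drop = FALSE]))
  dup <- anyDuplicated(idx) > 0L
  ag_node(va[idx, , drop = FALSE], function(g) {
    da <- matrix(0, nrow(va), ncol(va))
    if (dup) {
      agg <- rowsum(g, group = idx)
      da[as.integer(rownames(agg)), ] <- agg
    } else {
      da[idx, ] <- g
    }
    ag_accum(a, da)
  })
}

ag_rbind <- function(parts) {
  vals <- lapply(parts, ag_value)
  rows <- vapply(vals, nrow, 1L)
  ends <- cumsum(rows)
  starts <- ends - rows + 1L
  ag_node(do.call(rbind, vals), function(g) {
    for (i in seq_along(parts)) {
      ag_accum(parts[[i]], g[starts[i]:ends[i], , drop = FALSE])
    }
  })
}

ag_cbind <- function(parts) {
  vals <- lapply(parts, ag_value)
  cols <- vapply(vals, ncol, 1L)
  ends <- cumsum(cols)
  starts <- ends - cols + 1L
  ag_node(do.call(cbind, vals), function(g) {
    for (i in seq_along(parts)) {
      ag_accum(parts[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

# Row-wise layer normalization (population variance), followed by learned
# gain/bias outside this op when needed.
ag_layernorm_rows <- function(a, eps = 1e-5) {
  va <- ag_value(a)
  d <- ncol(va)
  mu <- rowMeans(va)
  xc <- va - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  ag_node(xhat, function(g) {
    gm <- rowMeans(g)
    gx <- rowMeans(g * xhat)
    ag_accum(a, inv * (g - gm - xhat * gx))
  })
}

# Inverted dropout driven by the session RNG; identity when not training.
ag_dropout <- function(a, p, training) {
  if (!training || p <= 0) return(a)
  va <- ag_value(a)
  mask <- (matrix(stats::runif(length(va)), nrow(va)) >= p) / (1 - p)
  ag_mul(a, ag_node(mask))
}

## ---- parameter binding ----------------------------------------------------

# Bind a named list of matrices as leaf nodes for one forward pass.
ag_bind_params <- function(store) {
  lapply(store, ag_leaf)
}

ag_collect_grads <- function(bound) {
  lapply(bound, function(nd) {
    if (is.null(nd$grad)) matrix(0, nrow(nd$value), ncol(nd$value)) else nd$grad
  })
}
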