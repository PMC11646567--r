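# RNA encoders.
#
# Graph view: multi-head graph attention (GAT) over the contact graph with
# self-loops. Per head, attention logits between node i and neighbour n are
# a^T [W_d h_i, W_d h_n] through a LeakyReLU, softmax-normalized over
# N(i) + {i}; aggregation applies a separate linear map W_a to the previous
# layer's states, weights by the attention rows, and passes through ReLU.
# Head outputs are averaged so the width stays d.
#
# Sequence view: the nucleotide embedding and a linear projection of the
# pretrained embedding are averaged position-wise, run through three
# same-length 1D convolutions (kernel sizes 7/11/15 by default), branch
# outputs averaged, then a two-layer ReLU projection head.

.gat_mask <- function(contact) {
  p <- nrow(contact)
  support <- (contact + diag(1, p)) > 0
  mask <- matrix(-Inf, p, p)
  mask[support] <- 0
  mask
}

# One GAT layer over node states H (node or matrix, p x d). Returns the
# averaged head outputs plus per-head attention matrices (plain values).
.gat_layer <- function(H, support, P, layer, n_heads, slope) {
  acc <- NULL
  attn_vals <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    nm <- function(s) P[[paste0("gat", layer, "h", h, "_", s)]]
    Hw <- ag_mm(H, nm("Wd"))
    f1 <- ag_mm(Hw, nm("a1")) # p x 1
    f2 <- ag_mm(Hw, nm("a2"))
    alpha <- ag_gat_attention(f1, f2, support, slope)
    out <- ag_relu(ag_mm(alpha, ag_mm(H, nm("Wa"))))
    acc <- if (is.null(acc)) out else ag_add(acc, out)
    attn_vals[[h]] <- ag_value(alpha)
  }
  list(out = ag_scale(acc, 1 / n_heads), attn = attn_vals)
}

.gat_forward <- function(P, feats, cfg) {
  support <- feats$gat_support
  if (is.null(support)) {
    support <- (feats$contact + diag(1, nrow(feats$contact))) > 0
  }
  H <- ag_rows(P$rna_embed, feats$indices + 1L)
  attn <- vector("list", cfg$gat_layers)
  for (l in seq_len(cfg$gat_layers)) {
    res <- .gat_layer(H, support, P, l, cfg$gat_heads, cfg$leaky_slope)
    H <- res$out
    attn[[l]] <- res$attn
  }
  list(tokens = H, pooled = ag_row_means(H), attention = attn)
}

# Same-length 1D convolution: out(j) = sum_i I_pad(j - i + k) K(i) + b,
# with symmetric zero padding of (k-1)/2 rows. K is stored as k stacked
# (d_in x d_out) blocks, block i = K(i). Implemented as a fused unfold +
# matrix product (ag_conv1d).
.conv1d_same <- function(x, W, b, k) {
  ag_conv1d(x, W, b, k)
}

.cnn_forward <- function(P, feats, cfg) {
  E_nuc <- ag_rows(P$rna_embed, feats$indices + 1L)
  P_proj <- ag_affine(feats$pretrained, P$pre_W, P$pre_b)
  input <- ag_scale(ag_add(E_nuc, P_proj), 0.5)
  ks <- cfg$kernel_sizes
  acc <- NULL
  for (k in ks) {
    branch <- .conv1d_same(input, P[[paste0("cnn", k, "_W")]],
                           P[[paste0("cnn", k, "_b")]], k)
    acc <- if (is.null(acc)) branch else ag_add(acc, branch)
  }
  E <- ag_scale(acc, 1 / length(ks))
  h <- ag_relu(ag_affine(E, P$rna_c1_W, P$rna_c1_b))
  tokens <- ag_relu(ag_affine(h, P$rna_c2_W, P$rna_c2_b))
  list(tokens = tokens, pooled = ag_row_means(tokens))
}

#' Initialize RNA-encoder weights
#'
#' @param d Hidden width.
#' @param d_pre Pretrained-embedding width.
#' @param gat_layers,gat_heads GAT depth and head count.
#' @param kernel_sizes Odd convolution kernel sizes.
#' @param seed Seed for Glorot initialization.
#' @param zero_bias Start biases at zero and also zero the convolution
#'   biases (they already start at zero; kept for symmetry with tests).
#' @return Named list of weight matrices.
#' @export
init_rna_encoder_params <- function(d = 128L, d_pre = 16L, gat_layers = 2L,
                                    gat_heads = 4L,
                                    kernel_sizes = c(7L, 11L, 15L),
                                    seed = 1L, zero_bias = TRUE) {
  with_preserved_rng(seed, {
    P <- list(
      rna_embed = init_weight(4L, d),
      pre_W = init_weight(d_pre, d),
      pre_b = init_bias(d)
    )
    for (l in seq_len(gat_layers)) {
      for (h in seq_len(gat_heads)) {
        pre <- paste0("gat", l, "h", h, "_")
        P[[paste0(pre, "Wd")]] <- init_weight(d, d)
        P[[paste0(pre, "a1")]] <- init_weight(d, 1L)
        P[[paste0(pre, "a2")]] <- init_weight(d, 1L)
        P[[paste0(pre, "Wa")]] <- init_weight(d, d)
      }
    }
    for (k in kernel_sizes) {
      P[[paste0("cnn", k, "_W")]] <- init_weight(k * d, d) / sqrt(k)
      P[[paste0("cnn", k, "_b")]] <- init_bias(d)
    }
    P$rna_c1_W <- init_weight(d, d); P$rna_c1_b <- init_bias(d)
    P$rna_c2_W <- init_weight(d, d); P$rna_c2_b <- init_bias(d)
    P
  })
}

#' GAT attention coefficients for one layer/head
#'
#' Softmax-normalized attention over each node's neighbourhood (self-loop
#' included); entries outside the neighbourhood are zero.
#'
#' @param node_states p x d matrix of node states.
#' @param contact p x p binary symmetric contact map.
#' @param W_d d x d shared linear map.
#' @param a Attention weight vector of length 2d (split into the source and
#'   target halves).
#' @param leaky_slope Negative slope of the LeakyReLU on the logits.
#' @return p x p matrix; each row sums to 1 over its support.
#' @export
gat_attention_coefficients <- function(node_states, contact, W_d, a,
                                       leaky_slope = 0.2) {
  stopifnot(nrow(node_states) == nrow(contact), ncol(contact) == nrow(contact))
  if (any(!is.finite(node_states))) stop("non-finite node states", call. = FALSE)
  d <- ncol(W_d)
  a <- as.numeric(a)
  stopifnot(length(a) == 2L * d)
  p <- nrow(node_states)
  Hw <- node_states %*% W_d
  f1 <- Hw %*% matrix(a[1:d], ncol = 1L)
  f2 <- Hw %*% matrix(a[(d + 1L):(2L * d)], ncol = 1L)
  logits <- matrix(f1, p, p) + matrix(f2, p, p, byrow = TRUE)
  logits <- ifelse(logits > 0, logits, leaky_slope * logits)
  mask <- .gat_mask(contact)
  z <- logits + mask
  e <- exp(z - apply(z, 1L, max))
  e[is.na(e)] <- 0
  e / rowSums(e)
}

#' Encode an RNA with the graph-view GAT encoder
#'
#' @param features An [featurize_rna()] bundle.
#' @param weights Named weight list from [init_rna_encoder_params()].
#' @param d,gat_layers,gat_heads,leaky_slope Architecture settings; must
#'   match the weight shapes.
#' @return List with `tokens` (p x d), `pooled` (length d), and `attention`
#'   (per layer, per head p x p coefficient matrices).
#' @export
gat_encode <- function(features, weights, d = 128L, gat_layers = 2L,
                       gat_heads = 4L, leaky_slope = 0.2) {
  stopifnot(length(features$indices) == nrow(features$contact))
  cfg <- list(gat_layers = gat_layers, gat_heads = gat_heads,
              leaky_slope = leaky_slope)
  res <- .gat_forward(weights, features, cfg)
  list(tokens = ag_value(res$tokens), pooled = as.numeric(ag_value(res$pooled)),
       attention = res$attention)
}

#' Encode an RNA with the multiscale sequence-view CNN encoder
#'
#' @param features An [featurize_rna()] bundle.
#' @param weights Named weight list from [init_rna_encoder_params()].
#' @param kernel_sizes Odd kernel sizes (must match the weights).
#' @return List with `tokens` (p x d) and `pooled` (length d).
#' @export
multiscale_cnn_encode <- function(features, weights,
                                  kernel_sizes = c(7L, 11L, 15L)) {
  p <- length(features$indices)
  if (p == 0L) stop("empty RNA", call. = FALSE)
  stopifnot(all(kernel_sizes %% 2L == 1L))
  cfg <- list(kernel_sizes = kernel_sizes)
  res <- .cnn_forward(weights, features, cfg)
  list(tokens = ag_value(res$tokens), pooled = as.numeric(ag_value(res$pooled)))
}

#' Same-length 1D convolution (single branch)
#'
#' Exposed for direct verification against the index-by-index definition
#' out(j) = sum_i I_pad(j - i + k) K(i) with symmetric zero padding.
#'
#' @param input p x d_in matrix.
#' @param kernel (k*d_in) x d_out matrix, k stacked blocks; block i is the
#'   kernel slice K(i).
#' @param bias 1 x d_out matrix (or scalar 0).
#' @param k Odd kernel size.
#' @return p x d_out matrix.
#' @export
conv1d_same <- function(input, kernel, bias = 0, k) {
  if (identical(bias, 0)) bias <- matrix(0, 1L, ncol(kernel))
  ag_value(.conv1d_same(input, kernel, bias, k))
}
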