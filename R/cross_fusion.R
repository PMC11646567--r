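# Cross-fusion Transformer.
#
# The RNA token matrices from both views are stacked (graph view first) and
# a learned per-view segment embedding is added, giving R_c (2p x d);
# likewise M_c (2q x d) for the molecule. Each cross block runs two
# perspectives in parallel from the block's inputs: the RNA perspective
# takes queries from R_c and keys/values from M_c (score shape 2p x 2q), the
# molecule perspective the reverse (2q x 2p). Heads are concatenated, then
# residual + layer normalization and a feed-forward sublayer per
# perspective. After L blocks the four pooled vectors are segment-wise
# means. All post-softmax score matrices are retained for interpretability.

.segment_stack <- function(tokens_g, tokens_s, seg_g, seg_s, use_graph, use_seq) {
  parts <- list()
  if (use_graph) parts <- c(parts, list(ag_add(tokens_g, seg_g)))
  if (use_seq) parts <- c(parts, list(ag_add(tokens_s, seg_s)))
  if (length(parts) == 1L) parts[[1L]] else ag_rbind(parts)
}

# One cross-attention perspective: queries from A, keys/values from B.
.cross_mha <- function(A, B, P, prefix, n_heads, d_head) {
  outs <- vector("list", n_heads)
  scores <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    nm <- function(s) P[[paste0(prefix, "_h", h, "_", s)]]
    Q <- ag_mm(A, nm("Wq"))
    K <- ag_mm(B, nm("Wk"))
    V <- ag_mm(B, nm("Wv"))
    S <- ag_softmax_rows(ag_scale(ag_mm(Q, ag_t(K)), 1 / sqrt(d_head)))
    outs[[h]] <- ag_mm(S, V)
    scores[[h]] <- ag_value(S)
  }
  list(out = ag_cbind(outs), scores = scores)
}

.cross_block <- function(R_c, M_c, P, block, n_heads, d_head) {
  preR <- paste0("cf", block, "R")
  preM <- paste0("cf", block, "M")
  # parallel: both perspectives read the block's inputs
  mr <- .cross_mha(R_c, M_c, P, preR, n_heads, d_head)
  mm_ <- .cross_mha(M_c, R_c, P, preM, n_heads, d_head)
  Rn <- ag_layernorm_rows(ag_add(R_c, mr$out))
  Rn <- ag_layernorm_rows(ag_add(Rn, .ffn(Rn, P, preR)))
  Mn <- ag_layernorm_rows(ag_add(M_c, mm_$out))
  Mn <- ag_layernorm_rows(ag_add(Mn, .ffn(Mn, P, preM)))
  list(R = Rn, M = Mn, rna_scores = mr$scores, mol_scores = mm_$scores)
}

.cross_forward <- function(P, rna_view, mol_view, cfg) {
  use_g <- cfg$use_graph_view
  use_s <- cfg$use_sequence_view
  R_c <- .segment_stack(rna_view$g_tokens, rna_view$s_tokens, P$seg_g, P$seg_s,
                        use_g, use_s)
  M_c <- .segment_stack(mol_view$g_tokens, mol_view$s_tokens, P$seg_g, P$seg_s,
                        use_g, use_s)
  d_head <- cfg$d %/% cfg$cf_heads
  maps <- list(rna = list(), mol = list())
  if (cfg$cf_blocks > 0L) {
    for (b in seq_len(cfg$cf_blocks)) {
      res <- .cross_block(R_c, M_c, P, b, cfg$cf_heads, d_head)
      R_c <- res$R; M_c <- res$M
      maps$rna[[b]] <- res$rna_scores
      maps$mol[[b]] <- res$mol_scores
    }
  }
  p <- rna_view$p; q <- mol_view$q
  n_views <- use_g + use_s
  seg_mean <- function(X, n_tok) {
    lapply(seq_len(n_views), function(v) {
      ag_row_means(ag_rows(X, ((v - 1L) * n_tok + 1L):(v * n_tok)))
    })
  }
  r_means <- seg_mean(R_c, p)
  m_means <- seg_mean(M_c, q)
  # order: graph view first when present, then sequence view
  list(
    R_cg = if (use_g) r_means[[1L]] else NULL,
    R_cs = if (use_s) r_means[[n_views]] else NULL,
    M_cg = if (use_g) m_means[[1L]] else NULL,
    M_cs = if (use_s) m_means[[n_views]] else NULL,
    attention = maps
  )
}

#' Initialize cross-fusion weights
#'
#' @param d Hidden width (divisible by `cf_heads`).
#' @param cf_blocks,cf_heads Cross-block depth and head count.
#' @param d_ff Feed-forward inner width.
#' @param seed Seed for Glorot initialization.
#' @return Named list of weight matrices, including the two learned segment
#'   embeddings `seg_g` and `seg_s`.
#' @export
init_cross_fusion_params <- function(d = 128L, cf_blocks = 1L, cf_heads = 4L,
                                     d_ff = 2L * d, seed = 1L) {
  stopifnot(d %% cf_heads == 0L)
  d_head <- d %/% cf_heads
  with_preserved_rng(seed, {
    P <- list(seg_g = init_weight(1L, d), seg_s = init_weight(1L, d))
    for (b in seq_len(cf_blocks)) {
      for (side in c("R", "M")) {
        pre <- paste0("cf", b, side)
        for (h in seq_len(cf_heads)) {
          P[[paste0(pre, "_h", h, "_Wq")]] <- init_weight(d, d_head)
          P[[paste0(pre, "_h", h, "_Wk")]] <- init_weight(d, d_head)
          P[[paste0(pre, "_h", h, "_Wv")]] <- init_weight(d, d_head)
        }
        P[[paste0(pre, "_f1W")]] <- init_weight(d, d_ff)
        P[[paste0(pre, "_f1b")]] <- init_bias(d_ff)
        P[[paste0(pre, "_f2W")]] <- init_weight(d_ff, d)
        P[[paste0(pre, "_f2b")]] <- init_bias(d)
      }
    }
    P
  })
}

#' Stack view embeddings with segment embeddings
#'
#' @param rna_g,rna_s p x d token matrices for the RNA graph and sequence
#'   views.
#' @param mol_g,mol_s q x d token matrices for the molecule views.
#' @param seg_g,seg_s Length-d segment embeddings (graph and sequence).
#' @return List with `R_c` (2p x d) and `M_c` (2q x d); graph-view rows
#'   first.
#' @export
apply_segment_embeddings <- function(rna_g, rna_s, mol_g, mol_s, seg_g, seg_s) {
  sg <- matrix(as.numeric(seg_g), 1L)
  ss <- matrix(as.numeric(seg_s), 1L)
  list(
    R_c = rbind(sweep(rna_g, 2L, sg[1L, ], "+"), sweep(rna_s, 2L, ss[1L, ], "+")),
    M_c = rbind(sweep(mol_g, 2L, sg[1L, ], "+"), sweep(mol_s, 2L, ss[1L, ], "+"))
  )
}

#' One cross-attention Transformer block
#'
#' @param R_c 2p x d RNA-side input.
#' @param M_c 2q x d molecule-side input.
#' @param weights Named weight list from [init_cross_fusion_params()].
#' @param block Block index into the weights.
#' @param cf_heads Head count.
#' @return List with updated `R_c`, `M_c`, and the per-head post-softmax
#'   score matrices `rna_scores` (2p x 2q) and `mol_scores` (2q x 2p).
#' @export
cross_attention_block <- function(R_c, M_c, weights, block = 1L, cf_heads = 4L) {
  if (any(!is.finite(R_c)) || any(!is.finite(M_c))) {
    stop("non-finite inputs", call. = FALSE)
  }
  d <- ncol(R_c)
  stopifnot(ncol(M_c) == d, d %% cf_heads == 0L)
  res <- .cross_block(R_c, M_c, weights, block, cf_heads, d %/% cf_heads)
  list(R_c = ag_value(res$R), M_c = ag_value(res$M),
       rna_scores = res$rna_scores, mol_scores = res$mol_scores)
}

#' Full cross-fusion encoding of one RNA-molecule pair
#'
#' @param rna_g,rna_s,mol_g,mol_s View token matrices (p x d and q x d).
#' @param weights Named weight list from [init_cross_fusion_params()].
#' @param cf_blocks,cf_heads Depth and heads (must match weights).
#' @return List with the four pooled vectors `R_cg`, `R_cs`, `M_cg`, `M_cs`
#'   (each length d) and `attention` (per block, per head score matrices for
#'   both perspectives).
#' @export
cross_fusion_encode <- function(rna_g, rna_s, mol_g, mol_s, weights,
                                cf_blocks = 1L, cf_heads = 4L) {
  d <- ncol(rna_g)
  cfg <- list(d = d, cf_blocks = cf_blocks, cf_heads = cf_heads,
              use_graph_view = TRUE, use_sequence_view = TRUE)
  rna_view <- list(g_tokens = rna_g, s_tokens = rna_s, p = nrow(rna_g))
  mol_view <- list(g_tokens = mol_g, s_tokens = mol_s, q = nrow(mol_g))
  res <- .cross_forward(weights, rna_view, mol_view, cfg)
  list(R_cg = as.numeric(ag_value(res$R_cg)),
       R_cs = as.numeric(ag_value(res$R_cs)),
       M_cg = as.numeric(ag_value(res$M_cg)),
       M_cs = as.numeric(ag_value(res$M_cs)),
       attention = res$attention)
}
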