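# Molecule encoders.
#
# Graph view: graph convolution with symmetric normalization,
#   M^{l} = ReLU(D~^{-1/2} A~ D~^{-1/2} M^{l-1} W^{l}),
# over the self-connected chemical graph.
#
# Sequence view: a Transformer encoder over atomic-level SMILES tokens.
# All tokens (atoms, bonds, ring digits, branches) flow through the blocks;
# the atom mask then selects the q atom rows, so the per-atom embedding has
# exactly q rows and pooling averages atoms only. Residual connections and
# (non-affine) row layer normalization follow each sublayer; scaled
# dot-product attention uses 1/sqrt(d_head).

.gcn_norm_adj <- function(graph) {
  dinv <- 1 / sqrt(diag(graph$D_tilde))
  graph$A_tilde * outer(dinv, dinv)
}

.gcn_forward <- function(P, graph, cfg) {
  S <- if (!is.null(graph$S)) graph$S else .gcn_norm_adj(graph)
  H <- graph$features
  for (l in seq_len(cfg$gcn_layers)) {
    H <- ag_relu(ag_mm(S, ag_mm(H, P[[paste0("gcn", l, "_W")]])))
  }
  list(tokens = H, pooled = ag_row_means(H))
}

# One multi-head self-attention sublayer; returns concatenated heads.
.mha_self <- function(X, P, prefix, n_heads, d_head) {
  outs <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    nm <- function(s) P[[paste0(prefix, "h", h, "_", s)]]
    Q <- ag_mm(X, nm("Wq"))
    K <- ag_mm(X, nm("Wk"))
    V <- ag_mm(X, nm("Wv"))
    A <- ag_softmax_rows(ag_scale(ag_mm(Q, ag_t(K)), 1 / sqrt(d_head)))
    outs[[h]] <- ag_mm(A, V)
  }
  ag_cbind(outs)
}

.ffn <- function(X, P, prefix) {
  h <- ag_relu(ag_affine(X, P[[paste0(prefix, "_f1W")]],
                         P[[paste0(prefix, "_f1b")]]))
  ag_affine(h, P[[paste0(prefix, "_f2W")]], P[[paste0(prefix, "_f2b")]])
}

.transformer_forward <- function(P, tok, cfg, ids = NULL) {
  if (is.null(ids)) ids <- smiles_token_ids(tok$tokens)
  n <- length(ids)
  if (n > cfg$max_smiles_len) {
    stop("SMILES token count ", n, " > maximum ", cfg$max_smiles_len,
         call. = FALSE)
  }
  d_head <- cfg$d %/% cfg$tr_heads
  X <- ag_add(ag_rows(P$tok_embed, ids), ag_rows(P$pos_embed, seq_len(n)))
  for (b in seq_len(cfg$tr_blocks)) {
    pre <- paste0("tr", b)
    mh <- .mha_self(X, P, pre, cfg$tr_heads, d_head)
    X <- ag_layernorm_rows(ag_add(X, mh))
    X <- ag_layernorm_rows(ag_add(X, .ffn(X, P, pre)))
  }
  atom_rows <- which(tok$atom_mask)
  Ms <- ag_rows(X, atom_rows)
  list(tokens = Ms, pooled = ag_row_means(Ms))
}

#' Initialize molecule-encoder weights
#'
#' @param d Hidden width (must be divisible by `tr_heads`).
#' @param f Atom-feature width (29 for the bundled featurizer).
#' @param gcn_layers GCN depth.
#' @param tr_blocks,tr_heads Transformer depth and head count.
#' @param d_ff Feed-forward inner width.
#' @param max_smiles_len Maximum SMILES token count (positional table size).
#' @param seed Seed for Glorot initialization.
#' @return Named list of weight matrices.
#' @export
init_mol_encoder_params <- function(d = 128L, f = ATOM_FEATURE_WIDTH,
                                    gcn_layers = 2L, tr_blocks = 2L,
                                    tr_heads = 4L, d_ff = 2L * d,
                                    max_smiles_len = 128L, seed = 1L) {
  stopifnot(d %% tr_heads == 0L)
  d_head <- d %/% tr_heads
  with_preserved_rng(seed, {
    P <- list(
      tok_embed = init_weight(length(SMILES_VOCAB), d),
      pos_embed = init_weight(max_smiles_len, d)
    )
    for (l in seq_len(gcn_layers)) {
      P[[paste0("gcn", l, "_W")]] <- init_weight(if (l == 1L) f else d, d)
    }
    for (b in seq_len(tr_blocks)) {
      pre <- paste0("tr", b)
      for (h in seq_len(tr_heads)) {
        P[[paste0(pre, "h", h, "_Wq")]] <- init_weight(d, d_head)
        P[[paste0(pre, "h", h, "_Wk")]] <- init_weight(d, d_head)
        P[[paste0(pre, "h", h, "_Wv")]] <- init_weight(d, d_head)
      }
      P[[paste0(pre, "_f1W")]] <- init_weight(d, d_ff)
      P[[paste0(pre, "_f1b")]] <- init_bias(d_ff)
      P[[paste0(pre, "_f2W")]] <- init_weight(d_ff, d)
      P[[paste0(pre, "_f2b")]] <- init_bias(d)
    }
    P
  })
}

#' Encode a molecule with the graph-view GCN encoder
#'
#' @param graph A [build_mol_graph()] object.
#' @param weights Named weight list from [init_mol_encoder_params()].
#' @param gcn_layers GCN depth (must match the weights).
#' @return List with `tokens` (q x d) and `pooled` (length d).
#' @export
gcn_encode <- function(graph, weights, gcn_layers = 2L) {
  stopifnot(inherits(graph, "rsma_mol_graph"))
  if (any(diag(graph$D_tilde) <= 0)) stop("zero-degree row", call. = FALSE)
  res <- .gcn_forward(weights, graph, list(gcn_layers = gcn_layers))
  list(tokens = ag_value(res$tokens), pooled = as.numeric(ag_value(res$pooled)))
}

#' One scaled dot-product self-attention head
#'
#' Softmax(X Wq (X Wk)^T / sqrt(d_head)) X Wv, exposed for direct
#' verification against a loop-written oracle.
#'
#' @param tokens n x d input matrix.
#' @param W_q,W_k,W_v d x d_head projection matrices.
#' @return List with `output` (n x d_head) and `attention` (n x n,
#'   row-stochastic).
#' @export
self_attention_head <- function(tokens, W_q, W_k, W_v) {
  stopifnot(nrow(tokens) >= 1L)
  d_head <- ncol(W_q)
  Q <- tokens %*% W_q
  K <- tokens %*% W_k
  V <- tokens %*% W_v
  z <- (Q %*% t(K)) / sqrt(d_head)
  e <- exp(z - apply(z, 1L, max))
  A <- e / rowSums(e)
  list(output = A %*% V, attention = A)
}

#' Encode a molecule with the sequence-view SMILES Transformer
#'
#' @param tok A [tokenize_smiles()] object.
#' @param weights Named weight list from [init_mol_encoder_params()].
#' @param d,tr_blocks,tr_heads Architecture settings (must match weights).
#' @param max_smiles_len Maximum token count.
#' @return List with `tokens` (q x d, atom rows only) and `pooled`
#'   (length d, mean over atom rows).
#' @export
transformer_encode <- function(tok, weights, d = 128L, tr_blocks = 2L,
                               tr_heads = 4L, max_smiles_len = 128L) {
  stopifnot(inherits(tok, "rsma_tokenized_smiles"))
  if (tok$q == 0L) stop("no atom tokens", call. = FALSE)
  cfg <- list(d = d, tr_blocks = tr_blocks, tr_heads = tr_heads,
              max_smiles_len = max_smiles_len)
  res <- .transformer_forward(weights, tok, cfg)
  list(tokens = ag_value(res$tokens), pooled = as.numeric(ag_value(res$pooled)))
}
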