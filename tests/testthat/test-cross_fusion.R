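# Brute-force oracle for one full cross-attention block, written with
# explicit loops and the shared helper oracles.

oracle_cross_block <- function(R_c, M_c, W, block, heads) {
  d <- ncol(R_c)
  dh <- d %/% heads
  persp <- function(A, B, side) {
    outs <- NULL
    for (h in seq_len(heads)) {
      nm <- function(s) W[[paste0("cf", block, side, "_h", h, "_", s)]]
      Q <- A %*% nm("Wq"); K <- B %*% nm("Wk"); V <- B %*% nm("Wv")
      S <- oracle_softmax_rows((Q %*% t(K)) / sqrt(dh))
      outs <- cbind(outs, S %*% V)
    }
    outs
  }
  ffn <- function(X, side) {
    h1 <- pmax(sweep(X %*% W[[paste0("cf", block, side, "_f1W")]], 2,
                     W[[paste0("cf", block, side, "_f1b")]][1, ], "+"), 0)
    sweep(h1 %*% W[[paste0("cf", block, side, "_f2W")]], 2,
          W[[paste0("cf", block, side, "_f2b")]][1, ], "+")
  }
  Rn <- oracle_layernorm(R_c + persp(R_c, M_c, "R"))
  Rn <- oracle_layernorm(Rn + ffn(Rn, "R"))
  Mn <- oracle_layernorm(M_c + persp(M_c, R_c, "M"))
  Mn <- oracle_layernorm(Mn + ffn(Mn, "M"))
  list(R = Rn, M = Mn)
}

test_that("segment embeddings add per view and stack graph rows first", {
  set.seed(2)
  p <- 3L; q <- 2L; d <- 4L
  rg <- rand_mat(p, d); rs <- rand_mat(p, d)
  mg <- rand_mat(q, d); ms <- rand_mat(q, d)
  sg <- stats::rnorm(d); ss <- stats::rnorm(d)
  out <- apply_segment_embeddings(rg, rs, mg, ms, sg, ss)
  expect_equal(dim(out$R_c), c(2L * p, d))
  expect_equal(dim(out$M_c), c(2L * q, d))
  # each graph-view row differs from its source row by exactly S_g
  for (j in seq_len(p)) {
    expect_equal(out$R_c[j, ] - rg[j, ], sg, tolerance = 1e-12)
    expect_equal(out$R_c[p + j, ] - rs[j, ], ss, tolerance = 1e-12)
  }
  # zero segments reduce to a plain vertical stack
  z <- apply_segment_embeddings(rg, rs, mg, ms, rep(0, d), rep(0, d))
  expect_equal(z$R_c, rbind(rg, rs))
  expect_equal(z$M_c, rbind(mg, ms))
})

test_that("cross-attention scores are row-stochastic with shape 2p x 2q", {
  set.seed(4)
  p <- 3L; q <- 2L; d <- 4L
  W <- init_cross_fusion_params(d = d, cf_blocks = 1L, cf_heads = 2L,
                                d_ff = 4L, seed = 4L)
  R_c <- rand_mat(2L * p, d); M_c <- rand_mat(2L * q, d)
  res <- cross_attention_block(R_c, M_c, W, block = 1L, cf_heads = 2L)
  for (S in res$rna_scores) {
    expect_equal(dim(S), c(2L * p, 2L * q))
    expect_equal(rowSums(S), rep(1, 2L * p), tolerance = 1e-5)
  }
  for (S in res$mol_scores) {
    expect_equal(dim(S), c(2L * q, 2L * p))
    expect_equal(rowSums(S), rep(1, 2L * q), tolerance = 1e-5)
  }
})

test_that("with identity projections the scores are softmax(R_c M_c^T / sqrt(d))", {
  p <- 2L; q <- 1L; d <- 3L
  W <- init_cross_fusion_params(d = d, cf_blocks = 1L, cf_heads = 1L,
                                d_ff = 3L, seed = 1L)
  W$cf1R_h1_Wq <- diag(1, d); W$cf1R_h1_Wk <- diag(1, d)
  set.seed(8)
  R_c <- rand_mat(2L * p, d); M_c <- rand_mat(2L * q, d)
  res <- cross_attention_block(R_c, M_c, W, block = 1L, cf_heads = 1L)
  raw <- R_c %*% t(M_c) # the [gg, gs; sg, ss] block structure
  expect_equal(res$rna_scores[[1L]], oracle_softmax_rows(raw / sqrt(d)),
               tolerance = 1e-10)
})

test_that("a cross block matches the brute-force loop oracle", {
  set.seed(9)
  for (trial in 1:10) {
    p <- sample(1:4, 1L); q <- sample(1:3, 1L)
    heads <- sample(c(1L, 2L), 1L)
    d <- 4L
    W <- init_cross_fusion_params(d = d, cf_blocks = 1L, cf_heads = heads,
                                  d_ff = 5L, seed = trial)
    R_c <- rand_mat(2L * p, d); M_c <- rand_mat(2L * q, d)
    got <- cross_attention_block(R_c, M_c, W, block = 1L, cf_heads = heads)
    want <- oracle_cross_block(R_c, M_c, W, 1L, heads)
    expect_equal(got$R_c, want$R, tolerance = 1e-5)
    expect_equal(got$M_c, want$M, tolerance = 1e-5)
  }
})

test_that("cross-fusion encoding composes blocks and segment means", {
  set.seed(12)
  p <- 3L; q <- 2L; d <- 4L
  rg <- rand_mat(p, d); rs <- rand_mat(p, d)
  mg <- rand_mat(q, d); ms <- rand_mat(q, d)
  W <- init_cross_fusion_params(d = d, cf_blocks = 1L, cf_heads = 2L,
                                d_ff = 4L, seed = 12L)

  out <- cross_fusion_encode(rg, rs, mg, ms, W, cf_blocks = 1L, cf_heads = 2L)
  # composition oracle: segment stack, one oracle block, segment means
  st <- apply_segment_embeddings(rg, rs, mg, ms, W$seg_g, W$seg_s)
  blk <- oracle_cross_block(st$R_c, st$M_c, W, 1L, 2L)
  expect_equal(out$R_cg, colMeans(blk$R[1:p, , drop = FALSE]), tolerance = 1e-5)
  expect_equal(out$R_cs, colMeans(blk$R[(p + 1):(2 * p), , drop = FALSE]),
               tolerance = 1e-5)
  expect_equal(out$M_cg, colMeans(blk$M[1:q, , drop = FALSE]), tolerance = 1e-5)
  expect_equal(out$M_cs, colMeans(blk$M[(q + 1):(2 * q), , drop = FALSE]),
               tolerance = 1e-5)
  expect_length(out$attention$rna, 1L)
  expect_length(out$attention$rna[[1L]], 2L)

  # degenerate depth: zero blocks leave the segment-wise means of the inputs
  out0 <- cross_fusion_encode(rg, rs, mg, ms, W, cf_blocks = 0L, cf_heads = 2L)
  expect_equal(out0$R_cg, colMeans(st$R_c[1:p, , drop = FALSE]), tolerance = 1e-12)
  expect_equal(out0$M_cs, colMeans(st$M_c[(q + 1):(2 * q), , drop = FALSE]),
               tolerance = 1e-12)
})

test_that("gradient flows to the segment embeddings", {
  ns <- asNamespace("rnaligand")
  set.seed(14)
  p <- 3L; q <- 2L; d <- 4L
  cfg <- list(d = d, cf_blocks = 1L, cf_heads = 2L,
              use_graph_view = TRUE, use_sequence_view = TRUE)
  W <- init_cross_fusion_params(d = d, cf_blocks = 1L, cf_heads = 2L,
                                d_ff = 8L, seed = 14L)
  ns$ag_tape_begin()
  B <- ns$ag_bind_params(W)
  rna_view <- list(g_tokens = rand_mat(p, d), s_tokens = rand_mat(p, d), p = p)
  mol_view <- list(g_tokens = rand_mat(q, d), s_tokens = rand_mat(q, d), q = q)
  res <- ns$.cross_forward(B, rna_view, mol_view, cfg)
  loss <- ns$ag_sum_all(ns$ag_square(res$R_cg))
  ns$ag_backward(loss)
  g <- ns$ag_collect_grads(B)
  ns$ag_tape_end()
  expect_true(all(is.finite(g$seg_g)))
  expect_true(all(is.finite(g$seg_s)))
  expect_gt(sum(abs(g$seg_g)), 0)
  expect_gt(sum(abs(g$seg_s)), 0)
})
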