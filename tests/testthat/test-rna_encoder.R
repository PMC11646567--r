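# Loop-written oracles for the graph-attention and convolution layers; all
# frozen expectations below were computed with these oracles.

oracle_gat_coeffs <- function(H, contact, W_d, a, slope = 0.2) {
  p <- nrow(H)
  d <- ncol(W_d)
  out <- matrix(0, p, p)
  for (i in seq_len(p)) {
    nb <- c(i, which(contact[i, ] > 0))
    logits <- vapply(nb, function(n) {
      z <- sum(a * c(crossprod(W_d, H[i, ]), crossprod(W_d, H[n, ])))
      if (z > 0) z else slope * z
    }, numeric(1L))
    e <- exp(logits - max(logits))
    out[i, nb] <- e / sum(e)
  }
  out
}

test_that("attention coefficients are softmax-normalized over the neighbourhood", {
  set.seed(5)
  d <- 3L
  H <- rand_mat(4L, d)
  W_d <- rand_mat(d, d)
  a <- stats::rnorm(2L * d)
  contact <- matrix(0, 4, 4)
  contact[1, 2] <- contact[2, 1] <- 1
  contact[2, 3] <- contact[3, 2] <- 1
  # node with 3 neighbours and identical states: all coefficients 1/4
  Hc <- matrix(rep(H[1, ], 4), 4, byrow = TRUE)
  full <- matrix(1, 4, 4) - diag(1, 4)
  al <- gat_attention_coefficients(Hc, full, W_d, a)
  expect_equal(unname(al[1, ]), rep(0.25, 4), tolerance = 1e-12)
  # isolated node attends only to itself
  al2 <- gat_attention_coefficients(H, contact, W_d, a)
  expect_equal(al2[4, 4], 1)
  expect_equal(sum(al2[4, ]), 1)
  # every row is a probability vector
  expect_equal(rowSums(al2), rep(1, 4), tolerance = 1e-10)
  expect_true(all(al2 >= 0))
  # matches the scalar-arithmetic oracle
  orc <- oracle_gat_coeffs(H, contact, W_d, a)
  expect_equal(al2, orc, tolerance = 1e-10)
})

test_that("one GAT layer matches a hand-computed aggregation on a path graph", {
  set.seed(7)
  d <- 4L
  W <- init_rna_encoder_params(d = d, d_pre = 2L, gat_layers = 1L,
                               gat_heads = 1L, kernel_sizes = 3L, seed = 2L)
  contact <- matrix(0, 3, 3)
  contact[1, 2] <- contact[2, 1] <- 1
  contact[2, 3] <- contact[3, 2] <- 1
  feats <- list(indices = c(0L, 2L, 3L), contact = contact,
                pretrained = rand_mat(3L, 2L))
  res <- gat_encode(feats, W, d = d, gat_layers = 1L, gat_heads = 1L)
  # oracle: explicit Eq-style loop
  H <- W$rna_embed[feats$indices + 1L, ]
  a <- c(W$gat1h1_a1, W$gat1h1_a2)
  alpha <- oracle_gat_coeffs(H, contact, W$gat1h1_Wd, a)
  expected <- matrix(0, 3L, d)
  for (i in 1:3) {
    acc <- numeric(d)
    for (n in which(alpha[i, ] > 0)) {
      acc <- acc + alpha[i, n] * as.numeric(H[n, , drop = FALSE] %*% W$gat1h1_Wa)
    }
    expected[i, ] <- pmax(acc, 0)
  }
  expect_equal(res$tokens, expected, tolerance = 1e-10)
  expect_equal(res$pooled, colMeans(expected), tolerance = 1e-10)
  expect_equal(res$attention[[1L]][[1L]], alpha, tolerance = 1e-10)
})

test_that("a single-nucleotide RNA reduces the GAT layer to ReLU(W_a embed)", {
  W <- init_rna_encoder_params(d = 4L, d_pre = 2L, gat_layers = 1L,
                               gat_heads = 1L, kernel_sizes = 3L, seed = 3L)
  feats <- list(indices = 1L, contact = matrix(0, 1, 1),
                pretrained = rand_mat(1L, 2L))
  res <- gat_encode(feats, W, d = 4L, gat_layers = 1L, gat_heads = 1L)
  expected <- pmax(W$rna_embed[2L, , drop = FALSE] %*% W$gat1h1_Wa, 0)
  expect_equal(res$tokens, expected, tolerance = 1e-12)
})

test_that("the default hidden width is 128", {
  cfg <- rsma_config()
  expect_equal(cfg$d, 128L)
  expect_equal(cfg$lr, 5e-4)
  expect_equal(cfg$batch_size, 16L)
  expect_equal(cfg$dropout, 0.2)
  expect_equal(cfg$weight_decay, 1e-7)
  expect_equal(cfg$kernel_sizes, c(7L, 11L, 15L))
})

test_that("attention rows are probability vectors at every layer and head", {
  set.seed(13)
  W <- init_rna_encoder_params(d = 6L, d_pre = 3L, gat_layers = 2L,
                               gat_heads = 3L, kernel_sizes = 3L, seed = 13L)
  for (trial in 1:20) {
    p <- sample(2:12, 1L)
    contact <- load_or_make_contact_map(p, "synthetic", seed = trial,
                                        density = 0.3)
    feats <- list(indices = sample(0:3, p, replace = TRUE), contact = contact,
                  pretrained = rand_mat(p, 3L))
    res <- gat_encode(feats, W, d = 6L, gat_layers = 2L, gat_heads = 3L)
    for (layer in res$attention) {
      for (al in layer) {
        expect_equal(rowSums(al), rep(1, p), tolerance = 1e-5)
        expect_true(all(al >= 0))
      }
    }
  }
})

test_that("GAT tokens are permutation-equivariant and the pool is invariant", {
  set.seed(19)
  p <- 9L
  W <- init_rna_encoder_params(d = 6L, d_pre = 3L, gat_layers = 2L,
                               gat_heads = 2L, kernel_sizes = 3L, seed = 19L)
  contact <- load_or_make_contact_map(p, "synthetic", seed = 1L, density = 0.3)
  idx <- sample(0:3, p, replace = TRUE)
  feats <- list(indices = idx, contact = contact, pretrained = rand_mat(p, 3L))
  res <- gat_encode(feats, W, d = 6L, gat_layers = 2L, gat_heads = 2L)
  perm <- sample(p)
  feats_p <- list(indices = idx[perm], contact = contact[perm, perm],
                  pretrained = feats$pretrained[perm, , drop = FALSE])
  res_p <- gat_encode(feats_p, W, d = 6L, gat_layers = 2L, gat_heads = 2L)
  expect_equal(res_p$tokens, res$tokens[perm, ], tolerance = 1e-8)
  expect_equal(res_p$pooled, res$pooled, tolerance = 1e-5)
})

test_that("convolution branches preserve sequence length for all odd kernels", {
  W <- init_rna_encoder_params(d = 5L, d_pre = 3L, gat_layers = 1L,
                               gat_heads = 1L, kernel_sizes = c(7L, 11L, 15L),
                               seed = 23L)
  pr <- mock_embedding_provider(3L, 1L)
  for (p in c(1L, 7L, 50L, 301L)) {
    seqs <- paste(sample(c("A", "C", "G", "U"), p, replace = TRUE), collapse = "")
    feats <- list(indices = encode_rna_tokens(seqs),
                  pretrained = pr$fn("x", seqs))
    res <- multiscale_cnn_encode(feats, W, kernel_sizes = c(7L, 11L, 15L))
    expect_equal(nrow(res$tokens), p)
    expect_equal(res$pooled, colMeans(res$tokens), tolerance = 1e-6)
  }
})

test_that("all-zero inputs with zero weights produce all-zero CNN output", {
  d <- 4L
  W <- init_rna_encoder_params(d = d, d_pre = 2L, gat_layers = 1L,
                               gat_heads = 1L, kernel_sizes = c(3L, 5L),
                               seed = 1L)
  W$rna_embed[] <- 0
  W$pre_W[] <- 0
  feats <- list(indices = c(0L, 1L, 2L), pretrained = rand_mat(3L, 2L))
  res <- multiscale_cnn_encode(feats, W, kernel_sizes = c(3L, 5L))
  expect_equal(res$tokens, matrix(0, 3L, d))
})

test_that("the convolution matches the index-by-index summation", {
  set.seed(31)
  p <- 3L; d_in <- 2L; d_out <- 2L; k <- 7L
  input <- rand_mat(p, d_in)
  kern <- rand_mat(k * d_in, d_out)
  got <- conv1d_same(input, kern, k = k)
  # oracle: C(j) = sum_i I_pad(j - i + k) K(i) over the zero-padded input
  pad <- (k - 1L) / 2L
  Ipad <- rbind(matrix(0, pad, d_in), input, matrix(0, pad, d_in))
  expected <- matrix(0, p, d_out)
  for (j in seq_len(p)) {
    for (i in seq_len(k)) {
      Ki <- kern[((i - 1L) * d_in + 1L):(i * d_in), , drop = FALSE]
      expected[j, ] <- expected[j, ] + as.numeric(Ipad[j - i + k, ] %*% Ki)
    }
  }
  expect_equal(got, expected, tolerance = 1e-12)
})
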