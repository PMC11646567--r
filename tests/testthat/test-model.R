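make_pair_features <- function(cfg, seq = "ACGUACGUACGU", smiles = "Cc1ccccc1O",
                               seed = 3L) {
  pr <- mock_embedding_provider(cfg$d_pre, seed)
  rf <- featurize_rna("r", seq, provider = pr, contact_seed = seed,
                      contact_density = cfg$contact_density)
  mf <- featurize_mol("m", smiles)
  list(rf = rf, mf = mf)
}

test_that("all-zero weights give a zero prediction", {
  cfg <- tiny_config()
  P <- init_rsma_params(cfg)
  for (nm in names(P)) P[[nm]][] <- 0
  fx <- make_pair_features(cfg)
  model <- structure(list(params = P, config = cfg, contact_source = "synthetic",
                          provider = mock_embedding_provider(cfg$d_pre, 3L)),
                     class = "rsma_model")
  out <- predict_affinity(model, fx$rf, fx$mf)
  expect_equal(out$yhat, 0)
})

test_that("the full forward matches a composition of the module encoders", {
  cfg <- tiny_config()
  P <- init_rsma_params(cfg)
  fx <- make_pair_features(cfg)
  model <- structure(list(params = P, config = cfg, contact_source = "synthetic",
                          provider = mock_embedding_provider(cfg$d_pre, 3L)),
                     class = "rsma_model")
  got <- predict_affinity(model, fx$rf, fx$mf)

  # compose the same prediction from the exported module functions
  gat <- gat_encode(fx$rf, P, d = cfg$d, gat_layers = cfg$gat_layers,
                    gat_heads = cfg$gat_heads)
  cnn <- multiscale_cnn_encode(fx$rf, P, kernel_sizes = cfg$kernel_sizes)
  gcn <- gcn_encode(fx$mf$graph, P, gcn_layers = cfg$gcn_layers)
  tr <- transformer_encode(fx$mf$tokens, P, d = cfg$d,
                           tr_blocks = cfg$tr_blocks, tr_heads = cfg$tr_heads,
                           max_smiles_len = cfg$max_smiles_len)
  cf <- cross_fusion_encode(gat$tokens, cnn$tokens, gcn$tokens, tr$tokens, P,
                            cf_blocks = cfg$cf_blocks, cf_heads = cfg$cf_heads)
  mlp <- function(x, pre) {
    h <- pmax(x %*% P[[paste0(pre, "_W1")]] + rep(P[[paste0(pre, "_b1")]][1, ],
                                                  each = 1), 0)
    h %*% P[[paste0(pre, "_W2")]] + rep(P[[paste0(pre, "_b2")]][1, ], each = 1)
  }
  rX <- cbind(matrix((gat$pooled + cf$R_cg) / 2, 1),
              matrix((cnn$pooled + cf$R_cs) / 2, 1))
  mX <- cbind(matrix((gcn$pooled + cf$M_cg) / 2, 1),
              matrix((tr$pooled + cf$M_cs) / 2, 1))
  R <- mlp(rX, "rhead"); M <- mlp(mX, "mhead")
  z <- pmax(cbind(R, M) %*% P$out_W1 + rep(P$out_b1[1, ], each = 1), 0)
  want <- (z %*% P$out_W2 + P$out_b2[1, 1])[1, 1]
  expect_equal(got$yhat, want, tolerance = 1e-8)
})

test_that("evaluation-mode prediction is exactly deterministic", {
  cfg <- tiny_config(dropout = 0.3) # dropout present but disabled at eval
  P <- init_rsma_params(cfg)
  fx <- make_pair_features(cfg)
  model <- structure(list(params = P, config = cfg, contact_source = "synthetic",
                          provider = mock_embedding_provider(cfg$d_pre, 3L)),
                     class = "rsma_model")
  y1 <- predict_affinity(model, fx$rf, fx$mf)$yhat
  y2 <- predict_affinity(model, fx$rf, fx$mf)$yhat
  expect_identical(y1, y2)
})

test_that("batch prediction preserves order and matches single-pair calls", {
  gen <- small_synthetic(seed = 5L, n_pairs = 6L)
  ds <- gen$dataset
  cfg <- tiny_config()
  fit <- suppressMessages(rsma_train(ds, cfg, provider = gen$provider,
                                     val_fraction = 0))
  preds <- predict_batch(fit, ds)
  expect_equal(nrow(preds), 6L)
  expect_equal(preds$rna_id, ds$pairs$rna_id)
  # per-pair forward agrees with the batch path
  for (i in c(1L, 4L)) {
    r <- ds$rnas[ds$rnas$id == ds$pairs$rna_id[i], ]
    m <- ds$molecules[ds$molecules$id == ds$pairs$mol_id[i], ]
    rf <- featurize_rna(r$id, r$sequence, provider = fit$provider,
                        contact_seed = cfg$seed,
                        contact_density = cfg$contact_density)
    mf <- featurize_mol(m$id, m$smiles)
    expect_equal(predict_affinity(fit, rf, mf)$yhat, preds$affinity_pred[i],
                 tolerance = 1e-12)
  }
  expect_error(predict_batch(fit, ds, tibble::tibble(rna_id = "nope",
                                                     mol_id = ds$pairs$mol_id[1])),
               "unknown rna_id")
})

test_that("checkpoints reload to bit-identical predictions", {
  gen <- small_synthetic(seed = 6L, n_pairs = 6L)
  cfg <- tiny_config(epochs = 1L)
  fit <- suppressMessages(rsma_train(gen$dataset, cfg, provider = gen$provider,
                                     val_fraction = 0))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  fit2 <- load_checkpoint(path)
  p1 <- predict_batch(fit, gen$dataset)
  p2 <- predict_batch(fit2, gen$dataset)
  expect_identical(p1$affinity_pred, p2$affinity_pred)
})

test_that("disabling both views is rejected", {
  expect_error(rsma_config(use_graph_view = FALSE, use_sequence_view = FALSE),
               "at least one")
})
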