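# End-to-end affinity predictor: four encoder streams, cross-fusion, and
# the prediction head
#   R = MLP([mean(Rg_pool, Rcg), mean(Rs_pool, Rcs)])
#   M = MLP([mean(Mg_pool, Mcg), mean(Ms_pool, Mcs)])
#   yhat = MLP([R, M])
# trained with mini-batch MSE and Adam. Ablation switches: dropping the
# graph or sequence view removes the corresponding halves of the
# concatenations (the head is sized accordingly); dropping fusion replaces
# the cross terms by the encoder pooled vectors (mean(x, x) = x).

#' Model configuration
#'
#' Defaults encode the published training recipe (hidden width 128, kernel
#' sizes 7/11/15, learning rate 5e-4, batch size 16, dropout 0.2, weight
#' decay 1e-7) plus declared choices for what the recipe leaves open
#' (depths, head counts, LeakyReLU slope, epochs and early stopping).
#'
#' @param d Hidden width.
#' @param d_pre Pretrained-embedding width the provider supplies.
#' @param kernel_sizes Odd 1D-CNN kernel sizes.
#' @param gat_layers,gat_heads RNA graph-encoder depth and heads.
#' @param leaky_slope LeakyReLU negative slope in GAT logits.
#' @param gcn_layers Molecule graph-encoder depth.
#' @param tr_blocks,tr_heads SMILES Transformer depth and heads.
#' @param cf_blocks,cf_heads Cross-fusion depth and heads.
#' @param d_ff Feed-forward inner width of Transformer/cross blocks.
#' @param dropout Dropout rate inside the head MLPs.
#' @param lr,batch_size,weight_decay,epochs,patience Training settings;
#'   `patience` is early-stopping patience on validation MSE.
#' @param seed Seed controlling initialization, shuffling, and dropout.
#' @param max_rna_len,max_smiles_len Hard input-length limits.
#' @param contact_density Long-range density for synthetic contact maps.
#' @param use_graph_view,use_sequence_view,use_fusion Ablation switches.
#' @return A list of class `rsma_config`.
#' @export
rsma_config <- function(d = 128L, d_pre = 16L, kernel_sizes = c(7L, 11L, 15L),
                        gat_layers = 2L, gat_heads = 4L, leaky_slope = 0.2,
                        gcn_layers = 2L, tr_blocks = 2L, tr_heads = 4L,
                        cf_blocks = 1L, cf_heads = 4L, d_ff = 2L * d,
                        dropout = 0.2, lr = 5e-4, batch_size = 16L,
                        weight_decay = 1e-7, epochs = 100L, patience = 20L,
                        seed = 1L, max_rna_len = 512L, max_smiles_len = 128L,
                        contact_density = 0.05,
                        use_graph_view = TRUE, use_sequence_view = TRUE,
                        use_fusion = TRUE) {
  if (!use_graph_view && !use_sequence_view) {
    stop("at least one of the graph and sequence views must be enabled",
         call. = FALSE)
  }
  stopifnot(dropout >= 0, dropout < 1, all(kernel_sizes %% 2L == 1L),
            d %% tr_heads == 0L, d %% cf_heads == 0L, gat_layers >= 1L,
            gcn_layers >= 1L)
  structure(list(
    d = as.integer(d), d_pre = as.integer(d_pre),
    kernel_sizes = as.integer(kernel_sizes),
    gat_layers = as.integer(gat_layers), gat_heads = as.integer(gat_heads),
    leaky_slope = leaky_slope, gcn_layers = as.integer(gcn_layers),
    tr_blocks = as.integer(tr_blocks), tr_heads = as.integer(tr_heads),
    cf_blocks = as.integer(cf_blocks), cf_heads = as.integer(cf_heads),
    d_ff = as.integer(d_ff), dropout = dropout, lr = lr,
    batch_size = as.integer(batch_size), weight_decay = weight_decay,
    epochs = as.integer(epochs), patience = as.integer(patience),
    seed = as.integer(seed), max_rna_len = as.integer(max_rna_len),
    max_smiles_len = as.integer(max_smiles_len),
    contact_density = contact_density,
    use_graph_view = use_graph_view, use_sequence_view = use_sequence_view,
    use_fusion = use_fusion
  ), class = "rsma_config")
}

#' Initialize all model weights for a configuration
#'
#' @param config An [rsma_config()].
#' @return Named list of weight matrices.
#' @export
init_rsma_params <- function(config) {
  cfg <- config
  P <- list()
  if (cfg$use_sequence_view || cfg$use_graph_view) {
    P <- c(P, init_rna_encoder_params(
      d = cfg$d, d_pre = cfg$d_pre, gat_layers = cfg$gat_layers,
      gat_heads = cfg$gat_heads, kernel_sizes = cfg$kernel_sizes,
      seed = cfg$seed))
    P <- c(P, init_mol_encoder_params(
      d = cfg$d, gcn_layers = cfg$gcn_layers, tr_blocks = cfg$tr_blocks,
      tr_heads = cfg$tr_heads, d_ff = cfg$d_ff,
      max_smiles_len = cfg$max_smiles_len, seed = cfg$seed + 1L))
  }
  if (cfg$use_fusion) {
    P <- c(P, init_cross_fusion_params(
      d = cfg$d, cf_blocks = cfg$cf_blocks, cf_heads = cfg$cf_heads,
      d_ff = cfg$d_ff, seed = cfg$seed + 2L))
  }
  v <- cfg$use_graph_view + cfg$use_sequence_view
  P <- c(P, with_preserved_rng(cfg$seed + 3L, list(
    rhead_W1 = init_weight(v * cfg$d, cfg$d), rhead_b1 = init_bias(cfg$d),
    rhead_W2 = init_weight(cfg$d, cfg$d), rhead_b2 = init_bias(cfg$d),
    mhead_W1 = init_weight(v * cfg$d, cfg$d), mhead_b1 = init_bias(cfg$d),
    mhead_W2 = init_weight(cfg$d, cfg$d), mhead_b2 = init_bias(cfg$d),
    out_W1 = init_weight(2L * cfg$d, cfg$d), out_b1 = init_bias(cfg$d),
    # zero-started output layer: an untrained model predicts a constant, so
    # feature dependence in the output only arises from gradient signal
    out_W2 = matrix(0, cfg$d, 1L), out_b2 = init_bias(1L)
  )))
  P
}

# Two-layer MLP with ReLU + dropout between the layers.
.head_mlp <- function(x, P, prefix, dropout, training) {
  h <- ag_dropout(ag_relu(ag_affine(x, P[[paste0(prefix, "_W1")]],
                                    P[[paste0(prefix, "_b1")]])),
                  dropout, training)
  ag_affine(h, P[[paste0(prefix, "_W2")]], P[[paste0(prefix, "_b2")]])
}

# Compose the prediction head from the pooled view vectors (each 1 x d
# nodes or matrices; NULL when the view is disabled).
.head_forward <- function(P, pooled, cfg, training) {
  half <- function(a, b) ag_scale(ag_add(a, b), 0.5)
  rparts <- list(); mparts <- list()
  if (cfg$use_graph_view) {
    rparts <- c(rparts, list(if (cfg$use_fusion) half(pooled$Rg, pooled$Rcg) else pooled$Rg))
    mparts <- c(mparts, list(if (cfg$use_fusion) half(pooled$Mg, pooled$Mcg) else pooled$Mg))
  }
  if (cfg$use_sequence_view) {
    rparts <- c(rparts, list(if (cfg$use_fusion) half(pooled$Rs, pooled$Rcs) else pooled$Rs))
    mparts <- c(mparts, list(if (cfg$use_fusion) half(pooled$Ms, pooled$Mcs) else pooled$Ms))
  }
  rX <- if (length(rparts) == 1L) rparts[[1L]] else ag_cbind(rparts)
  mX <- if (length(mparts) == 1L) mparts[[1L]] else ag_cbind(mparts)
  R <- .head_mlp(rX, P, "rhead", cfg$dropout, training)
  M <- .head_mlp(mX, P, "mhead", cfg$dropout, training)
  z <- ag_dropout(ag_relu(ag_affine(ag_cbind(list(R, M)), P$out_W1, P$out_b1)),
                  cfg$dropout, training)
  ag_affine(z, P$out_W2, P$out_b2)
}

# Full forward pass for one (RNA, molecule) pair.
.pair_forward <- function(P, rfeat, mfeat, cfg, training = FALSE) {
  pooled <- list()
  rna_view <- list(p = rfeat$p)
  mol_view <- list(q = mfeat$q)
  if (cfg$use_graph_view) {
    gat <- .gat_forward(P, rfeat, cfg)
    gcn <- .gcn_forward(P, mfeat$graph, cfg)
    pooled$Rg <- gat$pooled; pooled$Mg <- gcn$pooled
    rna_view$g_tokens <- gat$tokens; mol_view$g_tokens <- gcn$tokens
  }
  if (cfg$use_sequence_view) {
    cnn <- .cnn_forward(P, rfeat, cfg)
    tr <- .transformer_forward(P, mfeat$tokens, cfg, ids = mfeat$token_ids)
    pooled$Rs <- cnn$pooled; pooled$Ms <- tr$pooled
    rna_view$s_tokens <- cnn$tokens; mol_view$s_tokens <- tr$tokens
  }
  attention <- NULL
  if (cfg$use_fusion) {
    cf <- .cross_forward(P, rna_view, mol_view, cfg)
    pooled$Rcg <- cf$R_cg; pooled$Rcs <- cf$R_cs
    pooled$Mcg <- cf$M_cg; pooled$Mcs <- cf$M_cs
    attention <- cf$attention
  }
  yhat <- .head_forward(P, pooled, cfg, training)
  list(yhat = yhat, attention = attention)
}

## ---- feature caches -------------------------------------------------------

.featurize_dataset <- function(dataset, cfg, contact_source, provider) {
  rfe <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(dataset$rnas))) {
    r <- dataset$rnas[i, ]
    assign(r$id, featurize_rna(
      r$id, r$sequence, contact_source = contact_source, provider = provider,
      contact_density = cfg$contact_density, contact_seed = cfg$seed,
      max_len = cfg$max_rna_len), envir = rfe)
  }
  mfe <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(dataset$molecules))) {
    m <- dataset$molecules[i, ]
    assign(m$id, featurize_mol(m$id, m$smiles), envir = mfe)
  }
  list(rna = rfe, mol = mfe)
}

## ---- training -------------------------------------------------------------

#' Train the affinity model
#'
#' Mini-batch mean-squared-error minimization with Adam. Batches are
#' processed pair-by-pair with gradient accumulation (predictions are
#' therefore exactly independent of batch size); per-epoch training and
#' validation MSE are logged, and early stopping restores the best
#' validation-epoch weights.
#'
#' @param dataset An [rsma_dataset()].
#' @param config An [rsma_config()].
#' @param contact_source `"synthetic"` or a directory of contact-map files.
#' @param provider An embedding provider; defaults to the deterministic
#'   mock provider at the configured width.
#' @param val_fraction Fraction of pairs held out for validation (seeded).
#'   With 0, the training loss doubles as the validation series.
#' @param verbose Print per-epoch losses.
#' @return An object of class `rsma_model`: weights, config, loss history
#'   (tibble with epoch, train_mse, val_mse), the provider, and training
#'   state (optimizer snapshot, epoch, RNG state) for checkpointing.
#' @export
rsma_train <- function(dataset, config = rsma_config(),
                       contact_source = "synthetic",
                       provider = mock_embedding_provider(d_pre = config$d_pre,
                                                          seed = config$seed),
                       val_fraction = 0.1, verbose = FALSE) {
  cfg <- config
  stopifnot(inherits(dataset, "rsma_dataset"), nrow(dataset$pairs) >= 1L)
  cfg$d_pre <- provider$d_pre # the provider defines the pretrained width
  set.seed(cfg$seed)
  feats <- .featurize_dataset(dataset, cfg, contact_source, provider)
  pairs <- dataset$pairs
  n <- nrow(pairs)

  n_val <- floor(val_fraction * n)
  val_idx <- if (n_val >= 1L) sample.int(n, n_val) else integer(0)
  train_idx <- setdiff(seq_len(n), val_idx)

  params <- init_rsma_params(cfg)
  # start the output bias at the training-label mean (target centering):
  # with the zero-started output layer the untrained model then predicts
  # the mean exactly, so no mean-fitting phase leaks feature structure
  # into the output weights
  params$out_b2[] <- mean(pairs$affinity[train_idx])
  opt <- adam_new(params, lr = cfg$lr, weight_decay = cfg$weight_decay)

  eval_mse <- function(P, idx) {
    if (!length(idx)) return(NA_real_)
    se <- vapply(idx, function(i) {
      rf <- get(pairs$rna_id[i], envir = feats$rna)
      mf <- get(pairs$mol_id[i], envir = feats$mol)
      y <- .pair_forward(P, rf, mf, cfg, training = FALSE)$yhat
      (ag_value(y)[1L] - pairs$affinity[i])^2
    }, numeric(1L))
    mean(se)
  }

  history <- vector("list", cfg$epochs)
  best_val <- Inf; best_params <- params; best_epoch <- 0L; wait <- 0L
  epoch_done <- 0L

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(train_idx)
    batch_starts <- seq(1L, length(ord), by = cfg$batch_size)
    ep_losses <- numeric(0)
    for (bs in batch_starts) {
      bidx <- ord[bs:min(bs + cfg$batch_size - 1L, length(ord))]
      bn <- length(bidx)
      acc <- NULL
      for (i in bidx) {
        rf <- get(pairs$rna_id[i], envir = feats$rna)
        mf <- get(pairs$mol_id[i], envir = feats$mol)
        ag_tape_begin()
        B <- ag_bind_params(params)
        out <- .pair_forward(B, rf, mf, cfg, training = TRUE)
        loss <- ag_square(ag_shift(out$yhat, -pairs$affinity[i]))
        lv <- ag_value(loss)[1L]
        if (!is.finite(lv)) {
          ag_tape_end()
          stop("non-finite training loss at epoch ", epoch, ", pair (",
               pairs$rna_id[i], ", ", pairs$mol_id[i], "); loss = ", lv,
               call. = FALSE)
        }
        ep_losses <- c(ep_losses, lv)
        ag_backward(loss)
        g <- ag_collect_grads(B)
        ag_tape_end()
        if (is.null(acc)) {
          acc <- lapply(g, function(x) x / bn)
        } else {
          for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]] / bn
        }
      }
      params <- adam_step(opt, params, acc)
    }
    train_mse <- mean(ep_losses)
    val_mse <- if (length(val_idx)) eval_mse(params, val_idx) else train_mse
    history[[epoch]] <- c(epoch = epoch, train_mse = train_mse, val_mse = val_mse)
    if (verbose) {
      message(sprintf("epoch %3d  train_mse %.4f  val_mse %.4f",
                      epoch, train_mse, val_mse))
    }
    epoch_done <- epoch
    if (val_mse < best_val - 1e-12) {
      best_val <- val_mse; best_params <- params
      best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }

  hist <- tibble::as_tibble(do.call(rbind, history[seq_len(epoch_done)]))
  structure(list(
    params = best_params, config = cfg, history = hist,
    provider = provider, contact_source = contact_source,
    optimizer = adam_state_snapshot(opt), epoch = epoch_done,
    best_epoch = best_epoch,
    rng_state = get(".Random.seed", envir = globalenv())
  ), class = "rsma_model")
}

#' @export
print.rsma_model <- function(x, ...) {
  cfg <- x$config
  views <- c(if (cfg$use_graph_view) "graph", if (cfg$use_sequence_view) "sequence")
  cat("<rsma_model> d=", cfg$d, " | views: ", paste(views, collapse = "+"),
      if (cfg$use_fusion) " | cross-fusion" else " | no fusion",
      "\n  trained ", x$epoch, " epoch(s); best epoch ", x$best_epoch,
      " (val MSE ", signif(min(x$history$val_mse), 4), ")\n", sep = "")
  invisible(x)
}

#' Predict the affinity of a single RNA-molecule pair
#'
#' Evaluation-mode forward pass (dropout disabled, hence deterministic).
#'
#' @param model An [rsma_train()] fit (or assembled `rsma_model`).
#' @param rna_features A [featurize_rna()] bundle.
#' @param mol_features A [featurize_mol()] bundle.
#' @return List with `yhat` (predicted pKd) and `attention` (cross-fusion
#'   score matrices, `NULL` when fusion is disabled).
#' @export
predict_affinity <- function(model, rna_features, mol_features) {
  out <- .pair_forward(model$params, rna_features, mol_features,
                       model$config, training = FALSE)
  list(yhat = ag_value(out$yhat)[1L], attention = out$attention)
}

#' Predict affinities for a table of pairs
#'
#' @param model An `rsma_model`.
#' @param dataset The [rsma_dataset()] that resolves the ids.
#' @param pairs Tibble with `rna_id`, `mol_id` (defaults to all dataset
#'   pairs). Row order is preserved.
#' @return Tibble: `rna_id`, `mol_id`, (`affinity_true` when available),
#'   `affinity_pred`.
#' @export
predict_batch <- function(model, dataset, pairs = NULL) {
  if (is.null(pairs)) pairs <- dataset$pairs
  pairs <- tibble::as_tibble(pairs)
  bad_r <- setdiff(pairs$rna_id, dataset$rnas$id)
  if (length(bad_r)) stop("unknown rna_id: ", paste(bad_r, collapse = ", "),
                          call. = FALSE)
  bad_m <- setdiff(pairs$mol_id, dataset$molecules$id)
  if (length(bad_m)) stop("unknown mol_id: ", paste(bad_m, collapse = ", "),
                          call. = FALSE)
  need <- list(rnas = dataset$rnas[dataset$rnas$id %in% pairs$rna_id, ],
               molecules = dataset$molecules[dataset$molecules$id %in% pairs$mol_id, ])
  sub <- structure(list(rnas = need$rnas, molecules = need$molecules,
                        pairs = pairs), class = "rsma_dataset")
  feats <- .featurize_dataset(sub, model$config, model$contact_source,
                              model$provider)
  preds <- vapply(seq_len(nrow(pairs)), function(i) {
    rf <- get(pairs$rna_id[i], envir = feats$rna)
    mf <- get(pairs$mol_id[i], envir = feats$mol)
    ag_value(.pair_forward(model$params, rf, mf, model$config,
                           training = FALSE)$yhat)[1L]
  }, numeric(1L))
  out <- tibble::tibble(rna_id = pairs$rna_id, mol_id = pairs$mol_id)
  if ("affinity" %in% names(pairs)) out$affinity_true <- pairs$affinity
  out$affinity_pred <- preds
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single-file archive of the config, all weights, the
#' optimizer state, the epoch counter, and the RNG state; reloading
#' reproduces forward outputs bit-for-bit.
#'
#' @param model An `rsma_model`.
#' @param path Destination file.
#' @return `path` invisibly for save; the model for load.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "rsma_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "rsma_model"))
  model
}

#' Loss-history plot
#'
#' @param model An `rsma_model`.
#' @return A ggplot object with training and validation MSE per epoch.
#' @export
plot_loss_curve <- function(model) {
  h <- model$history
  df <- tibble::tibble(
    epoch = rep(h$epoch, 2L),
    mse = c(h$train_mse, h$val_mse),
    series = rep(c("train", "validation"), each = nrow(h))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "MSE (pKd^2)", colour = NULL) +
    ggplot2::theme_minimal()
}
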