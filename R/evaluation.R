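# Experimental designs: stratified k-fold CV over a continuous target,
# blind (cold) splits by entity, independent-test leakage filtering, and
# the regression/classification metric set.

#' Build a cross-validation split plan
#'
#' Modes: `stratified_kfold` bins affinities into quantile bins and deals
#' bin members round-robin across folds (so every fold tracks the global
#' affinity distribution); `blind_rna` / `blind_mol` partition entity ids
#' so no entity appears in two folds and pairs follow their entity;
#' `all_blind` partitions RNA ids and molecule ids jointly and keeps only
#' pairs whose two entities land in the same fold (others get fold `NA` and
#' take no part in CV).
#'
#' @param dataset An [rsma_dataset()].
#' @param mode One of `"stratified_kfold"`, `"blind_rna"`, `"blind_mol"`,
#'   `"all_blind"`.
#' @param k Number of folds (>= 2).
#' @param seed Seed for the shuffles.
#' @param n_bins Quantile bins for stratification.
#' @return Tibble with `pair_index`, `fold`; attributes `mode`, `k`,
#'   `seed`.
#' @export
make_splits <- function(dataset, mode = c("stratified_kfold", "blind_rna",
                                          "blind_mol", "all_blind"),
                        k = 5L, seed = 1L, n_bins = 10L) {
  mode <- match.arg(mode)
  stopifnot(k >= 2L)
  pairs <- dataset$pairs
  n <- nrow(pairs)
  fold <- rep(NA_integer_, n)

  deal <- function(ids) {
    # seeded shuffle, then round-robin
    stats::setNames(rep_len(seq_len(k), length(ids)), sample(ids))
  }

  with_preserved_rng(seed, {
    if (mode == "stratified_kfold") {
      y <- pairs$affinity
      br <- unique(stats::quantile(y, probs = seq(0, 1, length.out = n_bins + 1L)))
      bin <- cut(y, breaks = br, include.lowest = TRUE, labels = FALSE)
      ptr <- 0L
      for (b in sort(unique(bin))) {
        members <- sample(which(bin == b))
        fold[members] <- ((ptr + seq_along(members) - 1L) %% k) + 1L
        ptr <- ptr + length(members)
      }
    } else if (mode %in% c("blind_rna", "blind_mol")) {
      col <- if (mode == "blind_rna") "rna_id" else "mol_id"
      ids <- unique(pairs[[col]])
      if (length(ids) < k) {
        stop("blind mode needs at least k distinct entities (", length(ids),
             " < ", k, ")", call. = FALSE)
      }
      fmap <- deal(ids)
      fold <- unname(fmap[pairs[[col]]])
    } else { # all_blind
      rids <- unique(pairs$rna_id)
      mids <- unique(pairs$mol_id)
      if (length(rids) < k || length(mids) < k) {
        stop("all_blind needs at least k distinct RNAs and molecules",
             call. = FALSE)
      }
      rmap <- deal(rids)
      mmap <- deal(mids)
      fr <- unname(rmap[pairs$rna_id])
      fm <- unname(mmap[pairs$mol_id])
      fold <- ifelse(fr == fm, fr, NA_integer_)
    }
  })

  out <- tibble::tibble(pair_index = seq_len(n), fold = as.integer(fold))
  attr(out, "mode") <- mode
  attr(out, "k") <- as.integer(k)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Regression metrics: Pearson, Spearman, RMSE
#'
#' @param y_true,y_pred Numeric vectors of equal length >= 2; `y_true` must
#'   not be constant.
#' @return One-row tibble with `pcc`, `scc`, `rmse`, `n`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2L)
  if (stats::sd(y_true) == 0) {
    stop("y_true is constant; correlation undefined", call. = FALSE)
  }
  tibble::tibble(
    pcc = stats::cor(y_true, y_pred, method = "pearson"),
    scc = stats::cor(y_true, y_pred, method = "spearman"),
    rmse = sqrt(mean((y_true - y_pred)^2)),
    n = length(y_true)
  )
}

#' Classification metrics after thresholding a regression target
#'
#' Labels are `y_true >= threshold`; predicted labels for specificity and
#' balanced accuracy threshold `y_pred` the same way; AUC ranks the raw
#' predictions as scores (ties get half credit).
#'
#' @param y_true,y_pred Numeric vectors.
#' @param threshold Decision threshold on the pKd scale (default 4.0).
#' @return One-row tibble with `specificity`, `bacc`, `auc`, `n`.
#' @export
classification_metrics <- function(y_true, y_pred, threshold = 4.0) {
  stopifnot(length(y_true) == length(y_pred))
  lab <- y_true >= threshold
  if (all(lab) || !any(lab)) {
    stop("both classes must be present after thresholding", call. = FALSE)
  }
  pred <- y_pred >= threshold
  tp <- sum(lab & pred); fn <- sum(lab & !pred)
  tn <- sum(!lab & !pred); fp <- sum(!lab & pred)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  r <- rank(y_pred) # average ranks -> 0.5 credit for ties
  n1 <- sum(lab); n0 <- sum(!lab)
  auc <- (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  tibble::tibble(specificity = spec, bacc = (sens + spec) / 2, auc = auc,
                 n = length(y_true))
}

#' Tanimoto coefficient between two binary fingerprints
#'
#' |A intersect B| / |A union B| over on-bit sets; 0 when both sets are
#' empty (declared convention).
#'
#' @param fp_a,fp_b Integer vectors of on-bit positions (see
#'   [mol_fingerprint()]).
#' @return Numeric in `[0, 1]`.
#' @export
tanimoto <- function(fp_a, fp_b) {
  u <- length(union(fp_a, fp_b))
  if (u == 0L) return(0)
  length(intersect(fp_a, fp_b)) / u
}

#' Global-alignment sequence identity between two RNAs
#'
#' Needleman-Wunsch with unit match score and zero mismatch/gap penalties
#' (so the score counts the best co-linear matching), divided by the longer
#' sequence length.
#'
#' @param seq_a,seq_b RNA sequence strings.
#' @return Numeric in `[0, 1]`.
#' @export
rna_identity <- function(seq_a, seq_b) {
  letters4 <- c("A", "C", "G", "U")
  mat <- matrix(0, 4L, 4L, dimnames = list(letters4, letters4))
  diag(mat) <- 1
  al <- Biostrings::pairwiseAlignment(
    Biostrings::BString(seq_a), Biostrings::BString(seq_b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 0
  )
  Biostrings::score(al) / max(nchar(seq_a), nchar(seq_b))
}

#' Remove training entities similar to an independent test set
#'
#' Drops training molecules whose maximum Tanimoto similarity to any test
#' molecule reaches `mol_sim_threshold`, and training RNAs whose global
#' sequence identity to any test RNA reaches `rna_id_threshold`; all pairs
#' touching a removed entity go with it. Thresholds are configuration, not
#' derived values; defaults are declared assumptions.
#'
#' @param train,test [rsma_dataset()] objects.
#' @param mol_sim_threshold Tanimoto threshold in `[0, 1]`.
#' @param rna_id_threshold Identity threshold in `[0, 1]`.
#' @return List with `train` (filtered dataset) and `removed` (tibble:
#'   `type`, `id`, `max_similarity`).
#' @export
independent_filter <- function(train, test, mol_sim_threshold = 0.8,
                               rna_id_threshold = 0.8) {
  stopifnot(mol_sim_threshold >= 0, mol_sim_threshold <= 1,
            rna_id_threshold >= 0, rna_id_threshold <= 1)
  test_fps <- lapply(test$molecules$smiles, mol_fingerprint)
  mol_max <- vapply(train$molecules$smiles, function(s) {
    fp <- mol_fingerprint(s)
    max(vapply(test_fps, function(tf) tanimoto(fp, tf), numeric(1L)))
  }, numeric(1L))
  rna_max <- vapply(train$rnas$sequence, function(s) {
    max(vapply(test$rnas$sequence, function(ts) rna_identity(s, ts), numeric(1L)))
  }, numeric(1L))

  drop_m <- train$molecules$id[mol_max >= mol_sim_threshold]
  drop_r <- train$rnas$id[rna_max >= rna_id_threshold]
  removed <- rbind(
    tibble::tibble(type = "molecule", id = drop_m,
                   max_similarity = mol_max[mol_max >= mol_sim_threshold]),
    tibble::tibble(type = "rna", id = drop_r,
                   max_similarity = rna_max[rna_max >= rna_id_threshold])
  )

  keep <- !(train$pairs$rna_id %in% drop_r | train$pairs$mol_id %in% drop_m)
  filtered <- structure(list(
    rnas = train$rnas[!train$rnas$id %in% drop_r, ],
    molecules = train$molecules[!train$molecules$id %in% drop_m, ],
    pairs = train$pairs[keep, ]
  ), class = "rsma_dataset")
  list(train = filtered, removed = tibble::as_tibble(removed))
}

#' Run cross-validation for a split plan
#'
#' Trains on k-1 folds and evaluates on the held-out fold, for every fold
#' and every seed in `seeds`; reports per-fold metrics and their
#' mean/standard deviation. Folds whose test side breaks a metric
#' precondition (fewer than 2 pairs, constant target, single class) carry
#' the failure message in the `note` column with `NA` metrics.
#'
#' @param dataset An [rsma_dataset()].
#' @param config An [rsma_config()]; its seed is replaced by each entry of
#'   `seeds` in turn.
#' @param split_plan A [make_splits()] plan.
#' @param seeds Integer vector of training seeds (default: the config
#'   seed).
#' @param contact_source,provider Passed to [rsma_train()].
#' @param val_fraction Validation fraction inside each training run.
#' @param class_threshold pKd threshold for the classification metrics.
#' @param verbose Print progress.
#' @return List of class `rsma_cv_report`: `folds` (per seed x fold
#'   tibble) and `aggregate` (metric, mean, sd).
#' @export
run_cv <- function(dataset, config, split_plan, seeds = NULL,
                   contact_source = "synthetic", provider = NULL,
                   val_fraction = 0.1, class_threshold = 4.0,
                   verbose = FALSE) {
  if (is.null(seeds)) seeds <- config$seed
  k <- attr(split_plan, "k")
  rows <- list()
  for (seed in seeds) {
    cfg <- config
    cfg$seed <- as.integer(seed)
    prov <- if (is.null(provider)) {
      mock_embedding_provider(d_pre = cfg$d_pre, seed = cfg$seed)
    } else provider
    for (f in seq_len(k)) {
      test_i <- which(split_plan$fold == f)
      train_i <- which(!is.na(split_plan$fold) & split_plan$fold != f)
      sub_train <- structure(list(
        rnas = dataset$rnas, molecules = dataset$molecules,
        pairs = dataset$pairs[train_i, ]
      ), class = "rsma_dataset")
      fit <- rsma_train(sub_train, cfg, contact_source = contact_source,
                        provider = prov, val_fraction = val_fraction)
      test_pairs <- dataset$pairs[test_i, ]
      row <- tibble::tibble(seed = seed, fold = f, n = length(test_i),
                            pcc = NA_real_, scc = NA_real_, rmse = NA_real_,
                            specificity = NA_real_, bacc = NA_real_,
                            auc = NA_real_, note = NA_character_)
      res <- tryCatch({
        preds <- predict_batch(fit, dataset, test_pairs)
        reg <- regression_metrics(preds$affinity_true, preds$affinity_pred)
        row$pcc <- reg$pcc; row$scc <- reg$scc; row$rmse <- reg$rmse
        cls <- tryCatch(
          classification_metrics(preds$affinity_true, preds$affinity_pred,
                                 threshold = class_threshold),
          error = function(e) NULL)
        if (!is.null(cls)) {
          row$specificity <- cls$specificity
          row$bacc <- cls$bacc
          row$auc <- cls$auc
        }
        row
      }, error = function(e) {
        row$note <- conditionMessage(e)
        row
      })
      if (verbose) message("seed ", seed, " fold ", f, " done")
      rows[[length(rows) + 1L]] <- res
    }
  }
  folds <- dplyr::bind_rows(rows)
  metrics <- c("pcc", "scc", "rmse", "specificity", "bacc", "auc")
  aggregate <- tibble::tibble(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(folds[[m]], na.rm = TRUE),
                  numeric(1L), USE.NAMES = FALSE),
    sd = vapply(metrics, function(m) stats::sd(folds[[m]], na.rm = TRUE),
                numeric(1L), USE.NAMES = FALSE)
  )
  structure(list(folds = folds, aggregate = aggregate),
            class = "rsma_cv_report")
}

#' @export
print.rsma_cv_report <- function(x, ...) {
  cat("<rsma_cv_report> ", nrow(x$folds), " fold evaluations\n", sep = "")
  print(x$aggregate)
  invisible(x)
}
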