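# Brute-force metric oracles written as explicit formulas/loops.

oracle_pcc <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
oracle_scc <- function(x, y) oracle_pcc(rank(x), rank(y))
oracle_rmse <- function(x, y) sqrt(sum((x - y)^2) / length(x))
oracle_auc <- function(lab, score) {
  pos <- which(lab); neg <- which(!lab)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
  }
  tot / (length(pos) * length(neg))
}

test_that("regression metrics match explicit-formula oracles", {
  set.seed(2)
  y <- rnorm(20)
  expect_equal(regression_metrics(y, y)$pcc, 1)
  expect_equal(regression_metrics(y, y)$scc, 1)
  expect_equal(regression_metrics(y, y)$rmse, 0)
  expect_equal(regression_metrics(y, -(y - mean(y)))$pcc, -1, tolerance = 1e-12)
  for (trial in 1:20) {
    a <- rnorm(50); b <- rnorm(50) + 0.4 * a
    m <- regression_metrics(a, b)
    expect_equal(m$pcc, oracle_pcc(a, b), tolerance = 1e-10)
    expect_equal(m$scc, oracle_scc(a, b), tolerance = 1e-10)
    expect_equal(m$rmse, oracle_rmse(a, b), tolerance = 1e-10)
  }
  expect_error(regression_metrics(rep(1, 5), rnorm(5)), "constant")
})

test_that("classification metrics follow the 4.0 threshold convention", {
  # default threshold is 4.0
  expect_equal(formals(classification_metrics)$threshold, 4.0)
  y <- c(6, 5, 3, 2); s <- c(5.5, 4.5, 3.5, 2.5)
  m <- classification_metrics(y, s)
  expect_equal(m$specificity, 1)
  expect_equal(m$bacc, 1)
  expect_equal(m$auc, 1)
  # pair-counting oracle on a mixed example: labels [1,1,0,0]
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  sc <- c(0.9, 0.4, 0.6, 0.1)
  m2 <- classification_metrics(ifelse(lab, 5, 3), sc)
  expect_equal(m2$auc, oracle_auc(lab, sc))
  expect_equal(m2$auc, 0.75)
  expect_error(classification_metrics(c(5, 6), c(1, 2)), "both classes")
})

test_that("AUC is invariant to strictly monotone transforms and handles ties", {
  set.seed(3)
  for (trial in 1:20) {
    y <- sample(c(2, 6), 30, replace = TRUE)
    s <- round(rnorm(30), 1) # ties likely
    a1 <- classification_metrics(y, s)$auc
    a2 <- classification_metrics(y, exp(2 * s) + 5)$auc
    expect_equal(a1, a2, tolerance = 1e-12)
    expect_equal(a1, oracle_auc(y >= 4, s), tolerance = 1e-12)
  }
})

test_that("the Tanimoto coefficient is plain set arithmetic", {
  expect_equal(tanimoto(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(tanimoto(c(5, 9), c(5, 9)), 1)
  expect_equal(tanimoto(c(1, 2), c(3, 4)), 0)
  expect_equal(tanimoto(integer(0), integer(0)), 0)
  fp <- mol_fingerprint("c1ccccc1O")
  expect_equal(tanimoto(fp, fp), 1)
  expect_true(tanimoto(fp, mol_fingerprint("CCNCC")) < 0.5)
})

test_that("stratified folds partition the data with balanced sizes and means", {
  gen <- small_synthetic(seed = 31L, n_pairs = 100L)
  plan <- make_splits(gen$dataset, "stratified_kfold", k = 5L, seed = 9L)
  expect_setequal(plan$pair_index, 1:100)
  sizes <- table(plan$fold)
  expect_true(all(sizes >= 19 & sizes <= 21))
  y <- gen$dataset$pairs$affinity
  for (f in 1:5) {
    expect_lt(abs(mean(y[plan$fold == f]) - mean(y)), 0.3)
  }
})

test_that("blind splits keep entities disjoint across folds", {
  gen <- small_synthetic(seed = 33L, n_pairs = 60L)
  ds <- gen$dataset
  for (mode in c("blind_rna", "blind_mol")) {
    col <- if (mode == "blind_rna") "rna_id" else "mol_id"
    plan <- make_splits(ds, mode, k = 3L, seed = 2L)
    expect_true(all(!is.na(plan$fold)))
    sets <- lapply(1:3, function(f) unique(ds$pairs[[col]][plan$fold == f]))
    for (i in 1:2) for (j in (i + 1):3) {
      expect_length(intersect(sets[[i]], sets[[j]]), 0L)
    }
  }
  plan <- make_splits(ds, "all_blind", k = 3L, seed = 2L)
  for (col in c("rna_id", "mol_id")) {
    sets <- lapply(1:3, function(f) {
      unique(ds$pairs[[col]][!is.na(plan$fold) & plan$fold == f])
    })
    for (i in 1:2) for (j in (i + 1):3) {
      expect_length(intersect(sets[[i]], sets[[j]]), 0L)
    }
  }
  expect_error(make_splits(ds, "blind_rna", k = 50L), "at least k")
})

test_that("sequence identity and the leakage filter behave on fixtures", {
  expect_equal(rna_identity("ACGUACGU", "ACGUACGU"), 1)
  expect_lt(rna_identity("AAAAAAAA", "GGGGGGGG"), 0.01)

  # near-duplicate RNA at identity 0.95 is removed at threshold 0.8
  set.seed(41)
  base <- paste(sample(c("A", "C", "G", "U"), 100, replace = TRUE),
                collapse = "")
  mut <- strsplit(base, "")[[1]]
  flip <- sample(100, 5)
  mut[flip] <- vapply(mut[flip], function(ch) {
    setdiff(c("A", "C", "G", "U"), ch)[1]
  }, character(1))
  near <- paste(mut, collapse = "")
  expect_gte(rna_identity(base, near), 0.95)

  train <- suppressMessages(rsma_dataset(
    tibble::tibble(id = c("T1", "T2"),
                   sequence = c(near, "AUAUAUAUAUAUAUAUAUAU")),
    tibble::tibble(id = c("TM1", "TM2"), smiles = c("CCO", "c1ccccc1")),
    tibble::tibble(rna_id = c("T1", "T2"), mol_id = c("TM1", "TM2"),
                   affinity = c(5, 6))
  ))
  test <- suppressMessages(rsma_dataset(
    tibble::tibble(id = "X1", sequence = base),
    tibble::tibble(id = "XM1", smiles = "CCNC(=O)C1CCCCC1"),
    tibble::tibble(rna_id = "X1", mol_id = "XM1", affinity = 4)
  ))
  res <- independent_filter(train, test, mol_sim_threshold = 0.8,
                            rna_id_threshold = 0.8)
  expect_equal(res$removed$id, "T1")
  expect_equal(res$train$pairs$rna_id, "T2")

  # identical molecule in train and test is removed at any threshold <= 1
  train2 <- suppressMessages(rsma_dataset(
    train$rnas[2, c("id", "sequence")],
    tibble::tibble(id = "TM1", smiles = "CCNC(=O)C1CCCCC1"),
    tibble::tibble(rna_id = "T2", mol_id = "TM1", affinity = 5)
  ))
  res2 <- independent_filter(train2, test, mol_sim_threshold = 1,
                             rna_id_threshold = 1)
  expect_true("TM1" %in% res2$removed$id)
  expect_equal(nrow(res2$train$pairs), 0L)

  # dissimilar sets: nothing removed
  res3 <- independent_filter(train, test, mol_sim_threshold = 1,
                             rna_id_threshold = 1)
  expect_true(!"T2" %in% res3$removed$id)
})

test_that("cross-validation reports per-fold and aggregate metrics", {
  gen <- small_synthetic(seed = 51L, n_pairs = 40L, len = c(12L, 24L))
  cfg <- tiny_config(epochs = 2L)
  plan <- make_splits(gen$dataset, "stratified_kfold", k = 2L, seed = 1L)
  rep1 <- suppressMessages(run_cv(gen$dataset, cfg, plan,
                                  provider = gen$provider, val_fraction = 0))
  expect_equal(nrow(rep1$folds), 2L)
  expect_equal(rep1$aggregate$mean[rep1$aggregate$metric == "pcc"],
               mean(rep1$folds$pcc), tolerance = 1e-12)
  # identical seed list gives an identical aggregate report
  rep2 <- suppressMessages(run_cv(gen$dataset, cfg, plan,
                                  provider = gen$provider, val_fraction = 0))
  expect_identical(rep1$aggregate, rep2$aggregate)
})
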