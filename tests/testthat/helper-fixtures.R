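# Shared fixtures, built in code at test time.

# Tiny on-disk dataset: 2 RNAs, 3 molecules, 3 pairs.
write_toy_dataset_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  writeLines(c("rna_id,mol_id,affinity",
               "R1,M1,5.2", "R1,M2,3.1", "R2,M3,7.0"),
             file.path(dir, "pairs.csv"))
  writeLines(c(">R1", "ACGUACGUAC", ">R2", "GGCCAAUUGGCC"),
             file.path(dir, "rnas.fasta"))
  writeLines(c("CCO M1", "c1ccccc1 M2", "CC(=O)O M3"),
             file.path(dir, "mols.smi"))
  dir
}

toy_dataset <- function() {
  suppressMessages(rsma_dataset(
    rnas = tibble::tibble(id = c("R1", "R2"),
                          sequence = c("ACGUACGUAC", "GGCCAAUUGGCC")),
    molecules = tibble::tibble(id = c("M1", "M2", "M3"),
                               smiles = c("CCO", "c1ccccc1", "CC(=O)O")),
    pairs = tibble::tibble(rna_id = c("R1", "R1", "R2"),
                           mol_id = c("M1", "M2", "M3"),
                           affinity = c(5.2, 3.1, 7.0))
  ))
}

# Small synthetic dataset for fast end-to-end tests.
small_synthetic <- function(seed = 3L, n_pairs = 24L, len = c(12L, 30L)) {
  generate_dataset(synthetic_spec(
    n_rnas = 12L, n_mols = 12L, n_pairs = n_pairs, rna_len_range = len,
    seed = seed))
}

# Tiny model configuration used across model-level tests; any rsma_config
# argument can be overridden.
tiny_config <- function(...) {
  args <- list(d = 8L, d_pre = 4L, kernel_sizes = c(3L, 5L), gat_layers = 1L,
               gat_heads = 2L, gcn_layers = 1L, tr_blocks = 1L, tr_heads = 2L,
               cf_blocks = 1L, cf_heads = 2L, d_ff = 8L, dropout = 0,
               epochs = 2L, batch_size = 4L, seed = 11L)
  args <- utils::modifyList(args, list(...))
  do.call(rsma_config, args)
}

rand_mat <- function(n, m, scale = 0.3) matrix(stats::rnorm(n * m, 0, scale), n, m)

# Plain-loop softmax for oracles.
oracle_softmax_rows <- function(z) {
  out <- matrix(0, nrow(z), ncol(z))
  for (i in seq_len(nrow(z))) {
    e <- exp(z[i, ] - max(z[i, ]))
    out[i, ] <- e / sum(e)
  }
  out
}

# Plain-loop layer normalization matching the model's convention.
oracle_layernorm <- function(x, eps = 1e-5) {
  out <- x
  for (i in seq_len(nrow(x))) {
    mu <- mean(x[i, ])
    v <- mean((x[i, ] - mu)^2)
    out[i, ] <- (x[i, ] - mu) / sqrt(v + eps)
  }
  out
}
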