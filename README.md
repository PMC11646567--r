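# rnaligand

Dual-view cross-attention networks for RNA–small molecule binding affinity.

RNAs with druggable pockets are an emerging class of small-molecule targets;
prioritizing ligands for them needs a model that predicts the binding
affinity pKd = −log10 Kd of an (RNA, molecule) pair from sequence- and
structure-derived inputs alone. `rnaligand` implements a fine-grained neural
architecture for this regression task plus the full evaluation harness such
work requires, all runnable offline.

## The model

Each entity is encoded at its natural resolution from two views:

* **RNA, graph view** — multi-head graph attention (GAT) over a p×p contact
  map (8 Å nearest-heavy-atom convention; real maps come from an external
  structure predictor through a file interface, tests use synthetic
  backbone+long-range maps). Per head,
  α<sub>in</sub> = softmax<sub>n∈N(i)∪{i}</sub> LeakyReLU(aᵀ[W_d r_i, W_d r_n]),
  r_i ← ReLU(Σ α<sub>in</sub> W_a r_n).
* **RNA, sequence view** — nucleotide embeddings averaged position-wise with
  a projected pretrained per-nucleotide embedding (provider interface; a
  deterministic mock provider ships for offline use), then three same-length
  1D convolutions (kernels 7/11/15), branch-averaged, with a two-layer ReLU
  projection.
* **Molecule, graph view** — GCN over the self-connected heavy-atom graph:
  M ← ReLU(D̃^{−1/2} Ã D̃^{−1/2} M W), atom features from
  ChemmineR/OpenBabel perception (element, degree, charge, radicals,
  hybridisation, aromaticity, H count; width 29).
* **Molecule, sequence view** — Transformer over atomic-level SMILES tokens
  (scaled dot-product attention, residual + layer norm, FFN); an atom mask
  selects the q atom rows so pooling averages atoms only.

A **cross-fusion Transformer** stacks each entity's two views with learned
segment embeddings (R_c ∈ R^{2p×d}, M_c ∈ R^{2q×d}) and runs two parallel
cross-attention perspectives per block — RNA queries against molecule
keys/values (scores 2p×2q) and the reverse — whose post-softmax score
matrices double as the interpretability signal. The head is
ŷ = MLP([MLP([mean(R̄g, R̄cg), mean(R̄s, R̄cs)]), MLP([mean(M̄g, M̄cg),
mean(M̄s, M̄cs)])]). Training minimizes MSE with Adam (defaults: d = 128,
lr 5e-4, batch 16, dropout 0.2, weight decay 1e-7). All layers run on an
in-package reverse-mode autodiff engine (no external deep-learning
framework); gradients are finite-difference-verified in the tests.

The harness covers stratified k-fold CV over the continuous target, blind
(cold) splits by RNA/molecule/both, independent-test leakage filtering
(Tanimoto fingerprints + global-alignment identity), regression metrics
(PCC/SCC/RMSE) and threshold-4.0 classification metrics
(specificity/BACC/AUC), attention-based per-nucleotide and per-atom
rankings, and a seeded synthetic-data generator with a planted signal.

## Worked example

```r
library(rnaligand)

gen <- generate_dataset(synthetic_spec(n_rnas = 15, n_mols = 15,
                                       n_pairs = 120,
                                       rna_len_range = c(20, 80), seed = 42))
ds <- gen$dataset
ds
#> <rsma_dataset> 120 pairs | 15 RNAs | 15 molecules
#>   pKd range: [2.7, 8.99]

set.seed(1)
test_i <- sample.int(120, 24)
train <- ds; train$pairs <- ds$pairs[-test_i, ]

cfg <- rsma_config(d = 32, gat_layers = 1, gat_heads = 2, tr_blocks = 1,
                   tr_heads = 2, cf_blocks = 1, cf_heads = 2,
                   lr = 2e-3, epochs = 6, patience = 6, seed = 7)
fit <- rsma_train(train, cfg, provider = gen$provider, val_fraction = 0.1)
fit
#> <rsma_model> d=32 | views: graph+sequence | cross-fusion
#>   trained 6 epoch(s); best epoch 5 (val MSE 0.1514)

preds <- predict_batch(fit, ds, ds$pairs[test_i, ])
regression_metrics(preds$affinity_true, preds$affinity_pred)
#> # A tibble: 1 × 4
#>     pcc   scc  rmse     n
#> 1 0.906 0.894 0.757    24
classification_metrics(preds$affinity_true, preds$affinity_pred)  # threshold 4.0
#> # A tibble: 1 × 4
#>   specificity  bacc   auc     n
#> 1           1     1     1    24
```

A held-out Pearson correlation of 0.91 and RMSE of 0.76 pKd units on 24
unseen pairs says the model recovered most of the planted
GC-content/aromaticity signal (label noise alone bounds RMSE at 0.3).
Attention maps from any prediction convert to binding-site rankings:

```r
r <- ds$rnas[1, ]; m <- ds$molecules[6, ]
rf <- featurize_rna(r$id, r$sequence, provider = gen$provider, contact_seed = 7)
mf <- featurize_mol(m$id, m$smiles)
out <- predict_affinity(fit, rf, mf)
round(out$yhat, 3)
#> [1] 7.694
extract_attention_ranking(out$attention, p = rf$p, q = mf$q,
                          rna_id = r$id, mol_id = m$id)
#> <rsma_attention_ranking> p=68 q=13
#>   top5 nucleotides: 1 2 3 4 5 | atoms: 1 2 3 4 5
#>   top10 nucleotides: 1 2 3 4 5 6 7 8 9 10 | atoms: 1 2 3 4 5 6 7 8 9 10
```

Real data enter through `load_dataset(pairs.csv, rnas.fasta, mols.smi)` with
per-RNA contact-map and embedding matrix files via
`file_embedding_provider()`; splits come from `make_splits()` (stratified,
`blind_rna`, `blind_mol`, `all_blind`), full experiments from `run_cv()`, and
leakage control from `independent_filter()`.

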