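# Model-ready features: nucleotide index vectors, contact maps, pretrained
# nucleotide embeddings (through provider interfaces), chemical graphs with
# self-connected adjacency, and atomic-level SMILES tokens.

RNA_VOCAB <- c(A = 0L, C = 1L, G = 2L, U = 3L)

#' Encode an RNA sequence as nucleotide indices
#'
#' Fixed vocabulary A=0, C=1, G=2, U=3.
#'
#' @param sequence RNA sequence string (already normalized to A/C/G/U).
#' @return Integer vector of length `nchar(sequence)` with values 0..3.
#' @examples
#' encode_rna_tokens("ACGU")
#' @export
encode_rna_tokens <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  idx <- RNA_VOCAB[chars]
  if (anyNA(idx)) {
    stop("unknown nucleotide character(s): ",
         paste(unique(chars[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  unname(idx)
}

#' Load a contact map from file, or synthesize one
#'
#' A contact map is a binary symmetric p x p matrix marking nucleotide pairs
#' whose nearest heavy atoms lie within a distance cutoff (8 angstrom in the
#' structure-predictor convention this model consumes). Real maps come from
#' an external secondary/tertiary structure predictor and are read from a
#' whitespace-delimited 0/1 matrix file; synthetic maps contain the backbone
#' chain (|i-j| = 1 always in contact) plus symmetric random long-range
#' contacts at a configurable density.
#'
#' @param p RNA length (nucleotide count).
#' @param source A file path, or `"synthetic"`.
#' @param seed Integer seed for the synthetic generator.
#' @param density Expected fraction of long-range (non-backbone) pairs in
#'   contact when `source = "synthetic"`.
#' @return A p x p binary symmetric matrix with zero diagonal.
#' @examples
#' m <- load_or_make_contact_map(5, "synthetic", seed = 1)
#' all(m == t(m))
#' @export
load_or_make_contact_map <- function(p, source = "synthetic", seed = 1L,
                                     density = 0.05) {
  stopifnot(p >= 1L)
  if (identical(source, "synthetic")) {
    m <- matrix(0, p, p)
    if (p > 1L) {
      idx <- cbind(seq_len(p - 1L), seq_len(p - 1L) + 1L)
      m[idx] <- 1
      m[idx[, 2:1, drop = FALSE]] <- 1
      if (p > 2L && density > 0) {
        u <- with_preserved_rng(seed, {
          matrix(stats::runif(p * p), p, p)
        })
        long <- (u < density) & upper.tri(m, diag = FALSE) &
          (abs(row(m) - col(m)) > 1L)
        m[long] <- 1
        m[t(long)] <- 1
      }
    }
    return(m)
  }
  if (!file.exists(source)) stop("contact map file not found: ", source, call. = FALSE)
  m <- as.matrix(utils::read.table(source, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != p || ncol(m) != p) {
    stop("contact map shape ", nrow(m), "x", ncol(m),
         " does not match RNA length ", p, call. = FALSE)
  }
  if (!all(m %in% c(0, 1))) stop("contact map entries must be 0/1", call. = FALSE)
  if (!isTRUE(all.equal(m, t(m)))) stop("contact map is not symmetric", call. = FALSE)
  m
}

# Run expr under a fixed seed without disturbing the caller's RNG stream.
with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## ---- pretrained-embedding providers ---------------------------------------

#' Deterministic mock pretrained-embedding provider
#'
#' Stands in for an external pretrained nucleotide language model. Emits a
#' p x d_pre matrix computed by a seeded arithmetic hash of (sequence,
#' position, dimension); the same sequence always yields the same matrix,
#' bit-for-bit, in any session. Synthetic by construction -- it carries no
#' learned biology and exists so the pipeline runs and tests offline.
#'
#' @param d_pre Embedding width.
#' @param seed Integer mixed into the hash.
#' @return An embedding provider: list with `name`, `d_pre`, and
#'   `fn(id, sequence)` returning a p x d_pre matrix.
#' @export
mock_embedding_provider <- function(d_pre = 16L, seed = 1L) {
  force(d_pre); force(seed)
  fn <- function(id, sequence) {
    chars <- utf8ToInt(sequence)
    p <- length(chars)
    # polynomial sequence hash, then a sine lattice over (position, dim)
    h <- 0
    for (ch in chars) h <- (h * 31 + ch) %% 1e9
    pos <- matrix(seq_len(p), p, d_pre)
    dim_ <- matrix(seq_len(d_pre), p, d_pre, byrow = TRUE)
    x <- sin(h * 1e-4 + seed * 0.7071 + pos * 12.9898 + dim_ * 78.233) * 43758.5453
    2 * (x - floor(x)) - 1
  }
  structure(list(name = "mock", d_pre = as.integer(d_pre), seed = seed, fn = fn),
            class = "rsma_embedding_provider")
}

#' File-backed pretrained-embedding provider
#'
#' Loads one whitespace-delimited matrix file per RNA id (`<id>.txt` under
#' `dir`), as produced by an external pretrained model run offline.
#'
#' @param dir Directory of per-RNA matrix files.
#' @param d_pre Embedding width the files are expected to have.
#' @return An embedding provider (see [mock_embedding_provider()]).
#' @export
file_embedding_provider <- function(dir, d_pre) {
  force(dir); force(d_pre)
  fn <- function(id, sequence) {
    path <- file.path(dir, paste0(id, ".txt"))
    if (!file.exists(path)) stop("no embedding file for rna_id '", id, "'",
                                 call. = FALSE)
    m <- as.matrix(utils::read.table(path, header = FALSE))
    dimnames(m) <- NULL
    m
  }
  structure(list(name = "file", d_pre = as.integer(d_pre), dir = dir, fn = fn),
            class = "rsma_embedding_provider")
}

#' Fetch the pretrained embedding for one RNA
#'
#' @param id RNA id.
#' @param sequence RNA sequence (length p).
#' @param provider An embedding provider.
#' @return A p x d_pre matrix; errors if the provider's row count is not p.
#' @export
get_pretrained_embedding <- function(id, sequence, provider) {
  stopifnot(inherits(provider, "rsma_embedding_provider"))
  m <- provider$fn(id, sequence)
  p <- nchar(sequence)
  if (nrow(m) != p) {
    stop("provider returned ", nrow(m), " rows for RNA of length ", p,
         call. = FALSE)
  }
  if (ncol(m) != provider$d_pre) {
    stop("provider returned width ", ncol(m), ", declared d_pre ",
         provider$d_pre, call. = FALSE)
  }
  m
}

## ---- molecule features ----------------------------------------------------

ATOM_ELEMENTS <- c("C", "N", "O", "S", "F", "P", "Cl", "Br", "I", "B")
ATOM_HYBRIDS <- c("sp", "sp2", "sp3")

.one_hot <- function(value, levels) {
  v <- numeric(length(levels) + 1L)
  i <- match(value, levels)
  if (is.na(i)) v[length(v)] <- 1 else v[i] <- 1
  v
}

# Atom feature layout (width 29):
#   element one-hot over ATOM_ELEMENTS + other ... 11
#   heavy-atom degree one-hot 0..5             ...  6
#   formal charge                              ...  1
#   radical electrons                          ...  1
#   hybridization one-hot sp/sp2/sp3 + other   ...  4
#   aromaticity flag                           ...  1
#   total hydrogen count one-hot 0..4          ...  5
ATOM_FEATURE_WIDTH <- 29L

.atom_features <- function(parsed) {
  q <- parsed$q
  X <- matrix(0, q, ATOM_FEATURE_WIDTH)
  for (i in seq_len(q)) {
    deg <- numeric(6L); deg[min(parsed$degree[i], 5L) + 1L] <- 1
    hyd <- numeric(5L); hyd[min(parsed$n_h[i], 4L) + 1L] <- 1
    X[i, ] <- c(
      .one_hot(parsed$elements[i], ATOM_ELEMENTS),
      deg,
      parsed$charge[i],
      parsed$radical[i],
      .one_hot(parsed$hybridization[i], ATOM_HYBRIDS),
      as.numeric(parsed$aromatic[i]),
      hyd
    )
  }
  X
}

#' Build the chemical graph of a molecule
#'
#' Heavy-atom graph (hydrogens implicit) with self-connected adjacency, its
#' degree matrix, and the per-atom feature matrix. See the comment above
#' `ATOM_FEATURE_WIDTH` in the source for the exact feature layout.
#'
#' @param smiles A single SMILES string.
#' @return A list of class `rsma_mol_graph`: `q`, `A_tilde` (q x q adjacency
#'   with self-loops), `D_tilde` (diagonal degree matrix of `A_tilde`),
#'   `features` (q x 29), and `smiles`.
#' @examples
#' g <- build_mol_graph("CCO")
#' diag(g$D_tilde)
#' @export
build_mol_graph <- function(smiles) {
  parsed <- parse_smiles(smiles)
  q <- parsed$q
  A <- diag(1, q)
  if (nrow(parsed$bonds) > 0L) {
    A[parsed$bonds[, c("i", "j"), drop = FALSE]] <- 1
    A[parsed$bonds[, c("j", "i"), drop = FALSE]] <- 1
  }
  deg <- rowSums(A)
  dinv <- 1 / sqrt(deg)
  structure(list(q = q, A_tilde = A, D_tilde = diag(deg, q),
                 S = A * outer(dinv, dinv), # D~^{-1/2} A~ D~^{-1/2}, cached
                 features = .atom_features(parsed), smiles = smiles),
            class = "rsma_mol_graph")
}

# Atomic-level SMILES token pattern: bracket atoms, two-letter elements,
# single-letter atoms (aromatic lowercase included), ring-bond digits,
# bonds, branches, and stereo marks.
.SMILES_TOKEN_RE <- paste0(
  "(\\[[^\\]]+\\]|Br|Cl|Si|Se|se|@@|",
  "[BCNOPSFI]|[bcnops]|",
  "%\\d{2}|\\d|[-=#$:/\\\\\\.\\(\\)\\+@~\\*])"
)

.token_is_atom <- function(tok) {
  if (grepl("^\\[", tok)) {
    # bracket atom; exclude explicit hydrogens like [H] / [2H]
    el <- sub("^\\[\\d*([A-Za-z][a-z]?).*$", "\\1", tok)
    return(!toupper(el) %in% c("H"))
  }
  tok %in% c("Br", "Cl", "Si", "Se", "se", "B", "C", "N", "O", "P", "S", "F",
             "I", "b", "c", "n", "o", "p", "s")
}

#' Tokenize a SMILES string at atomic level
#'
#' Regex tokenizer that keeps bracket atoms (`[...]`) and two-letter
#' elements (Cl, Br, ...) as single tokens; bonds, ring digits, and branch
#' symbols become non-atom tokens. The atom mask marks tokens that are heavy
#' atoms; its count is checked against the parsed heavy-atom count, so the
#' token stream and the chemical graph always agree on q.
#'
#' @param smiles A single SMILES string.
#' @return A list of class `rsma_tokenized_smiles`: `tokens` (character),
#'   `atom_mask` (logical, same length), `q` (number of atom tokens), and
#'   `smiles`.
#' @examples
#' tokenize_smiles("c1ccccc1")$q
#' @export
tokenize_smiles <- function(smiles) {
  parsed <- parse_smiles(smiles) # validates, gives heavy-atom count
  m <- gregexpr(.SMILES_TOKEN_RE, smiles, perl = TRUE)[[1L]]
  tokens <- regmatches(smiles, list(m))[[1L]]
  if (sum(nchar(tokens)) != nchar(smiles)) {
    stop("SMILES contains untokenizable characters: '", smiles, "'",
         call. = FALSE)
  }
  atom_mask <- vapply(tokens, .token_is_atom, logical(1L), USE.NAMES = FALSE)
  q <- sum(atom_mask)
  if (q != parsed$q) {
    stop("tokenizer atom count (", q, ") disagrees with parsed heavy-atom ",
         "count (", parsed$q, ") for '", smiles, "'", call. = FALSE)
  }
  structure(list(tokens = tokens, atom_mask = atom_mask, q = q, smiles = smiles),
            class = "rsma_tokenized_smiles")
}

# Fixed Transformer vocabulary. Bracket atoms are mapped to their bare
# element symbol (charge and explicit-H detail inside brackets is dropped
# from the id, kept in the token string), so the vocabulary stays finite.
SMILES_VOCAB <- c(
  "<unk>", "B", "C", "N", "O", "P", "S", "F", "I", "Br", "Cl", "Si", "Se",
  "b", "c", "n", "o", "p", "s", "se",
  "-", "=", "#", "$", ":", "/", "\\", ".", "(", ")", "+", "@", "@@", "~", "*",
  as.character(0:9), paste0("%", 10:19)
)

smiles_token_ids <- function(tokens) {
  key <- vapply(tokens, function(tok) {
    if (grepl("^\\[", tok)) sub("^\\[\\d*([A-Za-z][a-z]?).*$", "\\1", tok) else tok
  }, character(1L), USE.NAMES = FALSE)
  idx <- match(key, SMILES_VOCAB)
  idx[is.na(idx)] <- 1L # <unk>
  idx
}

## ---- per-entity feature bundles -------------------------------------------

#' Assemble the full feature bundle for one RNA
#'
#' @param id,sequence RNA id and normalized sequence.
#' @param contact_source `"synthetic"` or a directory of `<id>.txt` contact
#'   map files.
#' @param provider An embedding provider.
#' @param contact_density Long-range contact density for synthetic maps.
#' @param contact_seed Base seed for synthetic maps (offset per RNA by a
#'   hash of its id so maps differ across RNAs but are reproducible).
#' @param max_len Maximum accepted RNA length.
#' @return List of class `rsma_rna_features`: `id`, `p`, `indices`,
#'   `contact`, `pretrained`.
#' @export
featurize_rna <- function(id, sequence, contact_source = "synthetic",
                          provider = mock_embedding_provider(),
                          contact_density = 0.05, contact_seed = 1L,
                          max_len = 512L) {
  p <- nchar(sequence)
  if (p > max_len) {
    stop("RNA '", id, "' has length ", p, " > maximum ", max_len,
         "; raise max_rna_len if intended", call. = FALSE)
  }
  src <- contact_source
  if (!identical(src, "synthetic")) src <- file.path(src, paste0(id, ".txt"))
  seed <- (contact_seed + .id_hash(id)) %% .Machine$integer.max
  contact <- load_or_make_contact_map(p, src, seed = seed, density = contact_density)
  structure(list(
    id = id, p = p,
    indices = encode_rna_tokens(sequence),
    contact = contact,
    gat_support = (contact + diag(1, p)) > 0, # neighbourhood + self, cached
    pretrained = get_pretrained_embedding(id, sequence, provider)
  ), class = "rsma_rna_features")
}

.id_hash <- function(id) {
  h <- 0
  for (ch in utf8ToInt(id)) h <- (h * 31 + ch) %% 1e7
  as.integer(h)
}

#' Assemble the full feature bundle for one molecule
#'
#' @param id,smiles Molecule id and SMILES.
#' @return List of class `rsma_mol_features`: `id`, `q`, `graph`
#'   ([build_mol_graph()]) and `tokens` ([tokenize_smiles()]).
#' @export
featurize_mol <- function(id, smiles) {
  graph <- build_mol_graph(smiles)
  tok <- tokenize_smiles(smiles)
  structure(list(id = id, q = graph$q, graph = graph, tokens = tok,
                 token_ids = smiles_token_ids(tok$tokens)),
            class = "rsma_mol_features")
}
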