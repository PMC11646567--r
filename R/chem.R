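# SMILES parsing through ChemmineR/OpenBabel, plus the small amount of
# perception (implicit hydrogens, hybridisation) the SDF V2000 blocks do not
# carry directly. Parsed molecules are memoised per SMILES string for the
# session, since datasets repeat molecules across pairs.

.chem_cache <- new.env(parent = emptyenv())

# Default valences used for implicit-hydrogen counting. Hypervalent S/P are
# handled by clamping at zero.
.default_valence <- c(B = 3, C = 4, N = 3, O = 2, F = 1, P = 3, S = 2,
                      Cl = 1, Br = 1, I = 1, Si = 4, Se = 2)

# V2000 legacy charge codes: 1..7 map to +3,+2,+1,radical,-1,-2,-3.
.charge_from_code <- function(code) {
  map <- c(`1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1, `6` = -2, `7` = -3)
  out <- rep(0L, length(code))
  hit <- as.character(code) %in% names(map)
  out[hit] <- map[as.character(code[hit])]
  out
}

.radical_from_code <- function(code) as.integer(code == 4)

#' Parse a SMILES string into an annotated chemical graph
#'
#' Heavy-atom graph with per-atom annotations used by [build_mol_graph()]:
#' element, degree, formal charge, radical-electron count, implicit hydrogen
#' count, aromaticity, and a bond-order-derived hybridisation label.
#'
#' @param smiles A single SMILES string.
#' @return A list with elements `q` (heavy-atom count), `elements`,
#'   `bonds` (matrix with columns `i`, `j`, `order`), `charge`, `radical`,
#'   `degree`, `n_h`, `aromatic`, `hybridization`, and `smiles`.
#' @examples
#' m <- parse_smiles("CCO")
#' m$q
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  key <- smiles
  hit <- get0(key, envir = .chem_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)

  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "m"))),
    error = function(e) NULL
  )
  # validSDF() additionally requires a non-empty bond block, which rejects
  # legitimate single-heavy-atom molecules ("C", "N", "O"); require a
  # readable atom block instead.
  if (is.null(sdf) || length(sdf) != 1L) {
    stop("invalid SMILES: '", smiles, "'", call. = FALSE)
  }
  one <- sdf[[1]]
  ab <- tryCatch(ChemmineR::atomblock(one), error = function(e) NULL)
  bb <- tryCatch(ChemmineR::bondblock(one), error = function(e) NULL)
  if (is.null(ab) || nrow(ab) < 1L) {
    stop("invalid SMILES: '", smiles, "'", call. = FALSE)
  }
  q <- nrow(ab)
  if (q < 1L) stop("invalid SMILES (no heavy atoms): '", smiles, "'", call. = FALSE)
  elements <- sub("_.*$", "", rownames(ab))
  code <- if ("C5" %in% colnames(ab)) as.integer(ab[, "C5"]) else rep(0L, q)
  charge <- .charge_from_code(code)
  radical <- .radical_from_code(code)

  if (is.null(bb) || !is.matrix(bb) || nrow(bb) == 0L || ncol(bb) < 3L ||
      all(bb[, 1L] == 0L)) {
    bonds <- matrix(integer(0), 0L, 3L, dimnames = list(NULL, c("i", "j", "order")))
  } else {
    bonds <- cbind(i = as.integer(bb[, 1L]), j = as.integer(bb[, 2L]),
                   order = as.integer(bb[, 3L]))
  }

  degree <- rep(0L, q)
  bondsum <- rep(0L, q)
  maxorder <- rep(0L, q)
  ndouble <- rep(0L, q)
  if (nrow(bonds) > 0L) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, "i"]; j <- bonds[r, "j"]; o <- bonds[r, "order"]
      degree[i] <- degree[i] + 1L; degree[j] <- degree[j] + 1L
      bondsum[i] <- bondsum[i] + o; bondsum[j] <- bondsum[j] + o
      maxorder[i] <- max(maxorder[i], o); maxorder[j] <- max(maxorder[j], o)
      if (o == 2L) { ndouble[i] <- ndouble[i] + 1L; ndouble[j] <- ndouble[j] + 1L }
    }
  }

  val <- .default_valence[elements]
  val[is.na(val)] <- bondsum[is.na(val)] # unknown elements: no implicit H
  n_h <- pmax(0L, as.integer(val) - bondsum + charge)

  aromatic <- rep(FALSE, q)
  rr <- tryCatch(
    suppressWarnings(ChemmineR::rings(one, type = "all", arom = TRUE)),
    error = function(e) NULL
  )
  if (!is.null(rr) && length(rr$RINGS) > 0L) {
    for (k in seq_along(rr$RINGS)) {
      if (isTRUE(rr$AROMATIC[[k]])) {
        idx <- as.integer(sub("^.*_", "", rr$RINGS[[k]]))
        aromatic[idx] <- TRUE
      }
    }
  }

  hybridization <- ifelse(
    maxorder >= 3L | ndouble >= 2L, "sp",
    ifelse(maxorder == 2L | aromatic, "sp2", "sp3")
  )

  out <- list(q = q, elements = elements, bonds = bonds, charge = charge,
              radical = radical, degree = degree, n_h = n_h,
              aromatic = aromatic, hybridization = hybridization,
              smiles = smiles)
  assign(key, out, envir = .chem_cache)
  out
}

#' Check whether a SMILES string parses as a valid molecule
#'
#' @param smiles A single SMILES string.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_smiles <- function(smiles) {
  !inherits(tryCatch(parse_smiles(smiles), error = function(e) e), "error")
}

# 1024-bit structural fingerprints (atom-pair descriptors folded to a binary
# fingerprint), returned as the sorted integer set of on-bits.
.fp_cache <- new.env(parent = emptyenv())

#' Binary structural fingerprint of a molecule
#'
#' Atom-pair descriptors folded into a 1024-bit binary fingerprint; the
#' fingerprint is returned as the set of on-bit positions, the form
#' [tanimoto()] consumes.
#'
#' @param smiles A single SMILES string.
#' @return Sorted integer vector of on-bit positions (1-based).
#' @export
mol_fingerprint <- function(smiles) {
  key <- smiles
  hit <- get0(key, envir = .fp_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  parse_smiles(smiles) # validates
  if (is.null(.fp_cache$.descnames)) {
    # the 1024 most frequent atom-pair descriptors shipped with ChemmineR
    e <- new.env(parent = emptyenv())
    utils::data("apfp", package = "ChemmineR", envir = e)
    .fp_cache$.descnames <- e$apfp$AP[seq_len(1024L)]
  }
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "m")))
  ap <- suppressWarnings(ChemmineR::sdf2ap(sdf))
  fp <- suppressWarnings(ChemmineR::desc2fp(ap, descnames = .fp_cache$.descnames,
                                            type = "FPset"))
  bits <- sort(which(fp@fpma[1L, ] == 1))
  assign(key, bits, envir = .fp_cache)
  bits
}
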