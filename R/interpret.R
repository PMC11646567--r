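# Attention interpretability: collapse cross-fusion score matrices into
# per-nucleotide and per-atom importance scores and top-k rankings.
#
# A nucleotide's score is the flat mean, over cross blocks, heads, and key
# positions, of the RNA-perspective attention rows belonging to that
# nucleotide in every view segment (row j for the graph view and row p + j
# for the sequence view, when both views are present). Atom scores are the
# molecule-perspective analogue. This is one consistent reading of
# "average the scores from the different perspectives"; the collapse order
# (flat mean over blocks/heads/views/keys) is fixed here and documented.
# Positions are reported 1-based.

#' Rank nucleotides and atoms by cross-attention weight
#'
#' @param maps Attention maps from [predict_affinity()] or
#'   [cross_fusion_encode()]: list with `rna` and `mol`, each a list (per
#'   block) of lists (per head) of score matrices.
#' @param p RNA length.
#' @param q Heavy-atom count.
#' @param k_list Top-k cutoffs to report (default 5 and 10).
#' @param rna_id,mol_id Optional ids carried through to the output.
#' @return Object of class `rsma_attention_ranking`: `nucleotide_scores`
#'   (length p), `atom_scores` (length q), and `top` (per cutoff, 1-based
#'   index vectors for nucleotides and atoms; ties broken by ascending
#'   position).
#' @export
extract_attention_ranking <- function(maps, p, q, k_list = c(5L, 10L),
                                      rna_id = NULL, mol_id = NULL) {
  stopifnot(length(maps$rna) >= 1L, length(maps$mol) >= 1L)

  collapse <- function(persp, n_entity) {
    mats <- unlist(persp, recursive = FALSE) # blocks x heads -> flat list
    nr <- nrow(mats[[1L]])
    if (nr %% n_entity != 0L) {
      stop("attention map rows (", nr, ") not a multiple of entity length (",
           n_entity, ")", call. = FALSE)
    }
    n_views <- nr %/% n_entity
    for (m in mats) {
      if (nrow(m) != nr) stop("inconsistent attention map shapes", call. = FALSE)
    }
    avg <- Reduce(`+`, mats) / length(mats)
    row_scores <- rowMeans(avg)
    # average the view segments: rows j, n_entity + j, ...
    colMeans(matrix(row_scores, nrow = n_views, byrow = TRUE))
  }

  nuc <- collapse(maps$rna, p)
  atm <- collapse(maps$mol, q)

  top_k <- function(scores, k) {
    k <- min(k, length(scores))
    order(-scores, seq_along(scores))[seq_len(k)]
  }
  top <- lapply(k_list, function(k) {
    list(nucleotides = top_k(nuc, k), atoms = top_k(atm, k))
  })
  names(top) <- paste0("top", k_list)

  structure(list(rna_id = rna_id, mol_id = mol_id,
                 nucleotide_scores = nuc, atom_scores = atm, top = top),
            class = "rsma_attention_ranking")
}

#' @export
print.rsma_attention_ranking <- function(x, ...) {
  cat("<rsma_attention_ranking> p=", length(x$nucleotide_scores),
      " q=", length(x$atom_scores), "\n", sep = "")
  for (nm in names(x$top)) {
    cat("  ", nm, " nucleotides: ", paste(x$top[[nm]]$nucleotides, collapse = " "),
        " | atoms: ", paste(x$top[[nm]]$atoms, collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Flat table of attention scores
#'
#' @param ranking An [extract_attention_ranking()] result.
#' @return Tibble with `entity` ("rna"/"molecule"), `position` (1-based),
#'   `score`, `rank` (1 = highest, ties by ascending position).
#' @export
attention_ranking_table <- function(ranking) {
  mk <- function(entity, scores) {
    rk <- integer(length(scores))
    rk[order(-scores, seq_along(scores))] <- seq_along(scores)
    tibble::tibble(entity = entity, position = seq_along(scores),
                   score = scores, rank = rk)
  }
  dplyr::bind_rows(mk("rna", ranking$nucleotide_scores),
                   mk("molecule", ranking$atom_scores))
}

#' Export an attention ranking to JSON
#'
#' @param ranking An [extract_attention_ranking()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_attention_ranking <- function(ranking, path) {
  obj <- list(
    rna_id = ranking$rna_id, mol_id = ranking$mol_id,
    nucleotide_scores = ranking$nucleotide_scores,
    atom_scores = ranking$atom_scores,
    top = lapply(ranking$top, function(t) {
      list(nucleotides = t$nucleotides, atoms = t$atoms)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Bar plot of attention scores
#'
#' @param ranking An [extract_attention_ranking()] result.
#' @param entity `"rna"` or `"molecule"`.
#' @param highlight_k Bars ranked within this cutoff are filled darker.
#' @return A ggplot object.
#' @export
plot_attention_ranking <- function(ranking, entity = c("rna", "molecule"),
                                   highlight_k = 5L) {
  entity <- match.arg(entity)
  tb <- attention_ranking_table(ranking)
  tb <- tb[tb$entity == entity, ]
  tb$highlight <- tb$rank <= highlight_k
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$position, y = .data$score,
                                   fill = .data$highlight)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "#b8860b")) +
    ggplot2::labs(x = if (entity == "rna") "nucleotide position" else "atom index",
                  y = "mean cross-attention score") +
    ggplot2::theme_minimal()
}
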