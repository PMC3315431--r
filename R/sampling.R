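# Sample selection for bootstrapping a specific system: Kennard-Stone
# max-min selection of maximally dissimilar documents, and the
# confidence-extremes alternative that pairs most-likely-useful with
# most-likely-non-useful articles.

#' Kennard-Stone sample selection
#'
#' Selects `n_select` maximally mutually dissimilar rows: the first two
#' selections are the pair at maximal Euclidean distance; every further
#' selection maximises its minimum distance to the already-selected set.
#' Exact distance ties are broken by the lowest row index (for the initial
#' pair, by the lexicographically smallest index pair), so the selection
#' is fully deterministic.
#'
#' @param x a `doc_term_matrix` or numeric matrix (rows = candidates).
#' @param n_select number of rows to select (between 2 and `nrow`).
#' @return An object of class `ks_selection`: list with `indices` (the
#'   selection order), `distances` (the max-min criterion value at each
#'   step; entries 1 and 2 share the initial maximal pairwise distance)
#'   and `metric`.
#' @export
#' @examples
#' kennard_stone(matrix(c(0, 1, 10)), 2)$indices
kennard_stone <- function(x, n_select) {
  if (inherits(x, "doc_term_matrix")) x <- dtm_dense(x)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n_select < 2 || n_select > n) {
    stop_validation("n_select must be between 2 and ", n,
                    " (got ", n_select, ")")
  }
  d <- as.matrix(stats::dist(x))
  dmax <- max(d)
  if (dmax == 0) {
    warning("all rows are identical; selecting by index order")
    return(structure(
      list(indices = seq_len(n_select), distances = rep(0, n_select),
           metric = "euclidean"),
      class = "ks_selection"
    ))
  }
  # initial pair: maximal distance, smallest (i, j) on ties
  hits <- which(d == dmax, arr.ind = TRUE)
  hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  sel <- as.integer(hits[1, ])
  dists <- c(dmax, dmax)

  mind <- pmin(d[, sel[1]], d[, sel[2]])
  while (length(sel) < n_select) {
    mind[sel] <- -Inf
    nxt <- which.max(mind) # lowest index on ties
    sel <- c(sel, nxt)
    dists <- c(dists, mind[nxt])
    mind <- pmin(mind, d[, nxt])
  }
  structure(
    list(indices = as.integer(unname(sel)),
         distances = as.numeric(unname(dists)),
         metric = "euclidean"),
    class = "ks_selection"
  )
}

#' @export
print.ks_selection <- function(x, ...) {
  cat(sprintf("<ks_selection> %d rows (%s); first indices: %s\n",
              length(x$indices), x$metric,
              paste(head(x$indices, 8), collapse = ", ")))
  invisible(x)
}

#' Select articles at both confidence extremes
#'
#' Takes the `n_select/2` highest-confidence (most likely useful) and the
#' `n_select/2` lowest-confidence (most likely non-useful) articles of a
#' ranked prediction list — the proposed remedy for single-class or badly
#' unbalanced Kennard-Stone selections.
#'
#' @param predictions data frame with `doc_id` and `confidence` columns
#'   (as returned by [score_model()] / [rank_articles()]).
#' @param n_select even number of documents to select, at most the number
#'   of predictions.
#' @return Character vector of selected `doc_id`s (top block first).
#' @export
confidence_extremes <- function(predictions, n_select) {
  n <- nrow(predictions)
  if (!n) stop_validation("predictions are empty")
  if (n_select %% 2 != 0) stop_validation("n_select must be even")
  if (n_select > n) {
    stop_validation("n_select (", n_select, ") exceeds population (", n, ")")
  }
  half <- n_select / 2
  ord_desc <- order(-predictions$confidence, predictions$doc_id)
  ord_asc <- order(predictions$confidence, predictions$doc_id)
  top <- predictions$doc_id[ord_desc[seq_len(half)]]
  rest <- setdiff(predictions$doc_id[ord_asc], top)
  bottom <- rest[seq_len(half)]
  c(top, bottom)
}
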