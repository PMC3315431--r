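`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-built term_counts / lexicon constructors for feature-level tests.
make_counts <- function(count_list, totals, ids = NULL) {
  ids <- ids %||% paste0("d", seq_along(count_list))
  structure(list(counts = count_list,
                 totals = setNames(as.integer(totals), ids),
                 doc_ids = ids),
            class = "term_counts")
}

make_lex <- function(terms, df) {
  out <- data.frame(term = terms, category = "specific",
                    document_frequency = as.integer(df),
                    stringsAsFactors = FALSE)
  class(out) <- c("predictor_lexicon", "data.frame")
  out
}

# Small dense matrices posing as doc_term_matrices for model unit tests.
toy_dtm <- function(x, weighting = "tfidf", ids = NULL) {
  ids <- ids %||% paste0("d", seq_len(nrow(x)))
  terms <- colnames(x) %||% paste0("t", seq_len(ncol(x)))
  vals <- Matrix::Matrix(as.matrix(x), sparse = TRUE)
  if (nrow(x) > 0) dimnames(vals) <- list(ids, terms)
  structure(
    list(values = vals,
         doc_ids = ids, terms = terms, weighting = weighting,
         idf = NULL, n_fit = nrow(x)),
    class = "doc_term_matrix"
  )
}
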