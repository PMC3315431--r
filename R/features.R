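# Document-term matrices under the three weightings compared in the
# study: raw word occurrence, binary presence/absence, and TF-IDF with
#   TF_ij  = n_ij / sum_k n_kj        (within-document proportion)
#   IDF_i  = log10(N / n_i)           (N documents fitted, n_i containing i)
#   value  = TF_ij * IDF_i

new_dtm <- function(values, doc_ids, terms, weighting,
                    idf = NULL, n_fit = NULL) {
  dimnames(values) <- list(doc_ids, terms)
  structure(
    list(values = values, doc_ids = doc_ids, terms = terms,
         weighting = weighting, idf = idf, n_fit = n_fit),
    class = "doc_term_matrix"
  )
}

#' @export
print.doc_term_matrix <- function(x, ...) {
  cat(sprintf("<doc_term_matrix> %d documents x %d terms, weighting = %s\n",
              length(x$doc_ids), length(x$terms), x$weighting))
  invisible(x)
}

# Sparse occurrence matrix shared by all three weightings.
counts_to_sparse <- function(counts, lexicon) {
  terms <- lexicon$term
  seen <- unique(unlist(lapply(counts$counts, names), use.names = FALSE))
  extra <- setdiff(seen, terms)
  if (length(extra)) {
    stop_validation("term in counts missing from lexicon: ", extra[1])
  }
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (d in seq_along(counts$counts)) {
    ct <- counts$counts[[d]]
    if (!length(ct)) next
    ii <- c(ii, rep.int(d, length(ct)))
    jj <- c(jj, match(names(ct), terms))
    vv <- c(vv, as.numeric(ct))
  }
  Matrix::sparseMatrix(
    i = ii, j = jj, x = vv,
    dims = c(length(counts$counts), length(terms))
  )
}

#' Weight a document-term matrix
#'
#' `weight_occurrence()` records the raw number of occurrences n_ij;
#' `weight_binary()` records presence/absence as 1/0; `weight_tfidf()`
#' computes term frequency (the proportion of the document's tokens that
#' are the term) times inverse document frequency `log10(N / n_i)`, fitted
#' on this corpus. Rarer terms get larger IDF and hence more weight.
#' Documents with zero surviving tokens get an all-zero row.
#'
#' @param counts a `term_counts` object (see [extract_predictors()]).
#' @param lexicon a `predictor_lexicon` consistent with `counts`.
#' @param log_base base of the IDF logarithm (default 10).
#' @return A `doc_term_matrix`; for TF-IDF it carries the fitted
#'   `idf` table and `n_fit` used by [transform_new()].
#' @export
weight_occurrence <- function(counts, lexicon) {
  new_dtm(counts_to_sparse(counts, lexicon),
          counts$doc_ids, lexicon$term, "occurrence")
}

#' @rdname weight_occurrence
#' @export
weight_binary <- function(counts, lexicon) {
  m <- counts_to_sparse(counts, lexicon)
  m@x <- rep(1, length(m@x))
  new_dtm(m, counts$doc_ids, lexicon$term, "binary")
}

#' @rdname weight_occurrence
#' @export
weight_tfidf <- function(counts, lexicon, log_base = 10) {
  if (any(lexicon$document_frequency < 1)) {
    stop_validation("every lexicon term must occur in at least 1 document")
  }
  n_fit <- length(counts$counts)
  idf <- log(n_fit / lexicon$document_frequency, base = log_base)
  names(idf) <- lexicon$term
  m <- counts_to_sparse(counts, lexicon)
  tot <- as.numeric(counts$totals)
  denom <- ifelse(tot > 0, tot, 1) # zero-token rows stay all-zero
  tf <- Matrix::Diagonal(x = 1 / denom) %*% m
  vals <- tf %*% Matrix::Diagonal(x = idf)
  new_dtm(methods::as(vals, "CsparseMatrix"),
          counts$doc_ids, lexicon$term, "tfidf",
          idf = idf, n_fit = n_fit)
}

#' Weight unseen documents against a fitted matrix
#'
#' Applies the weighting of a fitted `doc_term_matrix` to new documents:
#' the fitted term order is kept, terms outside the fitted lexicon are
#' ignored, and for TF-IDF the *fitted* IDF table is reused (the new
#' corpus does not alter the weights).
#'
#' @param fitted a `doc_term_matrix` produced by one of the `weight_*()`
#'   functions.
#' @param counts `term_counts` for the unseen documents (terms outside the
#'   fitted lexicon are silently dropped).
#' @return A `doc_term_matrix` over the fitted terms.
#' @export
transform_new <- function(fitted, counts) {
  if (!inherits(fitted, "doc_term_matrix")) {
    stop_validation("transform_new needs a fitted doc_term_matrix")
  }
  if (fitted$weighting == "tfidf" && is.null(fitted$idf)) {
    stop_validation("fitted matrix lacks an IDF table")
  }
  pruned <- lapply(counts$counts, function(ct) ct[names(ct) %in% fitted$terms])
  lex <- data.frame(term = fitted$terms, stringsAsFactors = FALSE)
  tc <- term_counts(pruned, counts$totals, counts$doc_ids)
  m <- counts_to_sparse(tc, lex)
  vals <- switch(fitted$weighting,
    occurrence = m,
    binary = { m@x <- rep(1, length(m@x)); m },
    tfidf = {
      tot <- as.numeric(tc$totals)
      denom <- ifelse(tot > 0, tot, 1)
      methods::as(
        Matrix::Diagonal(x = 1 / denom) %*% m %*%
          Matrix::Diagonal(x = fitted$idf),
        "CsparseMatrix"
      )
    },
    stop_validation("unknown weighting: ", fitted$weighting)
  )
  new_dtm(vals, tc$doc_ids, fitted$terms, fitted$weighting,
          idf = fitted$idf, n_fit = fitted$n_fit)
}

#' Export / import a document-term matrix as MatrixMarket
#'
#' Writes `<stem>.mtx` plus sidecar files `<stem>.terms`, `<stem>.docs`
#' and a JSON-ish header `<stem>.meta` recording the weighting (and the
#' IDF table for TF-IDF matrices).
#'
#' @param dtm a `doc_term_matrix`.
#' @param stem path stem (without extension).
#' @return `write_dtm()` returns `stem` invisibly; `read_dtm()` returns
#'   the reconstructed `doc_term_matrix`.
#' @export
write_dtm <- function(dtm, stem) {
  Matrix::writeMM(dtm$values, paste0(stem, ".mtx"))
  writeLines(dtm$terms, paste0(stem, ".terms"))
  writeLines(dtm$doc_ids, paste0(stem, ".docs"))
  meta <- c(paste0("weighting\t", dtm$weighting),
            paste0("n_fit\t", dtm$n_fit %||% ""),
            if (!is.null(dtm$idf)) {
              paste0("idf\t", dtm$terms, "\t",
                     formatC(dtm$idf, digits = 17, format = "g"))
            })
  writeLines(meta, paste0(stem, ".meta"))
  invisible(stem)
}

#' @rdname write_dtm
#' @export
read_dtm <- function(stem) {
  vals <- methods::as(Matrix::readMM(paste0(stem, ".mtx")), "CsparseMatrix")
  terms <- readLines(paste0(stem, ".terms"))
  docs <- readLines(paste0(stem, ".docs"))
  meta <- strsplit(readLines(paste0(stem, ".meta")), "\t", fixed = TRUE)
  keys <- vapply(meta, `[`, character(1), 1)
  weighting <- meta[[which(keys == "weighting")]][2]
  n_fit <- meta[[which(keys == "n_fit")]][2]
  n_fit <- if (nzchar(n_fit)) as.integer(n_fit) else NULL
  idf <- NULL
  if (any(keys == "idf")) {
    rows <- meta[keys == "idf"]
    idf <- stats::setNames(
      as.numeric(vapply(rows, `[`, character(1), 3)),
      vapply(rows, `[`, character(1), 2)
    )[terms]
  }
  new_dtm(vals, docs, terms, weighting, idf = idf, n_fit = n_fit)
}
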