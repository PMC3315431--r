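# The two composed deliverables: the drug-class-agnostic "general"
# automated system, and the bootstrap workflow that turns ~20 freshly
# labelled abstracts into a drug-class "specific" system.

new_system <- function(kind, resources, lexicon, dtm, model, min_df) {
  structure(
    list(kind = kind, resources = resources, lexicon = lexicon,
         dtm = dtm, model = model, weighting = dtm$weighting,
         min_document_frequency = min_df),
    class = "automated_system"
  )
}

#' @export
print.automated_system <- function(x, ...) {
  cat(sprintf("<automated_system> kind = %s, %d predictors (%s weighting), model = %s\n",
              x$kind, nrow(x$lexicon), x$weighting, x$model$algorithm))
  invisible(x)
}

#' Build the general automated system
#'
#' Extracts predictors from a labeled training corpus, restricts the
#' lexicon to general (drug-class-agnostic) terms, weights documents
#' (TF-IDF by default) and trains the classifier (Gaussian-kernel SVM by
#' default). The resulting system ranks any corpus, including corpora from
#' drug classes it never saw.
#'
#' @param training a labeled [corpus()] containing both classes.
#' @param resources a [resource_set()] whose `general_terms` mark the
#'   drug-class-agnostic predictors.
#' @param config a [model_config()] (default: SVM, gamma 1.0, C 1.0).
#' @param weighting `"tfidf"` (default), `"occurrence"` or `"binary"`.
#' @param min_document_frequency lexicon pruning threshold (default 2).
#' @return An `automated_system` of kind `"general"`.
#' @export
build_general_system <- function(training, resources,
                                 config = model_config("svm"),
                                 weighting = "tfidf",
                                 min_document_frequency = 2) {
  build_system("general", training, resources, config, weighting,
               min_document_frequency)
}

build_system <- function(kind, training, resources, config, weighting,
                         min_df) {
  if (any(training$label == "unlabeled")) {
    stop_validation("training corpus must be fully labeled")
  }
  ex <- extract_predictors(training, resources, min_df)
  lex <- if (kind == "general") restrict_general(ex$lexicon) else ex$lexicon
  counts <- ex$counts
  counts$counts <- lapply(counts$counts, function(ct) {
    ct[names(ct) %in% lex$term]
  })
  dtm <- switch(weighting,
    tfidf = weight_tfidf(counts, lex),
    occurrence = weight_occurrence(counts, lex),
    binary = weight_binary(counts, lex),
    stop_validation("unknown weighting: ", weighting)
  )
  model <- train_model(dtm, training$label, config)
  new_system(kind, resources, lex, dtm, model, min_df)
}

#' Rank a corpus by confidence of usefulness
#'
#' Runs the system's text-mining chain on every document, weights the
#' result against the system's fitted lexicon (frozen IDF for TF-IDF) and
#' scores it with the trained model. Articles are returned in decreasing
#' order of confidence (ties broken by ascending `doc_id`) — the order in
#' which they would be presented to an evaluator.
#'
#' @param system an `automated_system`.
#' @param x a [corpus()] (labels, if any, are carried through untouched).
#' @return Data frame `doc_id`, `confidence`, `label` (predicted), sorted
#'   by confidence descending.
#' @export
rank_articles <- function(system, x) {
  if (!nrow(x)) stop_validation("corpus is empty")
  counts <- count_terms(x, system$resources)
  dtm <- transform_new(system$dtm, counts)
  if (all(dtm$values == 0)) {
    warning("no document contains any predictor of the system; ",
            "ranking is uninformative")
  }
  pred <- score_model(system$model, dtm)
  pred[order(-pred$confidence, pred$doc_id), , drop = FALSE]
}

#' Bootstrap a specific automated system from ~20 labelled abstracts
#'
#' The routine-work workflow: a small batch of documents is selected from
#' an unlabeled corpus (by the general system's confidence extremes, or by
#' Kennard-Stone sampling on the corpus's own TF-IDF features), labelled
#' by an evaluator — abstracted here as the `oracle_labels` mapping — and
#' used to train a new system on *all* predictors extracted from those
#' documents alone.
#'
#' @param system the general `automated_system` used for selection.
#' @param x the target-class [corpus()] (treated as unlabeled).
#' @param oracle_labels named vector `doc_id -> label` standing in for the
#'   human evaluator; must cover the selected documents.
#' @param n_label number of documents to have labelled (default 20).
#' @param selection `"confidence_extremes"` (default) or
#'   `"kennard_stone"`.
#' @param config a [model_config()] for the specific system.
#' @param min_document_frequency lexicon pruning threshold applied to the
#'   selected subset (default 2).
#' @return An `automated_system` of kind `"specific"`, with the selected
#'   ids in its `selected_doc_ids` attribute.
#' @export
bootstrap_specific <- function(system, x, oracle_labels, n_label = 20,
                               selection = c("confidence_extremes",
                                             "kennard_stone"),
                               config = model_config("svm"),
                               min_document_frequency = 2) {
  selection <- match.arg(selection)
  if (n_label < 2) stop_validation("n_label must be >= 2")
  if (n_label > nrow(x)) {
    stop_validation("n_label (", n_label, ") exceeds corpus size (",
                    nrow(x), ")")
  }
  ids <- if (selection == "confidence_extremes") {
    confidence_extremes(rank_articles(system, x), n_label)
  } else {
    ex <- extract_predictors(x, system$resources, min_document_frequency)
    dtm <- weight_tfidf(ex$counts, ex$lexicon)
    x$doc_id[kennard_stone(dtm, n_label)$indices]
  }
  missing <- setdiff(ids, names(oracle_labels))
  if (length(missing)) {
    stop_validation("oracle_labels does not cover selected document(s): ",
                    paste(head(missing, 3), collapse = ", "))
  }
  sel <- corpus_subset(x, match(ids, x$doc_id),
                       provenance = "bootstrap selection")
  sel$label <- unname(oracle_labels[sel$doc_id])
  if (length(unique(sel$label)) < 2) {
    stop_validation(
      "the selected documents all received the label '", sel$label[1],
      "'; a specific system needs both classes. Try selection = ",
      "'confidence_extremes', which pairs likely-useful with ",
      "likely-non-useful articles."
    )
  }
  out <- build_system("specific", sel, system$resources, config,
                      system$weighting, min_document_frequency)
  attr(out, "selected_doc_ids") <- ids
  out
}

#' Training-set-size experiment
#'
#' For each requested size, Kennard-Stone-selects that many documents from
#' dataset A (on its TF-IDF features over all predictors), trains a
#' specific-style system on the selection, and reports the class ratio of
#' the selection and the AUC on the validation corpus. Selections that end
#' up single-class, or too small to yield a lexicon, produce an `NA` AUC
#' with an explanatory note instead of aborting the experiment.
#'
#' @param dataset_a labeled [corpus()] to select from.
#' @param validation labeled [corpus()] for AUC measurement.
#' @param sizes ascending training-set sizes, each `< nrow(dataset_a)`
#'   (the unselected remainder of dataset A is the testing set and must be
#'   non-empty).
#' @param resources a [resource_set()].
#' @param config a [model_config()].
#' @param min_document_frequency pruning threshold for the per-selection
#'   lexicons (default 2).
#' @return Data frame `size`, `n_useful`, `n_non_useful`, `ratio`, `auc`,
#'   `note`.
#' @export
training_size_experiment <- function(dataset_a, validation, sizes,
                                     resources,
                                     config = model_config("svm"),
                                     min_document_frequency = 2) {
  if (is.unsorted(sizes)) stop_validation("sizes must be ascending")
  if (any(sizes >= nrow(dataset_a))) {
    stop_validation("every size must leave a non-empty testing set ",
                    "(size < ", nrow(dataset_a), ")")
  }
  ex <- extract_predictors(dataset_a, resources, min_document_frequency)
  dtm_a <- weight_tfidf(ex$counts, ex$lexicon)
  rows <- lapply(sizes, function(sz) {
    sel_idx <- kennard_stone(dtm_a, sz)$indices
    sel <- corpus_subset(dataset_a, sel_idx, "KS selection")
    n_u <- sum(sel$label == "useful")
    n_n <- sum(sel$label == "non_useful")
    ratio <- if (n_u > 0) sprintf("1: %.4g", n_n / n_u) else
      sprintf("0: %d", n_n)
    res <- tryCatch({
      sys <- build_system("specific", sel, resources, config, "tfidf",
                          min_document_frequency)
      pred <- rank_articles(sys, validation)
      lab <- validation$label[match(pred$doc_id, validation$doc_id)]
      list(auc = auc_score(pred$confidence, lab), note = "")
    }, error = function(e) list(auc = NA_real_, note = conditionMessage(e)))
    data.frame(size = sz, n_useful = n_u, n_non_useful = n_n,
               ratio = ratio, auc = res$auc, note = res$note,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
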