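# Shared small synthetic setup: one corpus, split once.
small_setup <- function(seed = 101, n = 300) {
  g <- generate_corpus(generator_config(n_documents = n, seed = seed))
  parts <- stratified_split(g$corpus, c(0.7, 0.3), seed = seed)
  list(train = parts[[1]], holdout = parts[[2]], resources = g$resources,
       truth = g$truth)
}

holdout_auc <- function(system, holdout) {
  pred <- rank_articles(system, holdout)
  lab <- holdout$label[match(pred$doc_id, holdout$doc_id)]
  auc_score(pred$confidence, lab)
}

test_that("the general system never consults a specific-category predictor", {
  s <- small_setup()
  sys <- build_general_system(s$train, s$resources)
  expect_true(all(sys$lexicon$category == "general"))
  expect_true(all(sys$lexicon$term %in% s$truth$general))
  expect_identical(sys$model$terms, sys$lexicon$term)
  expect_equal(sys$weighting, "tfidf")
})

test_that("general system beats chance on held-out data with planted signal", {
  s <- small_setup()
  sys <- build_general_system(s$train, s$resources)
  auc <- holdout_auc(sys, s$holdout)
  # permutation null scale for this holdout
  n1 <- sum(s$holdout$label == "useful")
  n0 <- sum(s$holdout$label == "non_useful")
  sigma <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_gt(auc, 0.5 + 3 * sigma)
})

test_that("permuted training labels give chance-level held-out performance", {
  s <- small_setup(seed = 103)
  shuffled <- s$train
  withr::with_seed(103, shuffled$label <- sample(shuffled$label))
  sys <- build_general_system(shuffled, s$resources)
  auc <- holdout_auc(sys, s$holdout)
  n1 <- sum(s$holdout$label == "useful")
  n0 <- sum(s$holdout$label == "non_useful")
  sigma <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(auc - 0.5), 3 * sigma)
})

test_that("ranking is end-to-end deterministic and sorted", {
  s <- small_setup(seed = 107, n = 200)
  sys1 <- build_general_system(s$train, s$resources)
  sys2 <- build_general_system(s$train, s$resources)
  r1 <- rank_articles(sys1, s$holdout)
  r2 <- rank_articles(sys2, s$holdout)
  expect_identical(r1, r2)
  expect_true(all(diff(r1$confidence) <= 0))
  # singleton corpus ranks fine
  one <- corpus_subset(s$holdout, 1)
  expect_equal(nrow(rank_articles(sys1, one)), 1)
})

test_that("a planted useful document among noise rises to the top decile", {
  hits <- vapply(1:3, function(seed) {
    g <- generate_corpus(generator_config(n_documents = 400, seed = seed))
    parts <- stratified_split(g$corpus, c(0.7, 0.3), seed = seed)
    sys <- build_general_system(parts[[1]], g$resources)
    # probe: 1 useful + 99 non-useful held-out documents
    ho <- parts[[2]]
    probe <- corpus_subset(ho, c(which(ho$label == "useful")[1],
                                 which(ho$label == "non_useful")[1:99]))
    pred <- rank_articles(sys, probe)
    planted <- probe$doc_id[1]
    which(pred$doc_id == planted) <= 10
  }, logical(1))
  expect_gte(sum(hits), 2) # majority of seeds
})

test_that("documents with no predictors produce a warning, not an error", {
  s <- small_setup(seed = 109, n = 200)
  sys <- build_general_system(s$train, s$resources)
  blank <- corpus(c("b1", "b2"), c("qqfoo bar", "unrelated words"), "")
  expect_warning(pred <- rank_articles(sys, blank), "uninformative")
  expect_equal(nrow(pred), 2)
})

test_that("bootstrap_specific trains on the selected documents with all predictors", {
  g <- generate_multiclass(generator_config(n_documents = 300,
                                            n_drug_classes = 2, seed = 113))
  parts <- stratified_split(g$corpora[[1]], c(0.7, 0.3), seed = 113)
  general <- build_general_system(parts[[1]], g$resources)
  target <- g$corpora[[2]]
  oracle <- setNames(target$label, target$doc_id)
  blind <- target
  blind$label <- "unlabeled"

  spec <- bootstrap_specific(general, blind, oracle, n_label = 20)
  expect_equal(spec$kind, "specific")
  sel <- attr(spec, "selected_doc_ids")
  expect_length(sel, 20)
  expect_length(unique(sel), 20)
  # specific lexicon uses both categories, fit from the selection only
  expect_true(any(spec$lexicon$category == "specific"))
  expect_lte(spec$dtm$n_fit, 20)

  # kennard-stone selection route also runs
  spec_ks <- bootstrap_specific(general, blind, oracle, n_label = 10,
                                selection = "kennard_stone")
  expect_equal(spec_ks$kind, "specific")

  # an oracle that returns one class is a stated, advisory error
  all_useful <- setNames(rep("useful", nrow(target)), target$doc_id)
  expect_error(
    bootstrap_specific(general, blind, all_useful, n_label = 20),
    "confidence_extremes|both classes"
  )
  expect_error(bootstrap_specific(general, blind, oracle, n_label = 1),
               "n_label")
  expect_error(
    bootstrap_specific(general, blind, oracle[1:5], n_label = 20),
    "cover"
  )
})

test_that("a two-document bootstrap with one document per class is valid", {
  g <- generate_multiclass(generator_config(n_documents = 300,
                                            n_drug_classes = 2, seed = 127))
  parts <- stratified_split(g$corpora[[1]], c(0.7, 0.3), seed = 127)
  general <- build_general_system(parts[[1]], g$resources)
  target <- g$corpora[[2]]
  oracle <- setNames(target$label, target$doc_id)
  spec <- bootstrap_specific(general, target, oracle, n_label = 2,
                             min_document_frequency = 1)
  expect_equal(spec$kind, "specific")
  expect_equal(spec$model$class_prior, 0.5)
})

test_that("training_size_experiment reports sizes, ratios and AUCs", {
  g <- generate_corpus(generator_config(n_documents = 300, seed = 131))
  parts <- stratified_split(g$corpus, c(0.7, 0.3), seed = 131)
  tab <- training_size_experiment(parts[[1]], parts[[2]],
                                  sizes = c(10, 40), g$resources)
  expect_equal(tab$size, c(10, 40))
  expect_equal(tab$n_useful + tab$n_non_useful, tab$size)
  # ratio column equals a direct label tally of the same KS selection
  ex <- extract_predictors(parts[[1]], g$resources, 2)
  dtm <- weight_tfidf(ex$counts, ex$lexicon)
  sel <- kennard_stone(dtm, 10)$indices
  expect_equal(tab$n_useful[1], sum(parts[[1]]$label[sel] == "useful"))
  ok <- !is.na(tab$auc)
  expect_true(all(tab$auc[ok] >= 0 & tab$auc[ok] <= 1))

  expect_error(
    training_size_experiment(parts[[1]], parts[[2]],
                             sizes = nrow(parts[[1]]), g$resources),
    "testing set"
  )
  expect_error(
    training_size_experiment(parts[[1]], parts[[2]],
                             sizes = c(40, 10), g$resources),
    "ascending"
  )
})
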