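test_that("tokenize lowercases, strips punctuation/digits and splits hyphens", {
  expect_equal(tokenize("TNF-α blockers, e.g. infliximab."),
               c("tnf", "α", "blockers", "e", "g", "infliximab"))
  expect_equal(tokenize(""), character())
  expect_equal(tokenize("12 mg/kg dosing"), c("mg", "kg", "dosing"))
  # hand-tokenized three-sentence abstract
  txt <- paste("Twelve patients developed tuberculosis.",
               "All had received anti-TNF therapy.",
               "Screening is advised before treatment.")
  expect_equal(
    tokenize(txt),
    c("twelve", "patients", "developed", "tuberculosis", "all", "had",
      "received", "anti", "tnf", "therapy", "screening", "is", "advised",
      "before", "treatment")
  )
})

test_that("Porter stemmer collapses the activate family to one root", {
  fam <- c("activate", "activating", "activated", "activates")
  stems <- stem_tokens(fam)
  expect_equal(length(unique(stems)), 1L)
  expect_equal(stem_tokens("of"), "of")
})

test_that("Porter stemmer matches the published rule set on reference words", {
  # expected values derived by hand from the Porter (1980) rules
  pairs <- c(
    caresses = "caress", ponies = "poni", ties = "ti", caress = "caress",
    cats = "cat", feed = "feed", agreed = "agre", plastered = "plaster",
    bled = "bled", motoring = "motor", sing = "sing", troubled = "troubl",
    hopping = "hop", tanned = "tan", falling = "fall", hissing = "hiss",
    filing = "file", happy = "happi", sky = "sky", relational = "relat",
    electricity = "electr", hopeful = "hope", goodness = "good",
    formalize = "formal", controlling = "control", adjustment = "adjust",
    adoption = "adopt", communism = "commun", rate = "rate", cease = "ceas",
    conditional = "condit", effective = "effect", generalization = "gener"
  )
  expect_equal(stem_tokens(names(pairs)), unname(pairs))
  # determinism
  expect_identical(stem_tokens(names(pairs)), stem_tokens(names(pairs)))
})

test_that("stemming a corpus twice with fresh caches is reproducible", {
  texts <- c(corpus_text(toy_corpus()),
             "Adverse reactions were monitored in the safety trial.")
  toks <- unlist(lapply(texts, tokenize))
  expect_identical(stem_tokens(toks), stem_tokens(toks))
  # equivalence classing is what matters: inflected forms share a root
  expect_equal(stem_tokens("reactions"), stem_tokens("reaction"))
  expect_equal(stem_tokens("monitored"), stem_tokens("monitoring"))
})

test_that("remove_stopwords drops exactly the listed tokens", {
  expect_equal(
    remove_stopwords(c("while", "tnf", "to", "works", "on"),
                     c("while", "to", "on")),
    c("tnf", "works")
  )
  expect_equal(remove_stopwords(c("a", "b"), character()), c("a", "b"))
  expect_equal(remove_stopwords(c("to", "on"), c("to", "on")), character())
})

test_that("merge_synonyms canonicalises variants and preserves length", {
  expect_equal(merge_synonyms("tumour", c(tumour = "tumor")), "tumor")
  expect_equal(merge_synonyms(c("a", "b"), character()), c("a", "b"))
  withr::with_seed(4, {
    toks <- sample(letters[1:10], 20, replace = TRUE)
  })
  map <- c(a = "z1", c = "z2", e = "z3", g = "z4", i = "z5")
  got <- merge_synonyms(toks, map)
  ora <- vapply(toks, function(t) {
    if (t %in% names(map)) unname(map[t]) else t
  }, character(1), USE.NAMES = FALSE)
  expect_equal(got, ora)
  expect_length(got, length(toks))
})

test_that("resource_set rejects chained synonym mappings", {
  expect_error(
    resource_set(synonyms = c(tumour = "tumor", tumor = "neoplasm")),
    "chained"
  )
})

test_that("detect_phrases joins leftmost maximal non-overlapping matches", {
  expect_equal(
    detect_phrases(c("tumor", "necrosis", "factor", "alpha"),
                   list(c("tumor", "necrosis", "factor"))),
    c("tumor_necrosis_factor", "alpha")
  )
  expect_equal(detect_phrases(c("x", "y"), list(c("a", "b"))), c("x", "y"))
  # overlapping candidates: leftmost wins
  expect_equal(
    detect_phrases(c("a", "b", "c", "d"),
                   list(c("a", "b", "c"), c("b", "c", "d"))),
    c("a_b_c", "d")
  )
  # longer phrase beats its own prefix at the same start
  expect_equal(
    detect_phrases(c("a", "b", "c"), list(c("a", "b", "c"), c("a", "b"))),
    "a_b_c"
  )
})

test_that("extract_predictors reproduces a hand computation on a toy corpus", {
  rs <- resource_set(
    stopwords = c("the", "of", "was"),
    general_terms = c("safety", "adverse event"),
    phrases = "adverse event",
    stem = FALSE
  )
  cc <- corpus(
    c("d1", "d2"),
    c("Safety of infliximab", "Adverse event reporting"),
    c("The adverse event profile was clear.", "Safety signals emerged."),
    label = c("useful", "non_useful")
  )
  ex <- extract_predictors(cc, rs, min_document_frequency = 1)
  # hand-run of the chain:
  # d1: safety infliximab adverse_event profile clear  (total 5)
  # d2: adverse_event reporting safety signals emerged (total 5)
  expect_equal(ex$counts$totals, c(d1 = 5L, d2 = 5L))
  expect_equal(
    ex$lexicon$term,
    sort(c("safety", "infliximab", "adverse_event", "profile", "clear",
           "reporting", "signals", "emerged"))
  )
  df <- setNames(ex$lexicon$document_frequency, ex$lexicon$term)
  expect_equal(df[["safety"]], 2L)
  expect_equal(df[["adverse_event"]], 2L)
  expect_equal(df[["infliximab"]], 1L)
  cat_of <- setNames(ex$lexicon$category, ex$lexicon$term)
  expect_equal(cat_of[["safety"]], "general")
  expect_equal(cat_of[["adverse_event"]], "general")
  expect_equal(cat_of[["profile"]], "specific")
  expect_equal(ex$counts$counts[[1]][["adverse_event"]], 1L)

  # threshold semantics: min_df = 2 drops singleton terms
  ex2 <- extract_predictors(cc, rs, min_document_frequency = 2)
  expect_setequal(ex2$lexicon$term, c("safety", "adverse_event"))
  expect_false("infliximab" %in% ex2$lexicon$term)

  # infeasible threshold errors with advice
  expect_error(extract_predictors(cc, rs, min_document_frequency = 3),
               "lower min_document_frequency")
})

test_that("stopword removal before or after synonym merge agrees for disjoint resources", {
  toks <- tokenize("the tumour was active while the safety profile was clear")
  toks <- stem_tokens(toks)
  sw <- stem_tokens(c("the", "was", "while"))
  syn <- c(tumour = "tumor")
  syn_prep <- setNames(stem_tokens(unname(syn)), stem_tokens(names(syn)))
  a <- merge_synonyms(remove_stopwords(toks, sw), syn_prep)
  b <- remove_stopwords(merge_synonyms(toks, syn_prep), sw)
  expect_identical(a, b)
})

test_that("count_terms is deterministic and consistent with the lexicon", {
  rs <- default_resources()
  cc <- toy_corpus()
  ex <- extract_predictors(cc, rs, min_document_frequency = 1)
  ex2 <- extract_predictors(cc, rs, min_document_frequency = 1)
  expect_identical(ex$counts$counts, ex2$counts$counts)
  in_counts <- sort(unique(unlist(lapply(ex$counts$counts, names))))
  expect_setequal(in_counts, ex$lexicon$term)
})

test_that("restrict_general keeps general entries with frequencies intact", {
  lex <- data.frame(
    term = c("safety", "adverse", "infliximab", "etanercept", "trial"),
    category = c("general", "general", "specific", "specific", "general"),
    document_frequency = c(5L, 3L, 2L, 1L, 4L),
    stringsAsFactors = FALSE
  )
  class(lex) <- c("predictor_lexicon", "data.frame")
  gen <- restrict_general(lex)
  expect_equal(gen$term, c("safety", "adverse", "trial"))
  expect_equal(gen$document_frequency, c(5L, 3L, 4L))
  # all-general lexicon is the identity
  expect_equal(nrow(restrict_general(gen)), 3)
  # empty result errors
  spec_only <- lex[lex$category == "specific", ]
  class(spec_only) <- c("predictor_lexicon", "data.frame")
  expect_error(restrict_general(spec_only), "general")

  # set-intersection oracle on a larger synthetic lexicon
  withr::with_seed(21, {
    terms <- paste0("w", sprintf("%04d", 1:1000))
    gen_list <- sample(terms, 150)
  })
  big <- data.frame(
    term = terms,
    category = ifelse(terms %in% gen_list, "general", "specific"),
    document_frequency = 1L, stringsAsFactors = FALSE
  )
  class(big) <- c("predictor_lexicon", "data.frame")
  expect_equal(nrow(restrict_general(big)), length(intersect(terms, gen_list)))
})
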