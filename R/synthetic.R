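# Synthetic labeled abstract corpora with the statistical structure the
# triage systems assume: a minority 'useful' class, a drug-class-agnostic
# general signal vocabulary shared across classes, per-class specific
# vocabularies, and a large noise vocabulary. Useful documents oversample
# their class's active general terms and its specific terms; each class
# expresses only a subset of the general vocabulary, which is what makes
# cross-class transfer imperfect.

# consonant-only letter pairs: immune to tokenisation and Porter stemming
.synth_alphabet <- c("b", "c", "d", "f", "g", "h", "k", "l", "m",
                     "n", "p", "r", "t", "v", "w", "x", "z")

synth_vocab <- function(prefix, n) {
  pairs <- as.vector(outer(.synth_alphabet, .synth_alphabet, paste0))
  if (n > length(pairs)) stop_validation("vocabulary size too large")
  paste0(prefix, pairs[seq_len(n)])
}

#' Configure the synthetic-corpus generator
#'
#' Defaults emulate the scale of a manually screened drug-class corpus:
#' a 17.5% 'useful' prevalence, abstracts of ~80 informative tokens, a
#' vocabulary of 30 general (drug-class-agnostic) signal terms, 30
#' class-specific signal terms per drug class and 240 noise terms, with
#' signal terms 5-fold enriched in useful documents. Each drug class
#' expresses a random 70% of the general vocabulary (`general_overlap`),
#' so the general signal transfers across classes only partially.
#'
#' @param n_documents documents per corpus (default 1000).
#' @param prevalence probability that a document is useful (default 0.175).
#' @param n_general,n_specific,n_noise vocabulary sizes (defaults 30, 30,
#'   240).
#' @param enrichment multiplicative oversampling of active signal terms in
#'   useful documents (default 5; 1 means no signal).
#' @param general_overlap fraction of the general vocabulary active in any
#'   one drug class (default 0.7).
#' @param doc_length_mean,doc_length_dispersion negative-binomial document
#'   length (mean 80, size 20), floored at 10 tokens.
#' @param n_drug_classes number of drug classes for
#'   [generate_multiclass()] (default 5; class 1 is the training class).
#' @param seed integer seed; the same seed reproduces the corpora exactly.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_documents = 1000, prevalence = 0.175,
                             n_general = 30, n_specific = 30, n_noise = 240,
                             enrichment = 5, general_overlap = 0.7,
                             doc_length_mean = 80,
                             doc_length_dispersion = 20,
                             n_drug_classes = 5, seed = 1L) {
  if (prevalence <= 0 || prevalence >= 1) {
    stop_validation("prevalence must be in (0, 1)")
  }
  if (enrichment < 1) stop_validation("enrichment must be >= 1")
  if (general_overlap <= 0 || general_overlap > 1) {
    stop_validation("general_overlap must be in (0, 1]")
  }
  if (n_documents < 1 || n_general < 1 || n_specific < 1 || n_noise < 1) {
    stop_validation("counts must be positive")
  }
  structure(
    list(n_documents = as.integer(n_documents), prevalence = prevalence,
         n_general = as.integer(n_general),
         n_specific = as.integer(n_specific),
         n_noise = as.integer(n_noise),
         enrichment = enrichment, general_overlap = general_overlap,
         doc_length_mean = doc_length_mean,
         doc_length_dispersion = doc_length_dispersion,
         n_drug_classes = as.integer(n_drug_classes),
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# One class's corpus; assumes the RNG state is already controlled.
generate_class <- function(config, class_id, general_vocab, specific_vocab,
                           noise_vocab, active_general) {
  n <- config$n_documents
  vocab <- c(general_vocab, specific_vocab, noise_vocab)
  w_base <- rep(1, length(vocab))
  w_useful <- w_base
  w_useful[match(active_general, vocab)] <- config$enrichment
  w_useful[match(specific_vocab, vocab)] <- config$enrichment

  labels <- ifelse(rbinom(n, 1, config$prevalence) == 1,
                   "useful", "non_useful")
  lens <- pmax(10, rnbinom(n, mu = config$doc_length_mean,
                           size = config$doc_length_dispersion))
  texts <- vapply(seq_len(n), function(i) {
    w <- if (labels[i] == "useful") w_useful else w_base
    paste(sample(vocab, lens[i], replace = TRUE, prob = w), collapse = " ")
  }, character(1))
  toks <- strsplit(texts, " ", fixed = TRUE)
  title <- vapply(toks, function(t) paste(head(t, 8), collapse = " "),
                  character(1))
  abstract <- vapply(toks, function(t) paste(tail(t, -8), collapse = " "),
                     character(1))
  corpus(
    doc_id = sprintf("%s%05d", class_id, seq_len(n)),
    title = title, abstract = abstract, label = labels,
    drug_class = class_id,
    provenance = sprintf("synthetic corpus (class %s, seed %d)",
                         class_id, config$seed)
  )
}

#' Generate a synthetic labeled corpus
#'
#' Draws one drug class's corpus and returns it together with the
#' ground-truth [resource_set()] (whose `general_terms` are the true
#' general vocabulary) and the full vocabulary truth tables.
#'
#' @param config a [generator_config()].
#' @return List with `corpus` (a labeled [corpus()]), `resources` (a
#'   [resource_set()] with the true general-term list and no stop words,
#'   synonyms or phrases) and `truth` (general/specific/noise vocabularies
#'   and the class's active general subset).
#' @export
generate_corpus <- function(config = generator_config()) {
  out <- withr::with_seed(config$seed, {
    gen <- synth_vocab("gnl", config$n_general)
    spc <- synth_vocab("spcq", config$n_specific)
    noi <- synth_vocab("bkg", config$n_noise)
    active <- sort(sample(gen, round(config$general_overlap *
                                       config$n_general)))
    list(
      corpus = generate_class(config, "classq", gen, spc, noi, active),
      truth = list(general = gen, specific = spc, noise = noi,
                   active_general = active)
    )
  })
  out$resources <- resource_set(general_terms = out$truth$general)
  out
}

#' Generate corpora for several drug classes
#'
#' All classes share the general vocabulary (each expressing its own
#' random `general_overlap` subset in useful documents) and have disjoint
#' class-specific vocabularies. Class 1 plays the training-class role;
#' the remaining classes form the generalizability set.
#'
#' @param config a [generator_config()] with `n_drug_classes >= 2`.
#' @return List with `corpora` (list of labeled corpora, one per class),
#'   `resources` (ground-truth general-term [resource_set()]) and `truth`
#'   (per-class specific vocabularies and active general subsets).
#' @export
generate_multiclass <- function(config = generator_config()) {
  k <- config$n_drug_classes
  if (k < 2) stop_validation("n_drug_classes must be >= 2")
  class_ids <- paste0("class", letters[seq_len(k)])
  out <- withr::with_seed(config$seed, {
    gen <- synth_vocab("gnl", config$n_general)
    noi <- synth_vocab("bkg", config$n_noise)
    spc <- lapply(seq_len(k), function(ci) {
      synth_vocab(paste0("spc", letters[ci]), config$n_specific)
    })
    active <- lapply(seq_len(k), function(ci) {
      sort(sample(gen, round(config$general_overlap * config$n_general)))
    })
    corpora <- lapply(seq_len(k), function(ci) {
      generate_class(config, class_ids[ci], gen, spc[[ci]], noi,
                     active[[ci]])
    })
    names(corpora) <- class_ids
    names(spc) <- class_ids
    names(active) <- class_ids
    list(corpora = corpora,
         truth = list(general = gen, specific = spc, noise = noi,
                      active_general = active))
  })
  out$resources <- resource_set(general_terms = out$truth$general)
  out
}
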