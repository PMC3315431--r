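#' Break text into tokens
#'
#' Lowercases the text and extracts maximal runs of letters; punctuation
#' and digits are stripped and hyphenated terms fall apart into their
#' components. Single non-ASCII letters (Greek symbols common in
#' pharmacology abstracts) are kept as tokens.
#'
#' @param text character scalar (may be empty).
#' @return Character vector of lowercase tokens in original order.
#' @export
#' @examples
#' tokenize("TNF-α blockers, e.g. infliximab.")
tokenize <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character())
  m <- gregexpr("\\p{L}+", tolower(text), perl = TRUE)
  regmatches(tolower(text), m)[[1]]
}

#' Assemble a resource set for the text-mining chain
#'
#' Bundles the four lexical resources the chain consumes: stop words,
#' a synonym/acronym map (variant to canonical, e.g. British to American
#' spelling), a multiword phrase list, and the list of terms designated
#' *general* (drug-class-agnostic). All entries are tokenized and stemmed
#' at load time so they match the token stream they will be applied to.
#'
#' @param stopwords character vector of stop words.
#' @param synonyms named character vector: `names()` are variants, values
#'   are the canonical terms. Chained mappings (a canonical term that is
#'   itself a variant of something else) are rejected.
#' @param phrases character vector of space-separated multiword terms
#'   (each at least two tokens).
#' @param general_terms character vector of drug-class-agnostic terms;
#'   multiword entries are matched against detected phrases.
#' @param stem logical: stem all resources (and later all documents)?
#' @return An object of class `resource_set`.
#' @export
resource_set <- function(stopwords = character(),
                         synonyms = character(),
                         phrases = character(),
                         general_terms = character(),
                         stem = TRUE) {
  prep_term <- function(x) {
    toks <- tokenize(x)
    if (stem) toks <- stem_tokens(toks)
    paste(toks, collapse = "_")
  }
  prep_vec <- function(v) unique(vapply(v, prep_term, character(1),
                                        USE.NAMES = FALSE))

  sw <- prep_vec(stopwords)
  sw <- sw[nzchar(sw)]

  syn_to <- vapply(unname(synonyms), prep_term, character(1))
  syn_from <- vapply(names(synonyms) %||% character(), prep_term, character(1))
  keep <- nzchar(syn_from) & nzchar(syn_to) & syn_from != syn_to
  syn_from <- syn_from[keep]
  syn_to <- syn_to[keep]
  if (anyDuplicated(syn_from)) {
    stop_validation("synonym map has a variant mapped twice: ",
                    syn_from[duplicated(syn_from)][1])
  }
  chained <- intersect(syn_to, syn_from)
  if (length(chained)) {
    stop_validation("chained synonym mapping detected: '", chained[1],
                    "' is both a canonical term and a variant")
  }
  syn <- stats::setNames(syn_to, syn_from)

  phr <- lapply(phrases, function(p) {
    toks <- tokenize(p)
    if (stem) toks <- stem_tokens(toks)
    toks
  })
  phr <- phr[vapply(phr, length, integer(1)) >= 2]
  if (length(sw)) {
    in_stop <- vapply(phr, function(p) any(p %in% sw), logical(1))
    if (any(in_stop)) {
      stop_validation("phrase contains a stop word: '",
                      paste(phr[[which(in_stop)[1]]], collapse = " "), "'")
    }
  }
  # longest first, so maximal matches win during detection
  phr <- phr[order(vapply(phr, length, integer(1)), decreasing = TRUE)]

  gen <- prep_vec(general_terms)
  gen <- gen[nzchar(gen)]

  structure(
    list(stopwords = sw, synonyms = syn, phrases = phr,
         general_terms = gen, stem = stem),
    class = "resource_set"
  )
}

#' @export
print.resource_set <- function(x, ...) {
  cat(sprintf(
    "<resource_set> %d stopwords, %d synonyms, %d phrases, %d general terms (stemming %s)\n",
    length(x$stopwords), length(x$synonyms), length(x$phrases),
    length(x$general_terms), if (x$stem) "on" else "off"
  ))
  invisible(x)
}

#' Read resource files
#'
#' `read_stopwords()` and `read_general_terms()` expect one entry per line;
#' `read_synonyms()` expects `variant<TAB>canonical` pairs; `read_phrases()`
#' expects one space-separated multiword term per line. Blank lines and
#' lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return Character vector (named for synonyms).
#' @export
read_stopwords <- function(path) read_resource_lines(path)

#' @rdname read_stopwords
#' @export
read_general_terms <- function(path) read_resource_lines(path)

#' @rdname read_stopwords
#' @export
read_phrases <- function(path) read_resource_lines(path)

#' @rdname read_stopwords
#' @export
read_synonyms <- function(path) {
  lines <- read_resource_lines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2)
  if (length(bad)) {
    stop_validation("synonym file line ", bad[1],
                    ": expected variant<TAB>canonical")
  }
  stats::setNames(
    vapply(parts, `[`, character(1), 2),
    vapply(parts, `[`, character(1), 1)
  )
}

read_resource_lines <- function(path) {
  if (!file.exists(path)) stop("cannot read resource file: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Default lexical resources shipped with the package
#'
#' An English stop-word list, a small British/American + pharmacology
#' acronym synonym map, a multiword-term list, and a starter list of
#' drug-class-agnostic (general) predictor terms. Any component can be
#' replaced by a user-supplied file.
#'
#' @param stem logical, passed to [resource_set()].
#' @return A [resource_set()].
#' @export
default_resources <- function(stem = TRUE) {
  p <- function(f) system.file("extdata", f, package = "littriage",
                               mustWork = TRUE)
  resource_set(
    stopwords = read_stopwords(p("stopwords_en.txt")),
    synonyms = read_synonyms(p("synonyms_default.tsv")),
    phrases = read_phrases(p("phrases_default.txt")),
    general_terms = read_general_terms(p("general_predictors.txt")),
    stem = stem
  )
}

#' Remove stop words from a token stream
#'
#' @param tokens character vector of tokens.
#' @param stopwords character vector of stop words (already stemmed when
#'   stemming is in use).
#' @return The subsequence of `tokens` with stop words dropped.
#' @export
remove_stopwords <- function(tokens, stopwords) {
  tokens[!tokens %in% stopwords]
}

#' Replace synonym/acronym variants by their canonical form
#'
#' @param tokens character vector of tokens.
#' @param synonyms named character vector (variant -> canonical).
#' @return Token vector of identical length with variants canonicalised.
#' @export
merge_synonyms <- function(tokens, synonyms) {
  if (!length(synonyms) || !length(tokens)) return(tokens)
  hit <- match(tokens, names(synonyms))
  found <- !is.na(hit)
  tokens[found] <- unname(synonyms[hit[found]])
  tokens
}

#' Join known multiword phrases into single terms
#'
#' Scans left to right; at each position the longest phrase that matches
#' is collapsed into one underscore-joined term, and scanning resumes
#' after it (leftmost, maximal, non-overlapping matches).
#'
#' @param tokens character vector of tokens.
#' @param phrases list of character vectors (each a phrase token sequence),
#'   sorted by decreasing length as produced by [resource_set()].
#' @return Token vector with phrase occurrences collapsed.
#' @export
#' @examples
#' detect_phrases(c("tumor", "necrosis", "factor", "alpha"),
#'                list(c("tumor", "necrosis", "factor")))
detect_phrases <- function(tokens, phrases) {
  if (!length(phrases) || !length(tokens)) return(tokens)
  n <- length(tokens)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (p in phrases) {
      len <- length(p)
      if (i + len - 1L <= n && identical(tokens[i:(i + len - 1L)], p)) {
        out[length(out) + 1L] <- paste(p, collapse = "_")
        i <- i + len
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      out[length(out) + 1L] <- tokens[i]
      i <- i + 1L
    }
  }
  out
}

#' Run the full text-mining chain on one text
#'
#' tokenize, then stem, then stop-word removal, then synonym merging,
#' then phrase detection.
#'
#' @param text character scalar.
#' @param resources a [resource_set()].
#' @return Character vector of processed terms.
#' @export
process_text <- function(text, resources) {
  toks <- tokenize(text)
  if (resources$stem) toks <- stem_tokens(toks)
  toks <- remove_stopwords(toks, resources$stopwords)
  toks <- merge_synonyms(toks, resources$synonyms)
  detect_phrases(toks, resources$phrases)
}

# Per-document term tallies: the raw material for every weighting.
# counts: named integer vectors (term -> n_ij); totals: all retained tokens
# of the document (the within-document denominator of term frequency).
term_counts <- function(counts, totals, doc_ids) {
  structure(list(counts = counts, totals = totals, doc_ids = doc_ids),
            class = "term_counts")
}

#' Count terms for every document of a corpus
#'
#' Applies [process_text()] to each document's title+abstract and tallies
#' term occurrences. The per-document token total is taken over *all*
#' surviving tokens (before any lexicon pruning), so term frequencies are
#' true within-document proportions.
#'
#' @param x a [corpus()].
#' @param resources a [resource_set()].
#' @return A `term_counts` object.
#' @export
count_terms <- function(x, resources) {
  texts <- corpus_text(x)
  toks <- lapply(texts, tokenize)
  if (resources$stem) {
    # stem the whole corpus in one deduplicated pass
    idx <- factor(rep(seq_along(toks), lengths(toks)),
                  levels = seq_along(toks))
    stemmed <- stem_tokens(unlist(toks, use.names = FALSE))
    toks <- split(stemmed, idx)
  }
  counts <- lapply(toks, function(tk) {
    tk <- remove_stopwords(tk, resources$stopwords)
    tk <- merge_synonyms(tk, resources$synonyms)
    tk <- detect_phrases(tk, resources$phrases)
    if (!length(tk)) return(stats::setNames(integer(), character()))
    tb <- table(tk)
    stats::setNames(as.integer(tb), names(tb))
  })
  totals <- vapply(counts, sum, integer(1))
  term_counts(counts, stats::setNames(totals, x$doc_id), x$doc_id)
}

#' Extract the predictor lexicon of a corpus
#'
#' Runs the text-mining chain over the corpus, keeps every term occurring
#' in at least `min_document_frequency` documents, and classifies each
#' retained term as *general* (drug-class-agnostic, i.e. present in the
#' resource set's general-term list) or *specific*.
#'
#' @param x a non-empty [corpus()].
#' @param resources a [resource_set()].
#' @param min_document_frequency drop terms occurring in fewer documents
#'   than this (default 2: singleton terms are noise).
#' @return A list with components `lexicon` (a `predictor_lexicon`
#'   data frame: `term`, `category`, `document_frequency`) and `counts`
#'   (a `term_counts` restricted to the retained terms, with unrestricted
#'   per-document token totals).
#' @export
extract_predictors <- function(x, resources, min_document_frequency = 2) {
  if (!nrow(x)) stop_validation("corpus is empty")
  tc <- count_terms(x, resources)
  all_terms <- unlist(lapply(tc$counts, names), use.names = FALSE)
  df <- table(all_terms)
  keep <- names(df)[df >= min_document_frequency]
  if (!length(keep)) {
    stop_validation(
      "no term reaches document frequency ", min_document_frequency,
      "; lower min_document_frequency"
    )
  }
  keep <- sort(keep)
  lex <- data.frame(
    term = keep,
    category = ifelse(keep %in% resources$general_terms,
                      "general", "specific"),
    document_frequency = as.integer(df[keep]),
    stringsAsFactors = FALSE
  )
  class(lex) <- c("predictor_lexicon", "data.frame")
  pruned <- lapply(tc$counts, function(ct) ct[names(ct) %in% keep])
  list(
    lexicon = lex,
    counts = term_counts(pruned, tc$totals, tc$doc_ids)
  )
}

#' Restrict a lexicon to its general predictors
#'
#' The general automated system is trained on drug-class-agnostic terms
#' only; this drops every specific-category entry.
#'
#' @param lexicon a `predictor_lexicon`.
#' @return The general-only `predictor_lexicon` (document frequencies
#'   unchanged).
#' @export
restrict_general <- function(lexicon) {
  out <- lexicon[lexicon$category == "general", , drop = FALSE]
  if (!nrow(out)) {
    stop_validation("no general predictors in lexicon; check the ",
                    "general-term resource list")
  }
  rownames(out) <- NULL
  class(out) <- c("predictor_lexicon", "data.frame")
  out
}

#' @export
print.predictor_lexicon <- function(x, ...) {
  cat(sprintf("<predictor_lexicon> %d terms (%d general, %d specific)\n",
              nrow(x), sum(x$category == "general"),
              sum(x$category == "specific")))
  invisible(x)
}
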