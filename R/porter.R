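# Porter (1980) suffix-stripping stemmer.
#
# Conventions: a "consonant" is a letter other than a,e,i,o,u, and other
# than y when preceded by a consonant. m() is the number of VC blocks in
# the [C](VC)^m[V] form of a word. Within each step the longest matching
# suffix wins; if its condition fails no other rule of that step fires.

.p_is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.p_is_cons(chars, i - 1L))
  }
  TRUE
}

.p_types <- function(word) {
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  vapply(seq_along(chars), function(i) .p_is_cons(chars, i), logical(1))
}

.p_m <- function(word) {
  if (!nchar(word)) return(0L)
  runs <- rle(.p_types(word))$values # TRUE = consonant block
  sum(!head(runs, -1) & tail(runs, -1))
}

.p_has_vowel <- function(word) {
  nchar(word) > 0 && any(!.p_types(word))
}

.p_ends_double_cons <- function(word) {
  n <- nchar(word)
  n >= 2 &&
    substr(word, n, n) == substr(word, n - 1, n - 1) &&
    .p_types(word)[n]
}

# *o condition: stem ends cvc where the final c is not w, x or y
.p_ends_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3) return(FALSE)
  tp <- .p_types(word)
  tp[n] && !tp[n - 1] && tp[n - 2] &&
    !substr(word, n, n) %in% c("w", "x", "y")
}

.p_ends <- function(word, suffix) {
  n <- nchar(word)
  ns <- nchar(suffix)
  n > ns && substr(word, n - ns + 1, n) == suffix
}

.p_chop <- function(word, suffix) substr(word, 1, nchar(word) - nchar(suffix))

# Steps 2-4 share the pattern: longest matching suffix; replace iff the
# measure condition holds on the stem.
.p_rule_step <- function(word, rules, min_m, ion_special = FALSE) {
  ord <- order(nchar(names(rules)), decreasing = TRUE)
  for (suf in names(rules)[ord]) {
    if (.p_ends(word, suf)) {
      stem <- .p_chop(word, suf)
      ok <- .p_m(stem) > min_m
      if (ok && ion_special && suf == "ion") {
        last <- substr(stem, nchar(stem), nchar(stem))
        ok <- last %in% c("s", "t")
      }
      if (ok) word <- paste0(stem, rules[[suf]])
      return(word)
    }
  }
  word
}

.porter1 <- function(word) {
  if (nchar(word) <= 2) return(word)

  # Step 1a
  if (.p_ends(word, "sses")) {
    word <- paste0(.p_chop(word, "sses"), "ss")
  } else if (.p_ends(word, "ies")) {
    word <- paste0(.p_chop(word, "ies"), "i")
  } else if (!.p_ends(word, "ss") && .p_ends(word, "s")) {
    word <- .p_chop(word, "s")
  }

  # Step 1b
  fired <- FALSE
  if (.p_ends(word, "eed")) {
    stem <- .p_chop(word, "eed")
    if (.p_m(stem) > 0) word <- paste0(stem, "ee")
  } else if (.p_ends(word, "ed") && .p_has_vowel(.p_chop(word, "ed"))) {
    word <- .p_chop(word, "ed")
    fired <- TRUE
  } else if (.p_ends(word, "ing") && .p_has_vowel(.p_chop(word, "ing"))) {
    word <- .p_chop(word, "ing")
    fired <- TRUE
  }
  if (fired) {
    if (.p_ends(word, "at") || .p_ends(word, "bl") || .p_ends(word, "iz")) {
      word <- paste0(word, "e")
    } else if (.p_ends_double_cons(word) &&
               !substr(word, nchar(word), nchar(word)) %in% c("l", "s", "z")) {
      word <- substr(word, 1, nchar(word) - 1)
    } else if (.p_m(word) == 1 && .p_ends_cvc(word)) {
      word <- paste0(word, "e")
    }
  }

  # Step 1c
  if (.p_ends(word, "y") && .p_has_vowel(.p_chop(word, "y"))) {
    word <- paste0(.p_chop(word, "y"), "i")
  }

  # Step 2
  word <- .p_rule_step(word, c(
    ational = "ate", tional = "tion", enci = "ence", anci = "ance",
    izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
    ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
    alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
    aliti = "al", iviti = "ive", biliti = "ble"
  ), min_m = 0L)

  # Step 3
  word <- .p_rule_step(word, c(
    icate = "ic", ative = "", alize = "al", iciti = "ic",
    ical = "ic", ful = "", ness = ""
  ), min_m = 0L)

  # Step 4
  word <- .p_rule_step(word, c(
    al = "", ance = "", ence = "", er = "", ic = "", able = "", ible = "",
    ant = "", ement = "", ment = "", ent = "", ion = "", ou = "", ism = "",
    ate = "", iti = "", ous = "", ive = "", ize = ""
  ), min_m = 1L, ion_special = TRUE)

  # Step 5a
  if (.p_ends(word, "e")) {
    stem <- .p_chop(word, "e")
    m <- .p_m(stem)
    if (m > 1 || (m == 1 && !.p_ends_cvc(stem))) word <- stem
  }

  # Step 5b
  if (.p_m(word) > 1 && .p_ends_double_cons(word) &&
      .p_ends(word, "l")) {
    word <- substr(word, 1, nchar(word) - 1)
  }

  word
}

.stem_cache <- new.env(parent = emptyenv())

#' Stem tokens to their root terms (Porter algorithm)
#'
#' Inflected forms such as "activate", "activating", "activated" and
#' "activates" all reduce to one root term, so they are counted as the same
#' predictor. The function is deterministic; tokens
#' containing characters outside a-z (e.g. Greek letters) are returned
#' unchanged. Repeated tokens are stemmed once via an internal cache, which
#' makes corpus-scale stemming cheap.
#'
#' @param tokens character vector of lowercase tokens.
#' @return Character vector of root terms, same length and order.
#' @export
#' @examples
#' stem_tokens(c("activates", "activating", "tumours"))
stem_tokens <- function(tokens) {
  if (!length(tokens)) return(character())
  uniq <- unique(tokens)
  stems <- vapply(uniq, function(w) {
    hit <- .stem_cache[[w]]
    if (!is.null(hit)) return(hit)
    s <- if (grepl("^[a-z]+$", w)) .porter1(w) else w
    assign(w, s, envir = .stem_cache)
    s
  }, character(1), USE.NAMES = FALSE)
  stems[match(tokens, uniq)]
}
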