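# Independent oracles: deliberately naive re-implementations used to
# cross-check the package's algorithms. They share no code with R/.

# AUC by exhaustive enumeration of all (useful, non-useful) pairs with
# half credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "useful"]
  neg <- scores[labels == "non_useful"]
  wins <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  sum(wins) / (length(pos) * length(neg))
}

# Kennard-Stone by brute force: recompute every candidate's min distance
# to the selected set at every step with explicit loops.
oracle_kennard_stone <- function(x, n_select) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  best <- c(-1, 0, 0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (d[i, j] > best[1]) best <- c(d[i, j], i, j)
    }
  }
  sel <- c(best[2], best[3])
  while (length(sel) < n_select) {
    cand_best <- c(-1, 0)
    for (c in setdiff(seq_len(n), sel)) {
      mind <- min(d[c, sel])
      if (mind > cand_best[1]) cand_best <- c(mind, c) # first index wins ties
    }
    sel <- c(sel, cand_best[2])
  }
  as.integer(sel)
}

# TF-IDF by direct evaluation of the defining formulas with scalar loops.
oracle_tfidf <- function(count_list, totals, terms, n_docs) {
  df <- sapply(terms, function(tm) {
    sum(sapply(count_list, function(ct) tm %in% names(ct)))
  })
  out <- matrix(0, nrow = length(count_list), ncol = length(terms),
                dimnames = list(NULL, terms))
  for (j in seq_along(count_list)) {
    for (tm in terms) {
      nij <- count_list[[j]][tm]
      if (!is.na(nij) && totals[j] > 0) {
        tf <- nij / totals[j]
        idf <- log10(n_docs / df[tm])
        out[j, tm] <- tf * idf
      }
    }
  }
  out
}

# Lift curve by explicit sort-and-tally.
oracle_lift <- function(scores, labels, ids, n_bins) {
  ord <- order(-scores, ids)
  lab <- labels[ord]
  n <- length(scores)
  sizes <- rep(n %/% n_bins, n_bins)
  r <- n %% n_bins
  if (r > 0) sizes[1:r] <- sizes[1:r] + 1
  stops <- cumsum(sizes)
  starts <- c(1, head(stops, -1) + 1)
  per_bin <- mapply(function(a, b) sum(lab[a:b] == "useful"), starts, stops)
  list(per_bin = as.integer(per_bin),
       cum_pct = 100 * cumsum(per_bin) / sum(labels == "useful"))
}

# Random term_counts fixture over a synthetic term universe.
random_counts_fixture <- function(n_docs, n_terms, seed) {
  withr::with_seed(seed, {
    terms <- paste0("t", sprintf("%03d", seq_len(n_terms)))
    count_list <- lapply(seq_len(n_docs), function(i) {
      k <- sample(0:min(n_terms, 12), 1)
      if (k == 0) return(setNames(integer(), character()))
      tm <- sort(sample(terms, k))
      setNames(sample(1:6, k, replace = TRUE), tm)
    })
    # totals include extra out-of-lexicon tokens, as after real pruning
    totals <- sapply(count_list, sum) + sample(0:10, n_docs, replace = TRUE)
    list(terms = terms, count_list = count_list, totals = totals)
  })
}

# Build package-side term_counts + lexicon from a fixture, keeping only
# terms that appear somewhere (document_frequency >= 1).
fixture_to_package <- function(fx, doc_prefix = "d") {
  ids <- paste0(doc_prefix, sprintf("%03d", seq_along(fx$count_list)))
  seen <- sort(unique(unlist(lapply(fx$count_list, names))))
  lex <- data.frame(
    term = seen,
    category = "specific",
    document_frequency = sapply(seen, function(tm) {
      sum(sapply(fx$count_list, function(ct) tm %in% names(ct)))
    }),
    stringsAsFactors = FALSE
  )
  class(lex) <- c("predictor_lexicon", "data.frame")
  counts <- structure(
    list(counts = fx$count_list,
         totals = setNames(as.integer(fx$totals), ids),
         doc_ids = ids),
    class = "term_counts"
  )
  list(lexicon = lex, counts = counts)
}

# Small labeled corpus of free text for end-to-end unit tests.
toy_corpus <- function() {
  corpus(
    doc_id = c("d1", "d2", "d3", "d4"),
    title = c(
      "Adverse events of infliximab",
      "Tumour necrosis factor signalling",
      "Cost analysis of biologics",
      "Serious adverse events in trials"
    ),
    abstract = c(
      "A case report of serious adverse events and safety concerns.",
      "The tumor necrosis factor pathway activates inflammation.",
      "Economic outcomes were compared across hospitals.",
      "Safety monitoring identified adverse drug reactions."
    ),
    label = c("useful", "non_useful", "non_useful", "useful")
  )
}
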