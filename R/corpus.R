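#' Construct an abstract corpus
#'
#' A corpus is an ordered collection of abstract records. Only the title and
#' abstract are ever mined; titles and abstracts are treated as one text.
#'
#' @param doc_id character vector of unique document identifiers (e.g. PMIDs).
#' @param title character vector of titles.
#' @param abstract character vector of abstracts (may be empty strings).
#' @param label document labels: `"useful"`, `"non_useful"` or `"unlabeled"`.
#' @param drug_class optional drug-class tag per document.
#' @param provenance free-text description of where the corpus came from.
#'
#' @return An object of class `corpus`: a `data.frame` with columns
#'   `doc_id`, `title`, `abstract`, `label`, `drug_class` and a
#'   `provenance` attribute.
#' @export
#' @examples
#' corpus(c("1", "2"), c("A title", "Another"), c("Some text.", ""))
corpus <- function(doc_id, title, abstract,
                   label = "unlabeled", drug_class = NA_character_,
                   provenance = "constructed in R") {
  doc_id <- as.character(doc_id)
  n <- length(doc_id)
  if (anyDuplicated(doc_id)) {
    dup <- doc_id[duplicated(doc_id)][1]
    stop_validation("duplicate doc_id in corpus: ", dup)
  }
  label <- rep_len(as.character(label), n)
  bad <- setdiff(unique(label), c("useful", "non_useful", "unlabeled"))
  if (length(bad)) {
    stop_validation("invalid label value(s): ", paste(bad, collapse = ", "))
  }
  out <- data.frame(
    doc_id = doc_id,
    title = rep_len(as.character(title), n),
    abstract = rep_len(as.character(abstract), n),
    label = label,
    drug_class = rep_len(as.character(drug_class), n),
    stringsAsFactors = FALSE
  )
  attr(out, "provenance") <- provenance
  class(out) <- c("corpus", "data.frame")
  out
}

#' @export
print.corpus <- function(x, ...) {
  n <- nrow(x)
  tab <- table(factor(x$label, levels = c("useful", "non_useful", "unlabeled")))
  cat(sprintf(
    "<corpus> %d documents (%d useful, %d non_useful, %d unlabeled)\n",
    n, tab[["useful"]], tab[["non_useful"]], tab[["unlabeled"]]
  ))
  cat("provenance:", attr(x, "provenance") %||% "unknown", "\n")
  invisible(x)
}

#' Subset a corpus by row index, keeping class and provenance
#'
#' @param x a [corpus()].
#' @param idx integer or logical row index.
#' @param provenance optional new provenance string.
#' @return The sub-corpus.
#' @export
corpus_subset <- function(x, idx, provenance = attr(x, "provenance")) {
  out <- x[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- provenance
  class(out) <- c("corpus", "data.frame")
  out
}

# The text that is actually mined: title and abstract joined.
corpus_text <- function(x) {
  ifelse(nzchar(x$abstract), paste(x$title, x$abstract), x$title)
}

#' Read a MEDLINE tagged-format export
#'
#' Parses the tagged text dialect produced by PubMed's "MEDLINE" export:
#' records separated by blank lines, fields as `TAG - value` with
#' continuation lines indented six spaces. Only `PMID`, `TI` and `AB` are
#' consumed; records without an `AB` field get an empty abstract.
#'
#' @param path path to a MEDLINE text file.
#' @return A [corpus()] with `doc_id` taken from `PMID`.
#' @export
read_medline <- function(path) {
  if (!file.exists(path)) stop("cannot read MEDLINE file: ", path)
  lines <- readLines(path, warn = FALSE)

  # fold continuation lines into their field line
  recs <- list()
  cur <- character() # accumulated "TAG\tvalue" strings for current record
  tag <- NULL
  flush_rec <- function() {
    if (length(cur)) recs[[length(recs) + 1L]] <<- cur
    cur <<- character()
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) {
      flush_rec()
      tag <- NULL
    } else if (grepl("^[A-Z0-9]{1,4}\\s*- ", ln)) {
      tag <- sub("^([A-Z0-9]{1,4})\\s*- .*$", "\\1", ln)
      val <- sub("^[A-Z0-9]{1,4}\\s*- ", "", ln)
      if (tag == "PMID" && length(cur) &&
          any(startsWith(cur, "PMID\t"))) {
        # new record without separating blank line
        flush_rec()
      }
      cur[length(cur) + 1L] <- paste0(tag, "\t", val)
    } else if (grepl("^\\s+", ln) && length(cur)) {
      cur[length(cur)] <- paste(cur[length(cur)], trimws(ln))
    }
  }
  flush_rec()

  if (!length(recs)) {
    return(corpus(character(), character(), character(),
                  provenance = paste("MEDLINE file:", path)))
  }

  field <- function(rec, tg) {
    hit <- rec[startsWith(rec, paste0(tg, "\t"))]
    if (!length(hit)) "" else sub("^[A-Z0-9]{1,4}\t", "", hit[1])
  }
  ids <- vapply(recs, field, character(1), tg = "PMID")
  if (any(!nzchar(ids))) stop_validation("MEDLINE record without PMID field")
  if (anyDuplicated(ids)) {
    stop_validation("duplicate PMID in MEDLINE file: ",
                    ids[duplicated(ids)][1])
  }
  corpus(
    doc_id = ids,
    title = vapply(recs, field, character(1), tg = "TI"),
    abstract = vapply(recs, field, character(1), tg = "AB"),
    provenance = paste("MEDLINE file:", path)
  )
}

#' Write a corpus as MEDLINE tagged text
#'
#' Long titles/abstracts are wrapped at word boundaries with six-space
#' continuation indents; [read_medline()] of the output reproduces
#' `doc_id`, `title` and `abstract` exactly.
#'
#' @param x a [corpus()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_medline <- function(x, path) {
  emit_field <- function(tag, value) {
    if (!nzchar(value)) return(character())
    pieces <- strwrap(value, width = 75)
    c(sprintf("%-4s- %s", tag, pieces[1]),
      if (length(pieces) > 1) paste0("      ", pieces[-1]))
  }
  out <- unlist(lapply(seq_len(nrow(x)), function(i) {
    c(emit_field("PMID", x$doc_id[i]),
      emit_field("TI", x$title[i]),
      emit_field("AB", x$abstract[i]),
      "")
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read or write a corpus as CSV
#'
#' Plain CSV with columns `doc_id,title,abstract,label` (and optionally
#' `drug_class`); the dialect used for synthetic corpora.
#'
#' @param path file path.
#' @return [read_corpus_csv()] returns a [corpus()].
#' @export
read_corpus_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("doc_id", "title", "abstract")
  if (!all(need %in% names(df))) {
    stop_validation("corpus CSV must have columns doc_id,title,abstract")
  }
  corpus(
    doc_id = df$doc_id, title = df$title, abstract = df$abstract,
    label = if ("label" %in% names(df)) df$label else "unlabeled",
    drug_class = if ("drug_class" %in% names(df)) df$drug_class else NA,
    provenance = paste("CSV file:", path)
  )
}

#' @rdname read_corpus_csv
#' @param x a [corpus()].
#' @export
write_corpus_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read a label file
#'
#' Two-column delimited text (tab or comma): document id, label token.
#' Label tokens are normalised case-insensitively; `useful` and any of
#' `non-useful` / `non_useful` / `nonuseful` are accepted.
#'
#' @param path path to the label file.
#' @return Named character vector mapping `doc_id` to
#'   `"useful"`/`"non_useful"`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("cannot read label file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- character()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "[\t,]")[[1]]
    parts <- trimws(parts)
    parts <- parts[nzchar(parts)]
    if (length(parts) != 2) {
      stop_validation("label file line ", i, ": expected 2 columns, got ",
                      length(parts))
    }
    token <- gsub("-", "_", tolower(parts[2]))
    lab <- switch(token,
      useful = "useful",
      non_useful = "non_useful",
      nonuseful = "non_useful",
      stop_validation("label file line ", i, ": unknown label token '",
                      parts[2], "'")
    )
    id <- parts[1]
    if (id %in% names(out) && out[[id]] != lab) {
      stop_validation("label file line ", i, ": doc_id '", id,
                      "' already labeled '", out[[id]], "', conflicts with '",
                      lab, "'")
    }
    out[id] <- lab
  }
  out
}

#' Attach labels to a corpus
#'
#' @param x a [corpus()].
#' @param labels named vector as returned by [read_labels()].
#' @return The corpus with its `label` column filled in for matching ids.
#' @export
apply_labels <- function(x, labels) {
  hit <- x$doc_id %in% names(labels)
  x$label[hit] <- unname(labels[x$doc_id[hit]])
  x
}

#' Stratified random split of a labeled corpus
#'
#' Splits a corpus into parts with the given fractions while preserving the
#' useful:non-useful ratio in every part. Each class is shuffled
#' independently and cut by largest-remainder apportionment, so per-class
#' counts differ from the exact fraction by less than one document. The same
#' seed always yields the same partition.
#'
#' @param x a fully labeled [corpus()].
#' @param fractions numeric vector of part proportions, each in (0,1],
#'   summing to 1.
#' @param seed integer seed controlling the shuffle.
#' @return List of [corpus()] parts (disjoint; union is `x`).
#' @export
#' @examples
#' cc <- corpus(as.character(1:10), paste("t", 1:10), "",
#'              label = rep(c("useful", "non_useful"), c(4, 6)))
#' parts <- stratified_split(cc, c(0.5, 0.5), seed = 1)
#' sapply(parts, nrow)
stratified_split <- function(x, fractions, seed = 1L) {
  if (any(fractions <= 0) || any(fractions > 1)) {
    stop_validation("each fraction must be in (0, 1]")
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop_validation("fractions must sum to 1 (got ", sum(fractions), ")")
  }
  if (any(x$label == "unlabeled")) {
    stop_validation("stratified_split requires a fully labeled corpus")
  }
  n_parts <- length(fractions)
  classes <- sort(unique(x$label))
  for (cl in classes) {
    if (sum(x$label == cl) < n_parts) {
      stop_validation("class '", cl, "' has fewer members (",
                      sum(x$label == cl), ") than parts (", n_parts, ")")
    }
  }
  part_of <- integer(nrow(x))
  withr::with_seed(seed, {
    for (cl in classes) {
      idx <- which(x$label == cl)
      idx <- idx[sample.int(length(idx))]
      counts <- apportion(length(idx), fractions)
      part_of[idx] <- rep(seq_len(n_parts), counts)
    }
  })
  lapply(seq_len(n_parts), function(p) {
    corpus_subset(x, which(part_of == p),
                  provenance = sprintf("%s [split part %d/%d, seed %d]",
                                       attr(x, "provenance") %||% "corpus",
                                       p, n_parts, seed))
  })
}

#' Write a confidence-ranked article list
#'
#' Articles are written in decreasing order of confidence (the order in
#' which they would be presented to an evaluator); ties are broken by
#' ascending `doc_id`.
#'
#' @param x a [corpus()].
#' @param scores numeric confidence per document (finite).
#' @param path output TSV path (columns rank, doc_id, score, title).
#' @return The ranked data frame, invisibly.
#' @export
write_ranking <- function(x, scores, path) {
  if (length(scores) != nrow(x)) {
    stop_validation("need exactly one score per document")
  }
  if (any(!is.finite(scores))) {
    stop_validation("scores must be finite (NaN/NA/Inf present)")
  }
  ord <- order(-scores, x$doc_id)
  out <- data.frame(
    rank = seq_len(nrow(x)),
    doc_id = x$doc_id[ord],
    score = scores[ord],
    title = gsub("[\t\n]", " ", x$title[ord]),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
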