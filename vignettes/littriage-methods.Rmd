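---
title: "Methods: automated literature triage for product risk management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated literature triage for product risk management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(littriage)
```

## The problem

Pharmacovigilance teams screen the primary literature for articles that may
warrant regulatory action — reports of new adverse events, incidences of
rare events, mechanisms of toxicity. Only a small minority of retrieved
abstracts (typically well under 20%) is *useful* in this sense, and manual
screening of thousands of abstracts per drug class is slow. `littriage`
ranks abstracts by a classifier's confidence that they are useful, so that
an evaluator reading from the top of the list encounters most of the useful
articles early.

Two deliverables are composed from the same parts:

* a **general automated system**, trained once on a labelled corpus using
  only *general* predictors — terms that are not tied to any one drug
  class — so that it can rank articles about drug classes it never saw;
* a **specific automated system**, built per drug class during routine
  work: the general system selects ~20 articles for the evaluator to
  label, and a fresh classifier is trained on those 20 using *all*
  predictors, including drug-class-specific ones.

Only titles and abstracts are mined; the title and abstract of a document
are concatenated and treated as one text throughout.

## The text-mining chain

Each document passes through a fixed chain
(`tokenize()` → `stem_tokens()` → `remove_stopwords()` →
`merge_synonyms()` → `detect_phrases()`):

1. **Tokenisation** lowercases and keeps maximal runs of letters.
   Punctuation and digits are dropped and hyphenated terms split;
   single Greek letters (α, β …) survive as tokens because
   pharmacology abstracts carry them.
2. **Stemming** uses the Porter algorithm, so *activate*, *activating*,
   *activated* and *activates* count as one predictor. Porter stems are
   equivalence-class labels, not dictionary words (*activ*), and
   re-stemming a stem can shorten it further (*advers* → *adver*); only
   the equivalence classing matters for classification. Stemming of
   repeated tokens is cached, so corpus-scale stemming costs one pass
   over the distinct vocabulary.
3. **Stop words** (function words) are removed. The shipped list is a
   replacement for proprietary tool defaults and can be overridden with
   any one-token-per-line file.
4. **Synonyms and acronyms** are merged variant → canonical
   (British → American spellings, `adr` → *adverse drug reaction*, …).
   Chained mappings are rejected at load time.
5. **Phrases** from a configurable list are collapsed into single terms
   (*tumor necrosis factor* → `tumor_necrosi_factor`), with leftmost,
   maximal, non-overlapping matching.

All resource entries are themselves tokenized and stemmed at load time
(`resource_set()`), so they match the token stream regardless of the
inflection used in the resource file. Phrase entries are therefore stored
pre-stemmed; detection runs after stemming.

`extract_predictors()` tallies the surviving terms and keeps those
occurring in at least `min_document_frequency` documents (default 2 —
singleton terms are uninformative and inflate the lexicon). Each retained
term is *general* if it appears in the resource set's general-term list,
else *specific*. The per-document token total is taken before lexicon
pruning, so term frequencies below are true within-document proportions.

## Feature weightings

Three weightings are implemented (`weight_occurrence()`,
`weight_binary()`, `weight_tfidf()`):

* word occurrence: the raw count $n_{ij}$ of predictor $i$ in document $j$;
* binary frequency: $\mathbb{1}[n_{ij} \ge 1]$;
* TF-IDF: $\mathrm{TF}_{ij} \cdot \mathrm{IDF}_i$ with

$$\mathrm{TF}_{ij} = \frac{n_{ij}}{\sum_k n_{kj}}, \qquad
  \mathrm{IDF}_i = \log_{10}\frac{N}{n_i},$$

where $N$ is the number of fitted documents and $n_i$ the number
containing predictor $i$. Rare terms get larger weights, which is the
stated reason TF-IDF outranks the other two weightings in practice.

Numerical choices:

* The IDF logarithm is base 10 (configurable via `log_base`); the base is
  a positive scalar on all features and does not affect any classifier
  used here.
* IDF is **fitted once on the training corpus and frozen**:
  `transform_new()` weights unseen documents with the stored IDF table
  and term order. Re-fitting IDF per set would make feature values
  incomparable between training and scoring.
* Documents with zero surviving tokens get all-zero rows, never a
  division error.
* A degenerate but instructive corner: with a 2-document training set and
  `min_document_frequency = 2`, every retained term occurs in both
  documents, so every IDF is $\log_{10}(2/2) = 0$ and the feature matrix
  is identically zero — a TF-IDF system cannot be trained from two
  documents under the default pruning. The training-size experiment
  reports such rows honestly (chance-level ranking) rather than hiding
  them.

## Classifiers and confidence values

`train_model()` / `score_model()` expose one contract — a real-valued
confidence per document, higher meaning more likely useful — for four
algorithms:

* **SVM** with Gaussian kernel $k(x, y) = e^{-\gamma\|x-y\|^2}$
  (via libsvm in `e1071`), default $\gamma = 1$, $C = 1$. The confidence
  is the signed decision value, oriented so positive means useful; no
  probability calibration is applied because only the ranking is
  consumed. A configured $C = 0$ (a "determine automatically" sentinel in
  some toolkits) is mapped to the default with a warning — a literal zero
  soft-margin penalty is undefined.
* **Logistic regression** (binomial `glm.fit`); aliased coefficients from
  rank-deficient design matrices are treated as zero. On small
  high-dimensional training sets perfect separation is common; the
  resulting fitted-probability warnings are expected and suppressed, and
  the ranking remains well-defined.
* **k-nearest neighbours** (default $k = 3$, Euclidean distance on the
  weighted features): confidence is the fraction of the $k$ nearest
  training documents labelled useful. Distance ties are broken by
  training-row index so scoring is deterministic.
* **Naive Bayes**, variant chosen by feature type: multinomial with
  Laplace smoothing on occurrence/binary counts, Gaussian with a
  variance floor ($10^{-6}$) on continuous TF-IDF features, which keeps
  zero-variance features from producing degenerate densities.

The decision threshold for hard labels is 0 for decision values and 0.5
for posteriors/votes, but ranking — not labelling — is the primary output.

## Kennard–Stone selection and confidence extremes

`kennard_stone()` selects maximally mutually dissimilar documents: the
first two selections are the pair at maximal Euclidean distance, and each
later selection maximises its minimum distance to the already-selected
set. Exact ties break to the lowest row index (lexicographically smallest
pair for the seed pair), making selection fully deterministic. Distances
are computed on the same weighting the downstream system trains on
(TF-IDF over all predictors, by default).

Kennard–Stone ignores labels, so a selection can come out single-class or
badly unbalanced — exactly the hazard observed when a 36-document
selection underperforms a 20-document one. `confidence_extremes()` is the
remedy used by default in the bootstrap workflow: take the
$n/2$ highest-confidence and $n/2$ lowest-confidence articles from the
general system's ranking, which pairs likely-useful with
likely-non-useful documents.

`bootstrap_specific()` abstracts the human evaluator as an
`oracle_labels` mapping so the whole workflow is testable end to end. The
specific system re-extracts its lexicon — and re-fits IDF — from the ~20
selected documents only (configurable design choice: those documents are
the only labelled material the specific system is entitled to). If the
selection is single-class the function stops with advice to switch the
selection method.

## Evaluation

* `auc_score()` is the Mann–Whitney rank statistic with midrank ties:
  exactly the probability that a random useful article outranks a random
  non-useful one, with half credit for ties, in $O(n \log n)$. It
  coincides with trapezoidal ROC integration under midrank tie handling.
* `lift_curve()` sorts by confidence (ties by document id), cuts the list
  into near-equal bins — remainders go to the *first* bins, so "the first
  10%" of 1190 articles is 119 — and reports per-bin useful counts,
  cumulative percentages of all useful articles recovered, and the
  random-ranking diagonal.

## The synthetic benchmark generator

No labelled pharmacovigilance corpus ships with the package, so
`generate_corpus()` / `generate_multiclass()` emit corpora with the
statistical structure the systems assume. Per document: a label drawn
with prevalence 0.175 (the minority-useful regime of a screened drug
class corpus), a length drawn from NegBin(mean 80, size 20) floored at 10
tokens (the scale of an informative-token stream of a title plus
abstract), and tokens drawn from a mixture over three disjoint
vocabularies:

* 30 **general** signal terms, shared across drug classes;
* 30 **class-specific** signal terms per class, disjoint between classes;
* 240 **noise** terms.

In useful documents the active signal terms are oversampled by an
enrichment factor (default 5); non-useful documents draw uniformly.
Each drug class expresses its own random 70% subset of the general
vocabulary (`general_overlap`): general safety vocabulary overlaps
between drug classes but does not coincide, and this partial overlap is
what produces the generalizability drop — a general system keys on its
training class's active terms, only ~70% of which are active in an
unseen class. Tokens are consonant-pair strings (`gnlbb`, `spcacd`,
`bkgfh`) chosen to pass through tokenisation and stemming unchanged, and
synthetic corpora are emitted in both MEDLINE and CSV dialects so the
readers are exercised too.

What the generator deliberately does **not** model: grammar, topical
correlation between terms, label noise, near-duplicate abstracts, and
drifting vocabulary over time. Passing benchmarks on this generator shows
the machinery is correct and the qualitative trends (weighting order,
training-size effect, transfer degradation, bootstrap benefit) hold under
planted signal; it does not certify absolute performance on real
abstracts, where AUCs will be substantially lower.

## Experiment scale and reproducibility

The shipped tests and the acceptance script run the full pipeline at
sizes chosen to be representative while staying desk-scale: single-class
benchmarks use 500–1000 documents, multiclass transfer and bootstrap
experiments 400 documents per class, and the training-size experiment a
600-document corpus (420 in dataset A after the 70/30 split), with means
over 5–20 replicate seeds. Every source of randomness — label draws,
document lengths, token draws, stratified splits, model seeds — is
controlled by explicit integer seeds; the same seed reproduces a corpus,
a split, and a ranked list bitwise.

The splitting scheme mirrors routine practice: a stratified 70/30 split
into datasets A and B, dataset A further split 2:1 into training and
testing sets, with per-class largest-remainder apportionment so every
part preserves the useful:non-useful ratio to within one document.

## Known limitations

* Bag-of-words only: no MeSH/UMLS concepts, no n-gram discovery beyond
  the supplied phrase list, no full-text processing.
* The shipped stop-word/synonym/phrase/general-term lists are small open
  starter resources; serious use should supply curated lists via the
  `read_*` loaders (the general-term loader accepts any externally
  curated list verbatim).
* Class imbalance is not reweighted; highly unbalanced training sets
  degrade ranking quality, which is visible in the training-size
  experiment's ratio column.
* AUC weighs false positives and false negatives symmetrically, which
  understates the cost of missing a useful article; cost-sensitive
  measures are out of scope.

## A worked example

```{r example, eval = FALSE}
g <- generate_corpus(generator_config(n_documents = 1000, seed = 7))
parts <- stratified_split(g$corpus, c(0.7, 0.3), seed = 7)

sys <- build_general_system(parts[[1]], g$resources)
pred <- rank_articles(sys, parts[[2]])
lab <- parts[[2]]$label[match(pred$doc_id, parts[[2]]$doc_id)]

auc_score(pred$confidence, lab)
lift_curve(pred$confidence, lab, doc_ids = pred$doc_id)
```
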