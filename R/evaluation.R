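# The two performance surfaces: AUC (probability that a random useful
# article outranks a random non-useful one) and the decile lift chart
# (cumulative percentage of useful articles recovered as the evaluator
# works down the ranked list).

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic with midrank tie handling:
#' exactly the fraction of (useful, non-useful) pairs in which the useful
#' article scores higher, with half credit for ties.
#'
#' @param confidences numeric scores, higher = more likely useful.
#' @param labels `"useful"`/`"non_useful"` per document; both classes must
#'   be present.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc_score(c(0.9, 0.4, 0.6, 0.1),
#'           c("useful", "useful", "non_useful", "non_useful"))
auc_score <- function(confidences, labels) {
  if (length(confidences) != length(labels)) {
    stop_validation("confidences and labels differ in length")
  }
  if (any(!is.finite(confidences))) {
    stop_validation("confidences must be finite")
  }
  pos <- labels == "useful"
  n1 <- sum(pos)
  n0 <- sum(labels == "non_useful")
  if (n1 == 0 || n0 == 0) {
    stop_validation("both classes must be present to compute AUC")
  }
  r <- rank(confidences, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Decile lift curve of a ranked labeled list
#'
#' Documents are sorted by confidence descending (ties broken by ascending
#' `doc_id`) and cut into `n_bins` near-equal bins; remainders go to the
#' first bins. For every bin the curve records how many articles were
#' presented, how many of them were useful, the cumulative percentage of
#' all useful articles recovered so far, and the random-ranking baseline.
#'
#' @param confidences numeric scores.
#' @param labels `"useful"`/`"non_useful"` per document.
#' @param n_bins number of bins (default 10, i.e. deciles).
#' @param doc_ids optional ids used for the tie-break (default: input
#'   position).
#' @return A `lift_curve` data frame with columns `bin`, `n_presented`,
#'   `n_useful`, `cum_useful_pct`, `baseline_pct`.
#' @export
lift_curve <- function(confidences, labels, n_bins = 10, doc_ids = NULL) {
  n <- length(confidences)
  if (!n) stop_validation("empty input")
  if (n_bins < 1 || n < n_bins) {
    stop_validation("need at least n_bins (", n_bins, ") documents, got ", n)
  }
  if (is.null(doc_ids)) doc_ids <- sprintf("%09d", seq_len(n))
  pos <- labels == "useful"
  total_useful <- sum(pos)
  if (total_useful == 0) stop_validation("no useful documents in input")
  ord <- order(-confidences, doc_ids)
  sizes <- rep(floor(n / n_bins), n_bins)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  bin_of <- rep(seq_len(n_bins), sizes)
  useful_in <- vapply(seq_len(n_bins), function(b) {
    sum(pos[ord[bin_of == b]])
  }, numeric(1))
  out <- data.frame(
    bin = seq_len(n_bins),
    n_presented = sizes,
    n_useful = as.integer(useful_in),
    cum_useful_pct = 100 * cumsum(useful_in) / total_useful,
    baseline_pct = 100 * seq_len(n_bins) / n_bins
  )
  attr(out, "total_useful") <- total_useful
  class(out) <- c("lift_curve", "data.frame")
  out
}

#' Plot a lift curve
#'
#' Bars show the number of useful articles per bin; the line is the
#' cumulative percentage recovered, against the random-ranking diagonal.
#'
#' @param x a `lift_curve`.
#' @param main plot title.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.lift_curve <- function(x, main = "Lift chart", ...) {
  mid <- graphics::barplot(x$n_useful, names.arg = paste0(x$bin * 10, "%"),
                           col = "firebrick", border = NA,
                           ylim = c(0, max(x$n_useful) * 1.3),
                           xlab = "Articles presented",
                           ylab = "Useful articles in bin", main = main, ...)
  scale <- max(x$n_useful) * 1.25 / 100
  graphics::lines(mid, x$cum_useful_pct * scale, type = "b", pch = 19)
  graphics::lines(mid, x$baseline_pct * scale, lty = 2)
  graphics::axis(4, at = c(0, 25, 50, 75, 100) * scale,
                 labels = paste0(c(0, 25, 50, 75, 100), "%"))
  invisible(x)
}
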