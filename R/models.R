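# The four confidence-scoring classifiers compared in the study.
# Every model exposes one contract: a real-valued confidence per document,
# higher meaning "more likely useful"; ranking by confidence is the
# primary output, hard labels are a convenience.

#' Configure a classifier
#'
#' @param algorithm one of `"logistic_regression"`, `"knn"`,
#'   `"naive_bayes"`, `"svm"`.
#' @param k neighbour count for k-NN (odd, default 3).
#' @param gamma Gaussian-kernel width for the SVM (default 1.0).
#' @param C SVM soft-margin penalty. The value `0` is treated as a
#'   "determine automatically" sentinel (some toolkits print it that way)
#'   and mapped to the default `1.0` with a warning; a literal zero
#'   penalty is undefined for a soft-margin SVM.
#' @param seed integer seed consulted wherever fitting involves randomness.
#' @return A `model_config` list.
#' @export
model_config <- function(algorithm = c("svm", "logistic_regression",
                                       "knn", "naive_bayes"),
                         k = 3L, gamma = 1.0, C = 1.0, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "knn") {
    if (k < 1 || k %% 2 == 0) stop_validation("k must be odd and >= 1")
  }
  if (algorithm == "svm") {
    if (gamma <= 0) stop_validation("gamma must be > 0")
    if (C == 0) {
      warning("C = 0 interpreted as 'determine automatically'; using C = 1.0")
      C <- 1.0
    }
    if (C < 0) stop_validation("C must be > 0")
  }
  structure(list(algorithm = algorithm, k = as.integer(k),
                 gamma = gamma, C = C, seed = as.integer(seed)),
            class = "model_config")
}

#' Gaussian (RBF) kernel
#'
#' `exp(-gamma * ||x - y||^2)`: 1 iff the vectors coincide, decaying with
#' squared Euclidean distance.
#'
#' @param x,y numeric vectors of equal length.
#' @param gamma positive kernel width.
#' @return Similarity in (0, 1].
#' @export
gaussian_kernel <- function(x, y, gamma) {
  if (length(x) != length(y)) {
    stop_validation("gaussian_kernel: dimension mismatch (",
                    length(x), " vs ", length(y), ")")
  }
  if (gamma <= 0) stop_validation("gamma must be > 0")
  exp(-gamma * sum((x - y)^2))
}

dtm_dense <- function(dtm) as.matrix(dtm$values)

#' Train a confidence-scoring classifier
#'
#' @param dtm a `doc_term_matrix` of training documents.
#' @param labels character vector (`"useful"`/`"non_useful"`) aligned with
#'   the matrix rows; both classes must be present.
#' @param config a [model_config()].
#' @return A `trained_model` carrying the fitted state, the training term
#'   order (scoring requires the identical order; [transform_new()]
#'   guarantees it) and the training class prior.
#' @export
train_model <- function(dtm, labels, config = model_config()) {
  x <- dtm_dense(dtm)
  if (nrow(x) == 0 || ncol(x) == 0) stop_validation("empty training matrix")
  if (length(labels) != nrow(x)) {
    stop_validation("labels length (", length(labels),
                    ") != number of documents (", nrow(x), ")")
  }
  if (!all(labels %in% c("useful", "non_useful"))) {
    stop_validation("labels must be 'useful' or 'non_useful'")
  }
  if (length(unique(labels)) < 2) {
    stop_validation("training set contains a single class; both 'useful' ",
                    "and 'non_useful' examples are required")
  }
  y <- factor(labels, levels = c("non_useful", "useful"))
  fit <- withr::with_seed(config$seed, switch(config$algorithm,
    svm = fit_svm(x, y, config),
    logistic_regression = fit_logistic(x, y),
    knn = list(x = x, y = y, k = config$k),
    naive_bayes = fit_naive_bayes(x, y, dtm$weighting)
  ))
  structure(
    list(config = config, algorithm = config$algorithm, fit = fit,
         terms = dtm$terms, weighting = dtm$weighting,
         class_prior = mean(labels == "useful")),
    class = "trained_model"
  )
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s on %d terms (%s weighting), prior P(useful) = %.3f\n",
              x$algorithm, length(x$terms), x$weighting, x$class_prior))
  invisible(x)
}

fit_svm <- function(x, y, config) {
  e1071::svm(x = x, y = y, kernel = "radial", gamma = config$gamma,
             cost = config$C, scale = FALSE)
}

fit_logistic <- function(x, y) {
  xx <- cbind(`(Intercept)` = 1, x)
  fit <- suppressWarnings(
    stats::glm.fit(xx, as.integer(y == "useful"), family = binomial())
  )
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0 # aliased columns contribute nothing
  list(beta = beta)
}

# Naive Bayes, variant chosen by feature type: multinomial with Laplace
# smoothing on count-like features (occurrence/binary), Gaussian with a
# variance floor on continuous TF-IDF features.
fit_naive_bayes <- function(x, y, weighting) {
  if (weighting %in% c("occurrence", "binary")) {
    cls <- levels(y)
    tok <- t(vapply(cls, function(cl) colSums(x[y == cl, , drop = FALSE]),
                    numeric(ncol(x))))
    theta <- (tok + 1) / (rowSums(tok) + ncol(x)) # Laplace smoothing
    list(variant = "multinomial", log_theta = log(theta),
         log_prior = log(table(y) / length(y)))
  } else {
    cls <- levels(y)
    mu <- t(vapply(cls, function(cl) colMeans(x[y == cl, , drop = FALSE]),
                   numeric(ncol(x))))
    sg <- t(vapply(cls, function(cl) {
      apply(x[y == cl, , drop = FALSE], 2, stats::sd)
    }, numeric(ncol(x))))
    sg[!is.finite(sg) | sg < 1e-6] <- 1e-6 # variance floor
    list(variant = "gaussian", mu = mu, sigma = sg,
         log_prior = log(table(y) / length(y)))
  }
}

#' Score documents with a trained model
#'
#' The confidence is the SVM's signed decision value (positive side =
#' useful), the class-1 posterior for logistic regression and naive
#' Bayes, or the neighbour vote fraction for k-NN. Hard labels use
#' threshold 0 for decision values and 0.5 for posteriors/votes.
#'
#' @param model a `trained_model`.
#' @param dtm a `doc_term_matrix` with the same term order as the model
#'   (use [transform_new()]).
#' @return A data frame with columns `doc_id`, `confidence`, `label`,
#'   one row per document in matrix order.
#' @export
score_model <- function(model, dtm) {
  if (!identical(dtm$terms, model$terms)) {
    stop_validation("term order of matrix does not match the model; ",
                    "weight unseen documents with transform_new()")
  }
  x <- dtm_dense(dtm)
  conf <- switch(model$algorithm,
    svm = score_svm(model$fit, x),
    logistic_regression = as.numeric(
      plogis(cbind(1, x) %*% model$fit$beta)
    ),
    knn = score_knn(model$fit, x),
    naive_bayes = score_naive_bayes(model$fit, x)
  )
  threshold <- if (model$algorithm == "svm") 0 else 0.5
  data.frame(
    doc_id = dtm$doc_ids,
    confidence = as.numeric(conf),
    label = ifelse(conf >= threshold, "useful", "non_useful"),
    stringsAsFactors = FALSE
  )
}

score_svm <- function(fit, x) {
  pred <- predict(fit, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # libsvm orients the decision value towards the first training label;
  # flip so that positive always means 'useful'
  flip <- if (grepl("^useful/", colnames(dv)[1])) 1 else -1
  as.numeric(dv[, 1]) * flip
}

score_knn <- function(fit, x) {
  tr <- fit$x
  # squared Euclidean distances probe x training
  d2 <- outer(rowSums(x^2), rowSums(tr^2), "+") - 2 * x %*% t(tr)
  useful <- fit$y == "useful"
  k <- fit$k
  apply(d2, 1, function(dr) {
    nb <- order(dr, seq_along(dr))[seq_len(k)] # index tie-break
    mean(useful[nb])
  })
}

score_naive_bayes <- function(fit, x) {
  if (fit$variant == "multinomial") {
    ll <- x %*% t(fit$log_theta)
  } else {
    ll <- vapply(seq_along(fit$log_prior), function(ci) {
      rowSums(dnorm(x, rep(fit$mu[ci, ], each = nrow(x)),
                    rep(fit$sigma[ci, ], each = nrow(x)), log = TRUE))
    }, numeric(nrow(x)))
  }
  ll <- sweep(ll, 2, as.numeric(fit$log_prior), "+")
  # posterior of 'useful' (second class level), numerically stable
  m <- apply(ll, 1, max)
  p <- exp(ll - m)
  p[, 2] / rowSums(p)
}
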