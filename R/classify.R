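# Classifier front end over a score matrix. Four algorithms mirror the
# WEKA modules named in the field's CaM-binding work, with documented (not
# bit-matched) settings: k-NN with Euclidean distance, SVM with a
# normalized polynomial kernel on min-max scaled features, random forest
# with 100 trees, and Gaussian naive Bayes.

#' Classifier specification
#'
#' @param algorithm One of `"knn"`, `"svm"`, `"rf"`, `"nb"`.
#' @param k Neighbor count for k-NN (Euclidean distance).
#' @param degree Polynomial degree of the normalized polynomial SVM kernel
#'   `K'(x,y) = K(x,y) / sqrt(K(x,x) K(y,y))`, `K(x,y) = (x.y + 1)^degree`,
#'   applied to min-max scaled features with cost C = 1.
#' @param trees Tree count for the random forest.
#' @param seed Integer seed controlling any training randomness.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("rf", "knn", "svm", "nb"),
                            k = 1L, degree = 2L, trees = 100L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(k >= 1L, degree >= 1L, trees >= 1L)
  structure(list(algorithm = algorithm, k = as.integer(k),
                 degree = as.integer(degree), trees = as.integer(trees),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

# WEKA-style normalized polynomial kernel for kernlab
.norm_poly_kernel <- function(degree = 2L, offset = 1) {
  f <- function(x, y) {
    kxy <- (sum(x * y) + offset)^degree
    kxx <- (sum(x * x) + offset)^degree
    kyy <- (sum(y * y) + offset)^degree
    kxy / sqrt(kxx * kyy)
  }
  class(f) <- "kernel"
  f
}

# min-max scale columns by training ranges; constant columns map to 0
.minmax <- function(train, test) {
  lo <- apply(train, 2L, min)
  hi <- apply(train, 2L, max)
  rng <- pmax(hi - lo, .Machine$double.eps)
  scale_one <- function(m) sweep(sweep(m, 2L, lo), 2L, rng, "/")
  list(train = scale_one(train), test = scale_one(test))
}

# train on (x, y in {0,1}) and predict test_x; returns list(class = 0/1
# integer vector, score = positive-class score). All randomness is seeded.
.fit_predict <- function(spec, x, y, test_x) {
  yf <- factor(y, levels = c(0L, 1L))
  switch(spec$algorithm,
    knn = {
      pred <- .with_seed(spec$seed, class::knn(
        train = x, test = test_x, cl = yf, k = spec$k, prob = TRUE))
      win <- attr(pred, "prob")  # vote fraction of the winning class
      cls <- as.integer(as.character(pred))
      list(class = cls, score = ifelse(cls == 1L, win, 1 - win))
    },
    rf = {
      fit <- .with_seed(spec$seed, randomForest::randomForest(
        x = x, y = yf, ntree = spec$trees))
      prob <- predict(fit, test_x, type = "prob")[, "1"]
      list(class = as.integer(prob > 0.5), score = as.numeric(prob))
    },
    nb = {
      fit <- e1071::naiveBayes(x = as.data.frame(x), y = yf)
      prob <- predict(fit, as.data.frame(test_x), type = "raw")[, "1"]
      list(class = as.integer(prob > 0.5), score = as.numeric(prob))
    },
    svm = {
      sc <- .minmax(x, test_x)
      fit <- .with_seed(spec$seed, kernlab::ksvm(
        x = sc$train, y = yf, kernel = .norm_poly_kernel(spec$degree),
        C = 1, scaled = FALSE))
      dec <- as.numeric(kernlab::predict(fit, sc$test, type = "decision"))
      cls <- as.integer(as.character(kernlab::predict(fit, sc$test)))
      # orient the decision value toward the positive class using the
      # training data (the margin sign follows factor-level internals)
      dec_tr <- as.numeric(kernlab::predict(fit, sc$train,
                                            type = "decision"))
      if (mean(dec_tr[y == 1L]) < mean(dec_tr[y == 0L])) dec <- -dec
      list(class = cls, score = dec)
    }
  )
}

# stratified fold assignment: within each class, shuffle then deal folds
.stratified_folds <- function(y, folds, seed) {
  assign <- integer(length(y))
  .with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' k-fold cross-validation of a classifier on a score matrix
#'
#' Stratified, seeded fold assignment; out-of-fold predictions are pooled
#' into a single confusion table from which accuracy and MCC are computed;
#' ROC-AUC uses pooled positive-class scores (k-NN: neighbor-vote fraction,
#' RF: tree-vote fraction, NB: posterior, SVM: oriented decision value).
#'
#' @param sm An `sws_score_matrix` (or plain numeric matrix).
#' @param labels Integer 0/1 vector aligned to rows (taken from `sm` when
#'   `NULL` and available).
#' @param spec A [classifier_spec()].
#' @param folds Number of folds (>= 2; every class must have >= folds
#'   members).
#' @param seed Seed for the fold assignment.
#' @return Object of class `eval_result`: list with `accuracy`, `mcc`,
#'   `roc_auc`, `confusion`, `predictions` (pooled truth/pred/score) and
#'   `split` descriptor.
#' @export
cross_validate <- function(sm, labels = NULL, spec = classifier_spec(),
                           folds = 3L, seed = 1L) {
  x <- if (inherits(sm, "sws_score_matrix")) sm$scores else as.matrix(sm)
  if (is.null(labels) && inherits(sm, "sws_score_matrix")) {
    labels <- sm$labels
  }
  y <- as.integer(labels)
  stopifnot(length(y) == nrow(x), folds >= 2L)
  if (length(unique(y)) < 2L) stop("need two classes", call. = FALSE)
  if (min(table(y)) < folds) {
    stop("smallest class (", min(table(y)), ") has fewer members than folds (",
         folds, ")", call. = FALSE)
  }
  assign <- .stratified_folds(y, folds, seed)
  pred <- integer(length(y))
  score <- numeric(length(y))
  for (f in seq_len(folds)) {
    te <- assign == f
    r <- .fit_predict(spec, x[!te, , drop = FALSE], y[!te],
                      x[te, , drop = FALSE])
    pred[te] <- r$class
    score[te] <- r$score
  }
  cc <- .confusion_from(y, pred)
  structure(
    list(accuracy = accuracy(cc), mcc = mcc(cc),
         roc_auc = .roc_auc(y, score), confusion = cc,
         predictions = data.frame(truth = y, pred = pred, score = score),
         split = list(type = "cv", folds = folds, seed = seed)),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result (%s): accuracy=%.4f MCC=%.4f ROC-AUC=%s\n",
              x$split$type, x$accuracy, x$mcc,
              ifelse(is.na(x$roc_auc), "NA", sprintf("%.4f", x$roc_auc))))
  invisible(x)
}

#' Seeded holdout series with box statistics
#'
#' For each seed, one stratified split (default 90% train / 10% test) is
#' trained and evaluated; the per-seed metric values are summarized as a
#' five-number box ([box_summary()]).
#'
#' @inheritParams cross_validate
#' @param seeds Integer vector of split seeds (default `1:10`).
#' @param train_fraction Training fraction in (0, 1).
#' @return List with `results` (one `eval_result` per seed) and `box`
#'   (named list of box summaries for accuracy, mcc, roc_auc).
#' @export
holdout_series <- function(sm, labels = NULL, spec = classifier_spec(),
                           seeds = 1:10, train_fraction = 0.9) {
  x <- if (inherits(sm, "sws_score_matrix")) sm$scores else as.matrix(sm)
  if (is.null(labels) && inherits(sm, "sws_score_matrix")) {
    labels <- sm$labels
  }
  y <- as.integer(labels)
  stopifnot(train_fraction > 0, train_fraction < 1,
            length(y) == nrow(x))
  results <- lapply(seeds, function(s) {
    te <- .holdout_test_idx(y, train_fraction, s)
    r <- .fit_predict(spec, x[-te, , drop = FALSE], y[-te],
                      x[te, , drop = FALSE])
    cc <- .confusion_from(y[te], r$class)
    structure(
      list(accuracy = accuracy(cc), mcc = mcc(cc),
           roc_auc = .roc_auc(y[te], r$score), confusion = cc,
           split = list(type = "holdout", seed = s,
                        train_fraction = train_fraction)),
      class = "eval_result"
    )
  })
  metric <- function(name) vapply(results, `[[`, numeric(1L), name)
  list(
    results = results,
    box = list(accuracy = box_summary(metric("accuracy")),
               mcc = box_summary(metric("mcc")),
               roc_auc = box_summary(metric("roc_auc")))
  )
}

# stratified test indices; guarantees at least one test member per class
.holdout_test_idx <- function(y, train_fraction, seed) {
  idx <- .with_seed(seed, {
    unlist(lapply(unique(y), function(cl) {
      members <- which(y == cl)
      n_test <- max(1L, round(length(members) * (1 - train_fraction)))
      sample(members, n_test)
    }))
  })
  sort(idx)
}
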