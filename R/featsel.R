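# Feature ranking and subset selection over a score matrix: chi-square
# ranking after equal-frequency discretization, greedy-forward wrapper
# search scored by random-forest cross-validation, and recursive backward
# elimination.

#' Chi-square feature ranking
#'
#' Each continuous feature is discretized into at most `n_bins`
#' equal-frequency bins (type-1 quantile breaks, so the ranking is
#' invariant under strictly monotone transforms of a feature), then scored
#' by the chi-square statistic (no continuity correction) of the bin x
#' class contingency table. Constant features score 0. Ties keep original
#' column order.
#'
#' @param sm An `sws_score_matrix` or numeric matrix.
#' @param labels 0/1 vector aligned to rows (from `sm` when `NULL`).
#' @param n_bins Number of equal-frequency bins (>= 2).
#' @return `data.frame` of class `feature_ranking` with columns `rank`,
#'   `motif_id`, `score`, ordered by decreasing score.
#' @export
chi2_rank <- function(sm, labels = NULL, n_bins = 10L) {
  x <- if (inherits(sm, "sws_score_matrix")) sm$scores else as.matrix(sm)
  if (is.null(labels) && inherits(sm, "sws_score_matrix")) {
    labels <- sm$labels
  }
  y <- as.integer(labels)
  stopifnot(n_bins >= 2L, length(y) == nrow(x))
  if (length(unique(y)) < 2L) stop("need two classes", call. = FALSE)
  scores <- apply(x, 2L, .chi2_feature, y = y, n_bins = n_bins)
  ord <- order(-scores)  # stable: ties keep column order
  out <- data.frame(rank = seq_along(ord),
                    motif_id = colnames(x)[ord],
                    score = scores[ord], row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("feature_ranking", "data.frame")
  attr(out, "method") <- "chi2"
  out
}

.chi2_feature <- function(v, y, n_bins) {
  breaks <- unique(stats::quantile(v, probs = seq_len(n_bins - 1L) / n_bins,
                                   type = 1L, names = FALSE))
  bin <- findInterval(v, breaks, left.open = TRUE)
  tab <- table(bin, y)
  if (nrow(tab) < 2L) return(0)
  as.numeric(suppressWarnings(
    stats::chisq.test(tab, correct = FALSE))$statistic)
}

# CV accuracy of a feature subset, deterministic: the same fold assignment
# (from `seed`) and the same training seed are used for every subset
.subset_objective <- function(x, y, cols, spec, folds, seed) {
  if (length(cols) == 0L) return(max(table(y)) / length(y))
  cross_validate(x[, cols, drop = FALSE], y, spec = spec,
                 folds = folds, seed = seed)$accuracy
}

#' Wrapper feature selection with a random-forest evaluator
#'
#' Greedy forward best-first search over feature subsets. Each candidate
#' subset is scored by stratified `folds`-fold cross-validated accuracy of
#' a seeded random forest; the search expands the best single-feature
#' addition at every step and stops after `stall_limit` consecutive
#' non-improving expansions (or when all features are included). The empty
#' set's objective is the majority-class fraction.
#'
#' @param sm An `sws_score_matrix` or numeric matrix (>= 2 features).
#' @param labels 0/1 vector aligned to rows.
#' @param seed Integer seed for fold assignment and forest training.
#' @param folds CV folds for the evaluator.
#' @param stall_limit Consecutive non-improving expansions tolerated.
#' @param spec Evaluating classifier (default random forest).
#' @return Object of class `feature_subset`: list with `selected` (motif
#'   ids), `objective`, and `trace` (data.frame of evaluated subsets).
#' @export
wrapper_rf_select <- function(sm, labels = NULL, seed = 1L, folds = 5L,
                              stall_limit = 5L,
                              spec = classifier_spec("rf", seed = seed)) {
  x <- if (inherits(sm, "sws_score_matrix")) sm$scores else as.matrix(sm)
  if (is.null(labels) && inherits(sm, "sws_score_matrix")) {
    labels <- sm$labels
  }
  y <- as.integer(labels)
  stopifnot(ncol(x) >= 2L, length(y) == nrow(x))
  if (min(table(y)) < folds) {
    stop("smallest class has fewer members than folds", call. = FALSE)
  }
  cols <- colnames(x)
  current <- character(0)
  best_set <- current
  best_obj <- .subset_objective(x, y, current, spec, folds, seed)
  trace <- list(list(subset = current, objective = best_obj))
  stall <- 0L
  while (length(current) < length(cols)) {
    candidates <- setdiff(cols, current)
    objs <- vapply(candidates, function(f) {
      .subset_objective(x, y, c(current, f), spec, folds, seed)
    }, numeric(1L))
    pick <- which.max(objs)  # ties: first candidate in column order
    current <- c(current, candidates[pick])
    obj <- objs[pick]
    trace[[length(trace) + 1L]] <- list(subset = current, objective = obj)
    if (obj > best_obj) {
      best_obj <- obj
      best_set <- current
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall > stall_limit) break
    }
  }
  # stall_limit = 0 with no improving first step still reports the best
  # single expansion evaluated
  if (length(best_set) == 0L && length(trace) > 1L) {
    objs1 <- vapply(trace[-1L], `[[`, numeric(1L), "objective")
    best_set <- trace[[which.max(objs1) + 1L]]$subset
    best_obj <- max(objs1)
  }
  .feature_subset(best_set, best_obj, trace, "wrapper", seed)
}

.feature_subset <- function(selected, objective, trace, method, seed) {
  tr <- data.frame(
    size = vapply(trace, function(t) length(t$subset), integer(1L)),
    subset = vapply(trace, function(t) paste(t$subset, collapse = ","),
                    character(1L)),
    objective = vapply(trace, `[[`, numeric(1L), "objective"),
    stringsAsFactors = FALSE
  )
  structure(list(selected = selected, objective = objective, trace = tr,
                 method = method, seed = seed),
            class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  cat(sprintf("feature_subset (%s, seed %d): %d feature(s), objective %.4f\n",
              x$method, x$seed, length(x$selected), x$objective))
  if (length(x$selected)) cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Recursive backward elimination
#'
#' Starting from `start_set`, repeatedly removes the feature whose removal
#' yields the highest cross-validated accuracy, accepting a removal when
#' that accuracy is at least the current one (so redundant duplicates are
#' pruned); stops when every removal strictly decreases accuracy or a
#' single feature remains. Ties among removals drop the highest-index
#' column, keeping the earliest.
#'
#' @param sm An `sws_score_matrix` or numeric matrix.
#' @param labels 0/1 vector aligned to rows.
#' @param start_set Character vector of motif ids to start from (default
#'   all columns).
#' @param spec Evaluating classifier.
#' @param folds CV folds.
#' @param seed Integer seed.
#' @return A `feature_subset`.
#' @export
backward_eliminate <- function(sm, labels = NULL, start_set = NULL,
                               spec = classifier_spec("rf", seed = seed),
                               folds = 5L, seed = 1L) {
  x <- if (inherits(sm, "sws_score_matrix")) sm$scores else as.matrix(sm)
  if (is.null(labels) && inherits(sm, "sws_score_matrix")) {
    labels <- sm$labels
  }
  y <- as.integer(labels)
  if (is.null(start_set)) start_set <- colnames(x)
  stopifnot(length(start_set) >= 1L, all(start_set %in% colnames(x)))
  current <- start_set
  obj <- .subset_objective(x, y, current, spec, folds, seed)
  trace <- list(list(subset = current, objective = obj))
  while (length(current) > 1L) {
    objs <- vapply(seq_along(current), function(i) {
      .subset_objective(x, y, current[-i], spec, folds, seed)
    }, numeric(1L))
    best <- max(objs)
    if (best < obj) break
    drop_i <- max(which(objs == best))  # tie: drop the later column
    current <- current[-drop_i]
    obj <- best
    trace[[length(trace) + 1L]] <- list(subset = current, objective = obj)
  }
  .feature_subset(current, obj, trace, "backward", seed)
}
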