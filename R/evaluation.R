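# Confusion-matrix metrics and the three validation protocols:
# stratified k-fold cross-validation, the small-family one-member-test
# split, and the cumulative training-size sweep.
#
# Metrics are on the percent scale:
#   SE  = 100 * TP / (TP + FN)
#   SP  = 100 * TN / (TN + FP)
#   Acc = 100 * (TP + TN) / (TP + FP + TN + FN)
# A zero denominator raises a typed signal rather than returning 0, since a
# silent zero would corrupt averages.

#' Multiclass confusion matrix
#'
#' @param truth character vector of true family labels.
#' @param predicted character vector of predicted labels, same length.
#' @param labels label set defining row/column order (default: sorted union).
#' @return integer matrix, rows = true families, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted,
                             labels = sort_c(unique(c(truth, predicted)))) {
  if (length(truth) != length(predicted)) {
    abort_parameter("`truth` and `predicted` must have the same length")
  }
  as.matrix(table(factor(truth, levels = labels),
                  factor(predicted, levels = labels)))
}

#' Reduce a multiclass confusion matrix to one-vs-rest counts
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @param family the family treated as positive.
#' @return list with integer `TP`, `FP`, `TN`, `FN`.
#' @export
one_vs_rest_counts <- function(cm, family) {
  if (!family %in% rownames(cm)) {
    abort_parameter(sprintf("family '%s' not in the confusion matrix", family))
  }
  tp <- cm[family, family]
  fn <- sum(cm[family, ]) - tp
  fp <- sum(cm[, family]) - tp
  tn <- sum(cm) - tp - fn - fp
  list(TP = unname(tp), FP = unname(fp), TN = unname(tn), FN = unname(fn))
}

#' Sensitivity, specificity and accuracy from binary counts
#'
#' @param TP,FP,TN,FN non-negative counts (or pass a list from
#'   [one_vs_rest_counts()] as `TP`).
#' @param which metrics to compute; any of `"SE"`, `"SP"`, `"Acc"`.
#' @return named numeric vector on the percent scale.
#' @export
binary_metrics <- function(TP, FP = NULL, TN = NULL, FN = NULL,
                           which = c("SE", "SP", "Acc")) {
  if (is.list(TP)) {
    counts <- TP
    TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  }
  which <- match.arg(which, several.ok = TRUE)
  if (any(c(TP, FP, TN, FN) < 0)) {
    abort_parameter("confusion counts must be non-negative")
  }
  out <- numeric(0L)
  if ("SE" %in% which) {
    if (TP + FN == 0) abort_undefined_metric("SE undefined: no positive examples (TP + FN = 0)")
    out <- c(out, SE = 100 * TP / (TP + FN))
  }
  if ("SP" %in% which) {
    if (TN + FP == 0) abort_undefined_metric("SP undefined: no negative examples (TN + FP = 0)")
    out <- c(out, SP = 100 * TN / (TN + FP))
  }
  if ("Acc" %in% which) {
    if (TP + FP + TN + FN == 0) abort_undefined_metric("Acc undefined: no examples")
    out <- c(out, Acc = 100 * (TP + TN) / (TP + FP + TN + FN))
  }
  out
}

#' Overall accuracy of a multiclass confusion matrix
#'
#' @param cm confusion matrix.
#' @return percent of on-diagonal predictions.
#' @export
overall_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) abort_undefined_metric("accuracy undefined: no examples")
  100 * sum(diag(cm)) / total
}

# Fold construction -----------------------------------------------------------

#' Stratified k-fold partition
#'
#' Partitions indices into k disjoint folds covering the dataset, with
#' overall fold sizes differing by at most 1 and each family's per-fold
#' counts differing by at most 1. Families are processed in sorted order
#' and each family's surplus members go to the currently smallest folds, so
#' the same seed always yields the same partition.
#'
#' @param y character vector of family labels.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return list of k integer vectors of test indices.
#' @export
stratified_kfold <- function(y, k = 5L, seed = 42L) {
  k <- check_count(k, "k", min = 2L)
  seed <- check_seed(seed)
  y <- as.character(y)
  fams <- sort_c(unique(y))
  small <- fams[vapply(fams, function(f) sum(y == f), integer(1L)) < k]
  if (length(small)) {
    abort_precondition(sprintf(
      "famil%s %s ha%s fewer than k = %d members; use small_family_split()",
      if (length(small) == 1L) "y" else "ies",
      paste(utils::head(small, 5L), collapse = ", "),
      if (length(small) == 1L) "s" else "ve", k))
  }
  folds <- vector("list", k)
  sizes <- integer(k)
  maybe_with_seed(seed, {
    for (f in fams) {
      idx <- sample(which(y == f))
      n <- length(idx)
      per <- rep(n %/% k, k)
      extra <- n %% k
      if (extra > 0L) {
        grow <- order(sizes, seq_len(k))[seq_len(extra)]
        per[grow] <- per[grow] + 1L
      }
      chunk <- rep(seq_len(k), per)
      for (j in seq_len(k)) folds[[j]] <- c(folds[[j]], idx[chunk == j])
      sizes <- sizes + per
    }
  })
  lapply(folds, sort)
}

#' Train/test split honouring very small families
#'
#' Families with at least k members contribute a stratified 1/k fraction to
#' the test side; families with fewer than k members contribute exactly one
#' randomly chosen member, the rest going to training. This is the protocol
#' that lets families with as few as 2 members be evaluated at all.
#'
#' @param y character vector of family labels; every family needs >= 2
#'   members.
#' @param k reference fold count (default 5).
#' @param seed integer seed.
#' @return list with integer vectors `train` and `test`.
#' @export
small_family_split <- function(y, k = 5L, seed = 42L) {
  k <- check_count(k, "k", min = 2L)
  seed <- check_seed(seed)
  y <- as.character(y)
  fams <- sort_c(unique(y))
  singleton <- fams[vapply(fams, function(f) sum(y == f), integer(1L)) < 2L]
  if (length(singleton)) {
    abort_precondition(sprintf(
      "famil%s %s ha%s a single member and cannot appear on both sides of a split",
      if (length(singleton) == 1L) "y" else "ies",
      paste(utils::head(singleton, 5L), collapse = ", "),
      if (length(singleton) == 1L) "s" else "ve"))
  }
  test <- integer(0L)
  maybe_with_seed(seed, {
    for (f in fams) {
      idx <- which(y == f)
      n_test <- if (length(idx) >= k) max(1L, floor(length(idx) / k)) else 1L
      test <- c(test, sample(idx, n_test))
    }
  })
  test <- sort(test)
  list(train = setdiff(seq_along(y), test), test = test)
}

# Cross-validation ------------------------------------------------------------

new_cv_report <- function(folds_df, confusion, labels, k, cost, seed, types) {
  per_family <- do.call(rbind, lapply(labels, function(f) {
    counts <- one_vs_rest_counts(confusion, f)
    data.frame(family = f,
               n = counts$TP + counts$FN,
               SE = binary_metrics(counts, which = "SE"),
               SP = binary_metrics(counts, which = "SP"),
               row.names = NULL)
  }))
  structure(
    list(folds = folds_df,
         mean_accuracy = 100 * sum(diag(confusion)) / sum(confusion),
         confusion = confusion,
         per_family = per_family,
         k = k, cost = cost, seed = seed, types = types),
    class = "cv_report"
  )
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Featurizes the dataset once, builds a stratified partition, and for each
#' fold trains a one-vs-all model on the remaining k - 1 folds and predicts
#' the held-out fold. The mean accuracy is the example-weighted mean of the
#' fold accuracies (equivalently, the pooled accuracy). Per-family SE/SP
#' are computed from the pooled confusion matrix.
#'
#' @param ds labeled `mir_seqs` data.frame (every family with >= k members).
#' @param vocab an `ngram_vocab` (default: types 1-4).
#' @param cost SVM trade-off parameter (default 1).
#' @param k number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return a `cv_report`: per-fold accuracies, pooled mean accuracy,
#'   pooled confusion matrix, per-family SE/SP, and the run configuration.
#' @export
cross_validate <- function(ds, vocab = build_vocabulary(), cost = 1,
                           k = 5L, seed = 42L) {
  stopifnot(inherits(ds, "mir_seqs"))
  if (anyNA(ds$family)) {
    abort_parameter("cross-validation requires every sequence to be labeled")
  }
  fd <- featurize_dataset(ds, vocab)
  folds <- stratified_kfold(fd$y, k = k, seed = seed)
  # leakage guard: every index appears in exactly one test fold
  stopifnot(identical(sort(unlist(folds)), seq_len(nrow(ds))))
  labels <- sort_c(unique(fd$y))
  confusion <- matrix(0L, length(labels), length(labels),
                      dimnames = list(labels, labels))
  folds_df <- data.frame(fold = seq_along(folds), n_test = lengths(folds),
                         accuracy = NA_real_)
  for (j in seq_along(folds)) {
    test <- folds[[j]]
    model <- train_classifier(fd$X[-test, , drop = FALSE], fd$y[-test],
                              cost = cost, vocab = vocab)
    pred <- predict_batch(model, fd$X[test, , drop = FALSE])
    cm <- confusion_matrix(fd$y[test], pred, labels = labels)
    confusion <- confusion + cm
    folds_df$accuracy[j] <- overall_accuracy(cm)
  }
  new_cv_report(folds_df, confusion, labels, k, cost, seed, vocab$types)
}

#' Evaluate a single train/test split of the full pipeline
#'
#' Used with [small_family_split()] for datasets containing families too
#' small for k-fold cross-validation.
#'
#' @param ds labeled `mir_seqs` data.frame.
#' @param split list with `train` and `test` index vectors.
#' @param vocab an `ngram_vocab`.
#' @param cost SVM trade-off parameter.
#' @param seed seed recorded in the report (the split carries its own).
#' @return a `cv_report` with a single fold.
#' @export
evaluate_split <- function(ds, split, vocab = build_vocabulary(), cost = 1,
                           seed = NA_integer_) {
  stopifnot(inherits(ds, "mir_seqs"))
  fd <- featurize_dataset(ds, vocab)
  model <- train_classifier(fd$X[split$train, , drop = FALSE],
                            fd$y[split$train], cost = cost, vocab = vocab)
  pred <- predict_batch(model, fd$X[split$test, , drop = FALSE])
  labels <- sort_c(unique(fd$y))
  cm <- confusion_matrix(fd$y[split$test], pred, labels = labels)
  folds_df <- data.frame(fold = 1L, n_test = length(split$test),
                         accuracy = overall_accuracy(cm))
  new_cv_report(folds_df, cm, labels, k = 1L, cost = cost, seed = seed,
                types = vocab$types)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d fold(s), mean accuracy %.2f%%\n",
              nrow(x$folds), x$mean_accuracy))
  print(transform(x$folds, accuracy = round(accuracy, 2)))
  invisible(x)
}

#' Export a cross-validation report
#'
#' Writes the per-fold table as CSV and a JSON summary carrying the full
#' configuration (seed, vocabulary types, cost) plus per-family metrics.
#'
#' @param report a `cv_report`.
#' @param csv_path,json_path output paths (either may be NULL to skip).
#' @return invisibly, a list of the paths written.
#' @export
write_cv_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "cv_report"))
  if (!is.null(csv_path)) {
    utils::write.csv(report$folds, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(mean_accuracy = report$mean_accuracy,
           folds = report$folds,
           per_family = report$per_family,
           k = report$k, cost = report$cost, seed = report$seed,
           ngram_types = sort(report$types)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(csv = csv_path, json = json_path))
}

# Training-size sweep ----------------------------------------------------------

#' Accuracy as a function of the training-set size
#'
#' The dataset is cut into ten stratified parts; for each requested
#' fraction f in {0.1, ..., 0.5} the first 10 f parts (cumulative, so each
#' round's training set contains the previous one) form the training set
#' and the remaining parts the test set.
#'
#' @param ds labeled `mir_seqs` data.frame; every family needs >= 10
#'   members.
#' @param vocab an `ngram_vocab`.
#' @param cost SVM trade-off parameter.
#' @param fractions subset of {0.1, 0.2, 0.3, 0.4, 0.5}.
#' @param seed integer seed for the partition.
#' @return data.frame with columns `fraction`, `n_train`, `n_test`,
#'   `accuracy`.
#' @export
training_size_sweep <- function(ds, vocab = build_vocabulary(), cost = 1,
                                fractions = seq(0.1, 0.5, by = 0.1),
                                seed = 42L) {
  stopifnot(inherits(ds, "mir_seqs"))
  n_parts <- vapply(fractions, function(f) f * 10, numeric(1L))
  if (any(abs(n_parts - round(n_parts)) > 1e-9) ||
      any(round(n_parts) < 1L) || any(round(n_parts) > 5L)) {
    abort_parameter("`fractions` must be multiples of 0.1 between 0.1 and 0.5")
  }
  n_parts <- as.integer(round(n_parts))
  fd <- featurize_dataset(ds, vocab)
  parts <- stratified_kfold(fd$y, k = 10L, seed = seed)
  out <- data.frame(fraction = fractions, n_train = NA_integer_,
                    n_test = NA_integer_, accuracy = NA_real_)
  for (i in seq_along(fractions)) {
    train <- sort(unlist(parts[seq_len(n_parts[i])]))
    test <- setdiff(seq_len(nrow(ds)), train)
    model <- train_classifier(fd$X[train, , drop = FALSE], fd$y[train],
                              cost = cost, vocab = vocab)
    pred <- predict_batch(model, fd$X[test, , drop = FALSE])
    cm <- confusion_matrix(fd$y[test], pred,
                           labels = sort_c(unique(fd$y)))
    out$n_train[i] <- length(train)
    out$n_test[i] <- length(test)
    out$accuracy[i] <- overall_accuracy(cm)
  }
  out
}
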