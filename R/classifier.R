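# One-vs-all linear max-margin family classifier.
#
# For M families, M binary soft-margin linear SVMs are fitted: classifier i
# uses the members of family i as positives and every other sequence as
# negatives. Each fit is reduced to an explicit linear decision function
# F_i(x) = w_i . x + b_i oriented so that larger values mean "more like
# family i". A query is assigned to argmax_i F_i(x); exact ties go to the
# lexicographically smallest label so predictions are reproducible.
#
# No per-feature rescaling is applied before fitting: the concentration
# weighting of the embedding is the intended feature scaling, and
# standardization would silently undo it.

#' Train a one-vs-all linear family classifier
#'
#' @param X numeric feature matrix (rows = sequences).
#' @param y character vector of family labels aligned with the rows of `X`.
#' @param cost positive trade-off between training error and margin
#'   (the SVM C parameter; default 1).
#' @param vocab optional `ngram_vocab` the features were built with; when
#'   given, its signature (types, dimension) is recorded in the model and
#'   verified at prediction and load time.
#' @return an object of class `family_model`: `labels` (sorted), `W`
#'   (M x l weight matrix), `b` (M intercepts), `cost`, `l`, `vocab_types`.
#' @export
train_classifier <- function(X, y, cost = 1, vocab = NULL) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) != length(y)) {
    abort_parameter("`X` rows and `y` must have the same length")
  }
  if (anyNA(y)) {
    abort_parameter("all training sequences must carry a family label")
  }
  if (!is.numeric(cost) || length(cost) != 1L || is.na(cost) || cost <= 0) {
    abort_parameter("`cost` must be a single positive number")
  }
  labels <- sort_c(unique(as.character(y)))
  if (length(labels) < 2L) {
    abort_training("training requires at least 2 distinct families")
  }
  if (!is.null(vocab)) {
    stopifnot(inherits(vocab, "ngram_vocab"))
    if (ncol(X) != vocab$length) {
      abort_compatibility(sprintf(
        "feature matrix has %d columns but vocabulary has %d dimensions",
        ncol(X), vocab$length))
    }
  }
  l <- ncol(X)
  W <- matrix(0, nrow = length(labels), ncol = l,
              dimnames = list(labels, colnames(X)))
  b <- stats::setNames(numeric(length(labels)), labels)
  for (i in seq_along(labels)) {
    yy <- factor(ifelse(y == labels[i], "pos", "neg"), levels = c("pos", "neg"))
    fit <- e1071::svm(X, yy, kernel = "linear", cost = cost, scale = FALSE)
    w <- drop(crossprod(fit$coefs, fit$SV))
    rho <- fit$rho
    # libsvm orients the decision value toward the class of the first
    # training example; flip when that class is the negative one
    if (fit$levels[fit$labels[1L]] != "pos") {
      w <- -w
      rho <- -rho
    }
    W[i, ] <- w
    b[i] <- -rho
  }
  structure(
    list(labels = labels, W = W, b = b, cost = cost, l = l,
         vocab_types = if (is.null(vocab)) NULL else sort(vocab$types)),
    class = "family_model"
  )
}

check_probe <- function(model, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$l) {
    abort_compatibility(sprintf(
      "query has %d feature dimensions but the model was trained with %d",
      ncol(X), model$l))
  }
  X
}

#' Per-family decision values
#'
#' @param model a `family_model`.
#' @param X a feature vector or matrix.
#' @return numeric matrix (rows = queries, columns = families) of
#'   F_i(x) = w_i . x + b_i.
#' @export
decision_values <- function(model, X) {
  X <- check_probe(model, X)
  sweep(X %*% t(model$W), 2L, model$b, `+`)
}

#' Predict the family of one sequence vector
#'
#' Assigns the query to the family with the largest decision value; exact
#' ties are broken toward the lexicographically smallest label.
#'
#' @param model a `family_model`.
#' @param x a feature vector of length `model$l`.
#' @return list with `label` (character) and `decision_values` (named
#'   numeric vector over all families).
#' @export
predict_family <- function(model, x) {
  dec <- decision_values(model, x)[1L, ]
  # labels are stored sorted, and which.max returns the first maximum,
  # so ties resolve to the lexicographically smallest label
  list(label = model$labels[which.max(dec)],
       decision_values = stats::setNames(dec, model$labels))
}

#' Predict families for a batch of sequence vectors
#'
#' @param model a `family_model`.
#' @param X feature matrix (rows = queries); may have zero rows.
#' @return character vector of predicted labels, in row order.
#' @export
predict_batch <- function(model, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (nrow(X) == 0L) return(character(0L))
  dec <- decision_values(model, X)
  model$labels[apply(dec, 1L, which.max)]
}

#' @export
predict.family_model <- function(object, newdata,
                                 type = c("label", "decision"), ...) {
  type <- match.arg(type)
  if (type == "label") predict_batch(object, newdata)
  else decision_values(object, newdata)
}

#' @export
print.family_model <- function(x, ...) {
  cat(sprintf("<family_model> %d families, %d features, cost = %g\n",
              length(x$labels), x$l, x$cost))
  if (!is.null(x$vocab_types)) {
    cat("vocabulary types:", paste(x$vocab_types, collapse = ","), "\n")
  }
  invisible(x)
}

# Persistence -----------------------------------------------------------------

MODEL_MAGIC <- "mirgram_family_model"
MODEL_VERSION <- 1L

#' Save a family model to a self-describing JSON file
#'
#' @param model a `family_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "family_model"))
  payload <- list(
    format = MODEL_MAGIC,
    version = MODEL_VERSION,
    labels = model$labels,
    W = lapply(seq_len(nrow(model$W)), function(i) unname(model$W[i, ])),
    b = unname(model$b),
    cost = model$cost,
    l = model$l,
    vocab_types = model$vocab_types
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a family model saved by [save_model()]
#'
#' @param path path to the model file.
#' @return a `family_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("model file not found: %s", path))
  }
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) abort_format(sprintf("cannot parse model file %s: %s",
                                             path, conditionMessage(e)))
  )
  if (!identical(payload$format, MODEL_MAGIC)) {
    abort_format(sprintf("%s is not a mirgram model file", path))
  }
  if (!identical(as.integer(payload$version), MODEL_VERSION)) {
    abort_compatibility(sprintf("unsupported model format version %s",
                                payload$version))
  }
  W <- if (is.matrix(payload$W)) payload$W else do.call(rbind, lapply(payload$W, as.numeric))
  if (is.null(W) || ncol(W) != payload$l || length(payload$b) != nrow(W) ||
      length(payload$labels) != nrow(W)) {
    abort_format(sprintf("model file %s is truncated or corrupt", path))
  }
  rownames(W) <- payload$labels
  structure(
    list(labels = payload$labels, W = W,
         b = stats::setNames(as.numeric(payload$b), payload$labels),
         cost = payload$cost, l = as.integer(payload$l),
         vocab_types = if (length(payload$vocab_types)) as.integer(payload$vocab_types) else NULL),
    class = "family_model"
  )
}

#' Check that a model matches a vocabulary
#'
#' @param model a `family_model`.
#' @param vocab an `ngram_vocab`.
#' @return `TRUE`, invisibly; signals a compatibility error on mismatch.
#' @export
check_model_vocab <- function(model, vocab) {
  stopifnot(inherits(model, "family_model"), inherits(vocab, "ngram_vocab"))
  if (model$l != vocab$length ||
      (!is.null(model$vocab_types) &&
       !identical(model$vocab_types, sort(vocab$types)))) {
    abort_compatibility(sprintf(
      "model was trained with types {%s} (%d dims) but vocabulary is types {%s} (%d dims)",
      paste(model$vocab_types, collapse = ","), model$l,
      paste(sort(vocab$types), collapse = ","), vocab$length))
  }
  invisible(TRUE)
}
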