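# n-gram vocabulary, sliding-window counting and concentration-weighted
# feature vectors.
#
# A sequence is embedded in a fixed vector space whose dimensions are all
# unique n-grams of the selected types (type n = all length-n words over
# A/C/G/U, so 4^n of them). With the default types {1,2,3,4} the space has
# 4 + 16 + 64 + 256 = 340 dimensions. Within a vector the blocks are laid
# out from the longest type down to unigrams; inside a block grams are in
# lexicographic order over A < C < G < U.
#
# The concentration factor of type i,
#     C_i = 4^i / sum_k 4^k   (sum over the selected types),
# weights each type's relative frequencies, so longer (more informative)
# grams outweigh shorter ones. The feature value of gram j of type i is
#     C_i * t_j / T_i,
# where t_j is the sliding-window occurrence count of gram j and T_i the
# total count of type-i windows. When every selected type has at least one
# countable window the entries of a feature vector sum to exactly 1.

RNA_BASES <- c("A", "C", "G", "U")

all_grams <- function(n) {
  g <- RNA_BASES
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      # append the new base fastest so lexicographic order is preserved
      g <- as.vector(t(outer(g, RNA_BASES, paste0)))
    }
  }
  g
}

#' Build an n-gram vocabulary
#'
#' Fixes the feature-space layout: types are ordered longest first and grams
#' lexicographically (A < C < G < U) within a type. Concentrations are
#' normalized over the selected types, so restricted runs (e.g. types 1-3)
#' are self-normalizing.
#'
#' @param types integer vector of n-gram sizes, each in 1..8. Default
#'   `c(1, 2, 3, 4)`: unigrams through tetragrams, a 340-dimensional space.
#' @return an object of class `ngram_vocab` with elements `types` (sorted
#'   decreasing), `grams` (all dimension names in layout order),
#'   `concentrations` (named by type), `length`, and `blocks` (per-type
#'   index ranges into `grams`).
#' @export
build_vocabulary <- function(types = 1:4) {
  if (length(types) == 0L) {
    abort_parameter("`types` must contain at least one n-gram size")
  }
  if (!is.numeric(types) || anyNA(types) || any(types != floor(types)) ||
      any(types < 1L) || any(types > 8L)) {
    abort_parameter("n-gram sizes must be integers in 1..8")
  }
  types <- sort(unique(as.integer(types)), decreasing = TRUE)
  sizes <- as.integer(4^types)
  conc <- sizes / sum(sizes)
  grams_by_type <- lapply(types, all_grams)
  ends <- cumsum(sizes)
  blocks <- mapply(function(s, e) s:e, ends - sizes + 1L, ends, SIMPLIFY = FALSE)
  structure(
    list(
      types = types,
      grams = unlist(grams_by_type, use.names = FALSE),
      concentrations = stats::setNames(conc, types),
      length = as.integer(sum(sizes)),
      blocks = stats::setNames(blocks, types)
    ),
    class = "ngram_vocab"
  )
}

#' @export
print.ngram_vocab <- function(x, ...) {
  cat(sprintf("<ngram_vocab> types {%s}, %d dimensions\n",
              paste(sort(x$types), collapse = ","), x$length))
  cat("concentrations:",
      paste(sprintf("C_%s = %d/%d", names(x$concentrations),
                    4L^x$types, x$length), collapse = ", "), "\n")
  invisible(x)
}

# Sliding windows of size n over a single normalized sequence. Windows
# containing any letter outside A/C/G/U are dropped entirely: they count
# toward neither a gram nor the type total, which preserves the sum-to-1
# property in the presence of noise bases.
valid_windows <- function(bases, n) {
  L <- nchar(bases)
  if (L < n) return(character(0L))
  starts <- seq_len(L - n + 1L)
  w <- substring(bases, starts, starts + n - 1L)
  w[!grepl("[^ACGU]", w)]
}

#' Count sliding-window n-grams in one sequence
#'
#' A window of each selected size slides 5' to 3' along the sequence;
#' every window made solely of A/C/G/U increments its gram's count.
#' Windows containing any other letter are skipped and excluded from the
#' type total. Sequences shorter than n simply yield a zero total for
#' that type.
#'
#' @param bases a single normalized sequence (see [normalize_bases()]).
#' @param vocab an `ngram_vocab`.
#' @return an object of class `ngram_counts`: list with `counts` (per type,
#'   a named integer vector over encountered grams) and `totals` (named by
#'   type; equals sequence length - n + 1 for a fully valid sequence).
#' @export
count_ngrams <- function(bases, vocab) {
  stopifnot(inherits(vocab, "ngram_vocab"))
  if (!is.character(bases) || length(bases) != 1L) {
    abort_parameter("`bases` must be a single sequence string")
  }
  counts <- lapply(vocab$types, function(n) {
    w <- valid_windows(bases, n)
    if (length(w) == 0L) return(stats::setNames(integer(0L), character(0L)))
    tab <- table(w)
    stats::setNames(as.integer(tab), names(tab))
  })
  names(counts) <- vocab$types
  structure(
    list(counts = counts,
         totals = vapply(counts, sum, integer(1L))),
    class = "ngram_counts"
  )
}

#' Embed one sequence as a concentration-weighted feature vector
#'
#' The dimension of gram j of type i takes the value C_i * t_j / T_i (or
#' t_j / T_i when `weighted = FALSE`, the unweighted per-type relative
#' frequency used for comparison). A type with no countable window
#' contributes an all-zero block rather than an error, so degenerate inputs
#' do not crash batch runs.
#'
#' @param bases a single normalized sequence.
#' @param vocab an `ngram_vocab`.
#' @param weighted apply the concentration factor (default TRUE).
#' @return named numeric vector of length `vocab$length`; entries sum to 1
#'   whenever every selected type has at least one valid window (to 1e-9).
#' @export
featurize <- function(bases, vocab, weighted = TRUE) {
  nc <- count_ngrams(bases, vocab)
  v <- numeric(vocab$length)
  for (i in seq_along(vocab$types)) {
    n <- as.character(vocab$types[i])
    total <- nc$totals[[n]]
    if (total == 0L) next
    block <- vocab$blocks[[n]]
    t_j <- nc$counts[[n]]
    idx <- block[match(names(t_j), vocab$grams[block])]
    w <- if (weighted) vocab$concentrations[[n]] else 1
    v[idx] <- w * t_j / total
  }
  stats::setNames(v, vocab$grams)
}

#' Embed a sequence set as a feature matrix
#'
#' @param ds a non-empty `mir_seqs` data.frame.
#' @param vocab an `ngram_vocab`.
#' @param weighted apply the concentration factor (default TRUE).
#' @return list with `X` (numeric matrix, one row per sequence, rownames =
#'   ids, colnames = grams) and `y` (character vector of family labels,
#'   NA where unlabeled).
#' @export
featurize_dataset <- function(ds, vocab, weighted = TRUE) {
  stopifnot(inherits(ds, "mir_seqs"))
  if (nrow(ds) == 0L) {
    abort_empty("cannot featurize an empty sequence set")
  }
  X <- t(vapply(ds$bases, featurize, numeric(vocab$length),
                vocab = vocab, weighted = weighted, USE.NAMES = FALSE))
  dimnames(X) <- list(ds$id, vocab$grams)
  list(X = X, y = ds$family)
}

# Family centers and dispersion ----------------------------------------------

#' Mean feature vector of a family
#'
#' @param vectors a numeric matrix of feature vectors (one per row) or a
#'   list of equal-length numeric vectors.
#' @return the dimension-wise arithmetic mean.
#' @export
family_center <- function(vectors) {
  if (is.list(vectors)) {
    if (length(vectors) == 0L) abort_parameter("no vectors to average")
    vectors <- do.call(rbind, vectors)
  }
  if (!is.matrix(vectors) || nrow(vectors) == 0L) {
    abort_parameter("no vectors to average")
  }
  colMeans(vectors)
}

#' Euclidean distance between two family centers
#'
#' @param a,b equal-length numeric vectors.
#' @return non-negative scalar L2 distance.
#' @export
center_distance <- function(a, b) {
  if (length(a) != length(b)) {
    abort_parameter("center vectors must have equal length")
  }
  sqrt(sum((a - b)^2))
}

#' Per-dimension variance across family centers
#'
#' Population variance (divisor m, not m - 1) of each feature value across
#' the given centers; used to quantify how much a feature block separates
#' the families.
#'
#' @param centers numeric matrix with one center per row (>= 2 rows), or a
#'   list of equal-length vectors.
#' @return numeric vector of per-dimension variances.
#' @export
feature_variance_across_families <- function(centers) {
  if (is.list(centers)) centers <- do.call(rbind, centers)
  if (!is.matrix(centers) || nrow(centers) < 2L) {
    abort_parameter("need at least 2 family centers")
  }
  m <- colMeans(centers)
  colMeans(sweep(centers, 2L, m)^2)
}

#' Share of cross-family center variance captured by each n-gram type
#'
#' Computes family centers under both the concentration-weighted and the
#' unweighted (t_j / T_i) embeddings and reports, per type, the fraction of
#' total cross-family center variance carried by that type's block. The
#' weighting enhances the long-gram blocks at the expense of short ones,
#' which is what makes families more separable.
#'
#' @param ds a labeled `mir_seqs` data.frame with >= 2 families.
#' @param vocab an `ngram_vocab`.
#' @return data.frame with columns `type`, `share_unweighted`,
#'   `share_weighted`.
#' @export
weighting_variance_shares <- function(ds, vocab) {
  stopifnot(inherits(ds, "mir_seqs"))
  fams <- sort_c(unique(ds$family[!is.na(ds$family)]))
  if (length(fams) < 2L) {
    abort_parameter("need at least 2 labeled families")
  }
  share_of <- function(weighted) {
    fd <- featurize_dataset(ds, vocab, weighted = weighted)
    centers <- t(vapply(fams,
                        function(f) family_center(fd$X[fd$y == f, , drop = FALSE]),
                        numeric(vocab$length)))
    v <- feature_variance_across_families(centers)
    vapply(vocab$blocks, function(b) sum(v[b]), numeric(1L)) / sum(v)
  }
  data.frame(
    type = vocab$types,
    share_unweighted = unname(share_of(FALSE)),
    share_weighted = unname(share_of(TRUE))
  )
}

# Matrix export ---------------------------------------------------------------

#' Write a feature matrix as headered CSV
#'
#' Column names are the gram strings in vocabulary order.
#'
#' @param X feature matrix from [featurize_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(X, path) {
  utils::write.csv(as.data.frame(X), path, row.names = TRUE)
  invisible(path)
}

#' Write a feature matrix in sparse SVM-light format
#'
#' One line per row: `<label> <index>:<value> ...` with 1-based indices in
#' vocabulary order and zero entries omitted. Character labels are encoded
#' as their 1-based position in the sorted label set (0 for NA).
#'
#' @param X feature matrix.
#' @param y label vector aligned with the rows of `X` (may be NULL).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_svmlight <- function(X, y = NULL, path) {
  if (is.null(y)) y <- rep(NA_character_, nrow(X))
  if (is.numeric(y)) {
    codes <- y
  } else {
    lv <- sort_c(unique(y[!is.na(y)]))
    codes <- match(y, lv)
    codes[is.na(codes)] <- 0L
  }
  lines <- vapply(seq_len(nrow(X)), function(i) {
    nz <- which(X[i, ] != 0)
    paste(codes[i], paste(sprintf("%d:%.10g", nz, X[i, nz]), collapse = " "))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
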