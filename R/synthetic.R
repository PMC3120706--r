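# Synthetic sequence generators: every benchmark input the package needs
# can be produced in code, with all randomness derived from one integer
# seed so that repeated calls are byte-identical.
#
# Three constructions mirror the standard negative-control designs for
# alignment-free miRNA classification:
#   * reversed positives           (5'->3' reversal of a real/cloned family)
#   * composition-matched randoms  (i.i.d. sequences with the reference's
#                                   pooled mononucleotide frequencies)
#   * mutation-derived families    (members descend from a common ancestor
#                                   by i.i.d. substitutions and single-base
#                                   indels, emulating the shared-ancestor
#                                   structure of curated miRNA families)

#' Reverse sequences 5' to 3'
#'
#' Plain string reversal without complementation; ids gain a `_rev`
#' suffix. Reversal preserves length and base composition exactly, so the
#' reversed set is a composition-identical negative control that differs
#' only in higher-order (n >= 2) word usage.
#'
#' @param records a non-empty `mir_seqs` data.frame.
#' @param complement also complement the bases (A<->U, C<->G), giving the
#'   reverse complement instead; default FALSE.
#' @return a `mir_seqs` data.frame of reversed sequences (family unset).
#' @export
reverse_sequences <- function(records, complement = FALSE) {
  stopifnot(inherits(records, "mir_seqs"))
  if (nrow(records) == 0L) {
    abort_empty("no sequences to reverse")
  }
  rev1 <- function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  bases <- vapply(records$bases, rev1, character(1L), USE.NAMES = FALSE)
  if (complement) bases <- chartr("ACGU", "UGCA", bases)
  mir_seqs(paste0(records$id, "_rev"), bases)
}

#' Random sequences with matched base composition
#'
#' Draws `n` i.i.d. sequences whose bases follow the pooled A/C/G/U
#' frequencies of the reference set (letters outside A/C/G/U are ignored
#' when pooling) and whose lengths are uniform over the reference's length
#' range.
#'
#' @param reference a `mir_seqs` data.frame (or character vector of
#'   sequences) to match.
#' @param n number of sequences to generate.
#' @param seed integer seed (NULL = use the current RNG state).
#' @return a `mir_seqs` data.frame with ids `random_0001`, ... (family
#'   unset).
#' @export
random_matched_composition <- function(reference, n, seed = 42L) {
  if (inherits(reference, "mir_seqs")) reference <- reference$bases
  if (length(reference) == 0L) {
    abort_parameter("`reference` must contain at least one sequence")
  }
  n <- check_count(n, "n")
  seed <- check_seed(seed)
  pooled <- paste(reference, collapse = "")
  counts <- vapply(RNA_BASES, function(b)
    lengths(regmatches(pooled, gregexpr(b, pooled, fixed = TRUE))),
    integer(1L))
  if (sum(counts) == 0L) {
    abort_parameter("reference contains no A/C/G/U bases to match")
  }
  lens <- nchar(reference)
  maybe_with_seed(seed, {
    rng <- seq.int(min(lens), max(lens))
    out_len <- rng[sample.int(length(rng), n, replace = TRUE)]
    bases <- vapply(out_len, function(L)
      paste(sample(RNA_BASES, L, replace = TRUE, prob = counts), collapse = ""),
      character(1L))
    mir_seqs(sprintf("random_%04d", seq_len(n)), bases)
  })
}

#' Dinucleotide-preserving shuffle
#'
#' Shuffles each sequence while preserving its exact dinucleotide (and
#' hence mononucleotide) counts, via a random Eulerian walk on the
#' dinucleotide transition multigraph. A stricter null than i.i.d.
#' composition matching. Sequences containing letters outside A/C/G/U are
#' rejected.
#'
#' @param records a `mir_seqs` data.frame.
#' @param seed integer seed.
#' @return a `mir_seqs` data.frame of shuffled sequences, ids suffixed
#'   `_shuf`.
#' @export
shuffle_dinucleotide <- function(records, seed = 42L) {
  stopifnot(inherits(records, "mir_seqs"))
  seed <- check_seed(seed)
  if (any(grepl("[^ACGU]", records$bases))) {
    abort_parameter("dinucleotide shuffle requires pure A/C/G/U sequences")
  }
  shuffle1 <- function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    L <- length(ch)
    if (L < 3L) return(s)
    # random Eulerian walk over dinucleotide edges: retry until a walk
    # consumes every edge (start/end vertices make most attempts succeed)
    for (attempt in seq_len(1000L)) {
      succ <- split(ch[-1L], ch[-L])
      succ <- lapply(succ, sample)
      used <- stats::setNames(integer(length(succ)), names(succ))
      walk <- character(L)
      walk[1L] <- ch[1L]
      ok <- TRUE
      for (i in 2L:L) {
        v <- walk[i - 1L]
        k <- used[[v]] + 1L
        if (is.null(succ[[v]]) || k > length(succ[[v]])) { ok <- FALSE; break }
        walk[i] <- succ[[v]][k]
        used[[v]] <- k
      }
      if (ok) return(paste(walk, collapse = ""))
    }
    abort_parameter(sprintf("could not shuffle sequence of length %d", L))
  }
  maybe_with_seed(seed, {
    mir_seqs(paste0(records$id, "_shuf"),
             vapply(records$bases, shuffle1, character(1L), USE.NAMES = FALSE))
  })
}

# Mutation-derived families ----------------------------------------------------

mutate_seq <- function(ch, substitution_rate, indel_rate) {
  L <- length(ch)
  if (substitution_rate > 0) {
    hit <- stats::runif(L) < substitution_rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b)
        sample(setdiff(RNA_BASES, b), 1L), character(1L), USE.NAMES = FALSE)
    }
  }
  if (indel_rate > 0) {
    u <- stats::runif(L)
    del <- u < indel_rate / 2
    ins <- u >= indel_rate / 2 & u < indel_rate
    n_ins <- sum(ins)
    inserted <- if (n_ins) sample(RNA_BASES, n_ins, replace = TRUE) else character(0L)
    out <- vector("list", L)
    ii <- 0L
    for (p in seq_len(L)) {
      kept <- if (del[p]) character(0L) else ch[p]
      if (ins[p]) {
        ii <- ii + 1L
        kept <- c(kept, inserted[ii])
      }
      out[[p]] <- kept
    }
    ch <- unlist(out, use.names = FALSE)
  }
  ch
}

#' Generate mutation-derived synthetic families
#'
#' For each family one ancestor sequence is drawn from `base_composition`;
#' each member is an independent copy of the ancestor mutated base-wise
#' (substitution to a uniformly chosen different base with probability
#' `substitution_rate`; deletion or single-base insertion with probability
#' `indel_rate / 2` each). Defaults produce 10 families of 20 members from
#' 80 nt ancestors at 10% substitution and 2% indels — a mid-sized
#' benchmark with within-family identity comparable to a curated miRNA
#' family collection of similar scale.
#'
#' @param n_families number of families.
#' @param members_per_family members per family (scalar, or one per family).
#' @param ancestor_length ancestor length in nt.
#' @param substitution_rate per-base substitution probability in \[0, 1).
#' @param indel_rate per-base indel probability in \[0, 1).
#' @param base_composition probability 4-vector over A, C, G, U.
#' @param seed integer seed (NULL = use the current RNG state).
#' @return a labeled `mir_seqs` data.frame; families `fam_001`, ...
#' @export
generate_families <- function(n_families = 10L, members_per_family = 20L,
                              ancestor_length = 80L,
                              substitution_rate = 0.10, indel_rate = 0.02,
                              base_composition = c(A = 0.25, C = 0.25,
                                                   G = 0.25, U = 0.25),
                              seed = 42L) {
  n_families <- check_count(n_families, "n_families")
  ancestor_length <- check_count(ancestor_length, "ancestor_length")
  substitution_rate <- check_rate(substitution_rate, "substitution_rate")
  indel_rate <- check_rate(indel_rate, "indel_rate")
  seed <- check_seed(seed)
  members <- rep_len(vapply(members_per_family, check_count,
                            integer(1L), name = "members_per_family"),
                     n_families)
  if (length(base_composition) != 4L || any(base_composition < 0) ||
      abs(sum(base_composition) - 1) > 1e-9) {
    abort_parameter("`base_composition` must be 4 non-negative values summing to 1")
  }
  maybe_with_seed(seed, {
    rows <- lapply(seq_len(n_families), function(f) {
      ancestor <- sample(RNA_BASES, ancestor_length, replace = TRUE,
                         prob = base_composition)
      bases <- vapply(seq_len(members[f]), function(m)
        paste(mutate_seq(ancestor, substitution_rate, indel_rate),
              collapse = ""),
        character(1L))
      mir_seqs(sprintf("fam%03d_m%03d", f, seq_len(members[f])), bases,
               family = sprintf("fam_%03d", f))
    })
    out <- do.call(rbind, rows)
    class(out) <- c("mir_seqs", "data.frame")
    out
  })
}

#' Generate families from disjoint trigram pools
#'
#' Partitions the 64 trigrams into disjoint per-family pools and builds
#' each family's ancestor by concatenating trigrams drawn from its pool.
#' By construction the families differ strongly in trigram usage while
#' sharing the unigram alphabet — the setting in which concentration
#' weighting of long-gram blocks visibly improves separability.
#'
#' @param n_families number of families (<= 8 so pools stay disjoint).
#' @param members_per_family members per family.
#' @param n_triplets trigrams concatenated per ancestor (length = 3 x this).
#' @param pool_size trigrams per family pool (n_families x pool_size <= 64).
#' @param substitution_rate,indel_rate member mutation rates.
#' @param seed integer seed.
#' @return a labeled `mir_seqs` data.frame.
#' @export
trigram_pool_families <- function(n_families = 2L, members_per_family = 20L,
                                  n_triplets = 27L, pool_size = 8L,
                                  substitution_rate = 0, indel_rate = 0,
                                  seed = 42L) {
  n_families <- check_count(n_families, "n_families")
  members_per_family <- check_count(members_per_family, "members_per_family")
  n_triplets <- check_count(n_triplets, "n_triplets")
  pool_size <- check_count(pool_size, "pool_size")
  substitution_rate <- check_rate(substitution_rate, "substitution_rate")
  indel_rate <- check_rate(indel_rate, "indel_rate")
  seed <- check_seed(seed)
  if (n_families * pool_size > 64L) {
    abort_parameter("n_families x pool_size must not exceed the 64 trigrams")
  }
  trigrams <- all_grams(3L)
  maybe_with_seed(seed, {
    pools <- split(sample(trigrams)[seq_len(n_families * pool_size)],
                   rep(seq_len(n_families), each = pool_size))
    rows <- lapply(seq_len(n_families), function(f) {
      ancestor <- strsplit(paste(sample(pools[[f]], n_triplets, replace = TRUE),
                                 collapse = ""), "", fixed = TRUE)[[1L]]
      bases <- vapply(seq_len(members_per_family), function(m)
        paste(mutate_seq(ancestor, substitution_rate, indel_rate),
              collapse = ""),
        character(1L))
      mir_seqs(sprintf("pool%02d_m%03d", f, seq_len(members_per_family)),
               bases, family = sprintf("fam_%03d", f))
    })
    out <- do.call(rbind, rows)
    class(out) <- c("mir_seqs", "data.frame")
    out
  })
}

#' Ready-to-run benchmark datasets
#'
#' Emits the three benchmark designs used throughout:
#' \describe{
#'   \item{`single_family_reverse`}{one mutation-derived family (label
#'     `real`) versus its 5'->3' reversal (label `reversed`), balanced.}
#'   \item{`single_family_random`}{one family (label `real`) versus
#'     composition-matched random sequences (label `random`), balanced.}
#'   \item{`multi_family`}{`n_families` mutation-derived families.}
#' }
#' The binary designs default to 100 + 100 sequences at 5% substitution;
#' the multi-family design defaults to the [generate_families()] defaults.
#'
#' @param kind one of `"single_family_reverse"`, `"single_family_random"`,
#'   `"multi_family"`.
#' @param n_members members of the positive family (binary kinds).
#' @param substitution_rate,indel_rate mutation rates of the positive
#'   family (binary kinds).
#' @param n_families,members_per_family multi-family sizes.
#' @param ancestor_length ancestor length in nt.
#' @param seed integer seed governing the whole construction.
#' @return a labeled `mir_seqs` data.frame.
#' @export
make_benchmark <- function(kind = c("single_family_reverse",
                                    "single_family_random",
                                    "multi_family"),
                           n_members = 100L,
                           substitution_rate = 0.05, indel_rate = 0.02,
                           n_families = 10L, members_per_family = 20L,
                           ancestor_length = 80L, seed = 42L) {
  if (!is.character(kind) || !kind[1L] %in% c("single_family_reverse",
                                              "single_family_random",
                                              "multi_family")) {
    abort_parameter(sprintf("unknown benchmark kind '%s'", kind[1L]))
  }
  kind <- kind[1L]
  seed <- check_seed(seed)
  maybe_with_seed(seed, {
    if (kind == "multi_family") {
      return(generate_families(n_families = n_families,
                               members_per_family = members_per_family,
                               ancestor_length = ancestor_length,
                               substitution_rate = substitution_rate,
                               indel_rate = indel_rate, seed = NULL))
    }
    pos <- generate_families(n_families = 1L,
                             members_per_family = n_members,
                             ancestor_length = ancestor_length,
                             substitution_rate = substitution_rate,
                             indel_rate = indel_rate, seed = NULL)
    pos$family <- "real"
    neg <- if (kind == "single_family_reverse") {
      r <- reverse_sequences(pos)
      r$family <- "reversed"
      r
    } else {
      r <- random_matched_composition(pos, n = n_members, seed = NULL)
      r$family <- "random"
      r
    }
    out <- rbind(pos, neg)
    class(out) <- c("mir_seqs", "data.frame")
    out
  })
}
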