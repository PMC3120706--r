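# Reading, validating and writing RNA sequence sets and family-label tables.
#
# A sequence set is represented as a data.frame of class "mir_seqs" with
# columns:
#   id     character, unique, no whitespace
#   bases  character, upper-case RNA; T already converted to U; letters
#          outside {A,C,G,U} (IUPAC ambiguity codes, sequencing noise) are
#          retained verbatim and handled downstream by feature extraction
#   family character, NA when unknown

#' Normalize raw sequence text
#'
#' Upper-cases the sequence and converts every T to U, so that DNA-spelled
#' and RNA-spelled inputs map to the same feature vector. Idempotent.
#'
#' @param x character vector of raw sequences.
#' @return character vector of normalized sequences.
#' @export
normalize_bases <- function(x) {
  chartr("T", "U", toupper(x))
}

new_mir_seqs <- function(id, bases, family = NA_character_) {
  df <- data.frame(
    id = as.character(id),
    bases = as.character(bases),
    family = rep_len(as.character(family), length(id)),
    stringsAsFactors = FALSE
  )
  class(df) <- c("mir_seqs", "data.frame")
  df
}

#' Construct a sequence set
#'
#' Builds a validated sequence set from parallel vectors. Bases are
#' normalized (upper-case, T to U); ids must be unique and free of
#' whitespace; empty sequences are rejected.
#'
#' @param id character vector of sequence identifiers.
#' @param bases character vector of sequences.
#' @param family optional character vector of family labels (NA = unlabeled).
#' @return a `mir_seqs` data.frame with columns `id`, `bases`, `family`.
#' @export
mir_seqs <- function(id, bases, family = NA_character_) {
  if (length(id) != length(bases)) {
    abort_parameter("`id` and `bases` must have the same length")
  }
  id <- as.character(id)
  if (any(grepl("[[:space:]]", id))) {
    abort_format("sequence ids must not contain whitespace")
  }
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    abort_format(sprintf("duplicate sequence id(s): %s",
                         paste(utils::head(dup, 5L), collapse = ", ")))
  }
  bases <- normalize_bases(as.character(bases))
  empty <- id[!nzchar(bases)]
  if (length(empty)) {
    abort_format(sprintf("empty sequence for id(s): %s",
                         paste(utils::head(empty, 5L), collapse = ", ")))
  }
  new_mir_seqs(id, bases, family)
}

#' Read sequences from a FASTA file
#'
#' Headers are truncated at the first whitespace to form the id; bases are
#' normalized (upper-case, T to U). Letters outside A/C/G/U are retained so
#' that records with ambiguity codes or sequencing noise survive to feature
#' extraction. Family labels are left unset; see [read_family_table()].
#'
#' @param path path to a FASTA file.
#' @return a `mir_seqs` data.frame, one row per record in file order.
#' @export
read_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    abort_parameter("`path` must be a single file path")
  }
  if (!file.exists(path)) {
    abort_io(sprintf("FASTA file not found: %s", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort_format(sprintf("cannot parse FASTA %s: %s",
                                             path, conditionMessage(e)))
  )
  if (length(set) == 0L) {
    abort_empty(sprintf("no sequence records in %s", path))
  }
  ids <- sub("[[:space:]].*$", "", names(set))
  mir_seqs(ids, as.character(set))
}

#' Read a two-column id-to-family table
#'
#' Tab-separated, no header: column 1 is the sequence id, column 2 the family
#' label. Exact duplicate rows are tolerated; the same id mapped to two
#' different families is an error.
#'
#' @param path path to a TSV file.
#' @return named character vector mapping id to family label.
#' @export
read_family_table <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("family table not found: %s", path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    abort_empty(sprintf("no entries in family table %s", path))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    abort_format(sprintf("family table %s: line %d has %d column(s), expected 2",
                         path, lineno[bad[1L]], lengths(fields)[bad[1L]]))
  }
  ids <- vapply(fields, `[`, character(1L), 1L)
  fams <- vapply(fields, `[`, character(1L), 2L)
  first <- !duplicated(ids)
  conflict <- ids[!first][fams[!first] != fams[first][match(ids[!first], ids[first])]]
  if (length(conflict)) {
    abort_conflict(sprintf("conflicting family labels for id(s): %s",
                           paste(unique(conflict), collapse = ", ")))
  }
  stats::setNames(fams[first], ids[first])
}

#' Attach family labels to a sequence set
#'
#' Records whose id is absent from the mapping are dropped (with a warning
#' giving the count), which keeps the same reader usable for predict-only
#' workflows where only a subset is labeled.
#'
#' @param records a `mir_seqs` data.frame.
#' @param labels named character vector (id to family), as returned by
#'   [read_family_table()].
#' @return a labeled `mir_seqs` data.frame; the number of dropped records is
#'   available as `attr(x, "n_dropped")`.
#' @export
attach_labels <- function(records, labels) {
  stopifnot(inherits(records, "mir_seqs"))
  hit <- records$id %in% names(labels)
  n_dropped <- sum(!hit)
  if (!any(hit)) {
    abort_empty("no sequence id matches the label table")
  }
  if (n_dropped > 0L) {
    warning(sprintf("dropped %d record(s) without a family label", n_dropped),
            call. = FALSE)
  }
  out <- records[hit, , drop = FALSE]
  out$family <- unname(labels[out$id])
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("mir_seqs", "data.frame")
  out
}

#' Write a sequence set to FASTA
#'
#' Round-trip safe: reading the written file reproduces ids and bases
#' exactly. Lines are wrapped at 70 characters.
#'
#' @param records a non-empty `mir_seqs` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(inherits(records, "mir_seqs"))
  if (nrow(records) == 0L) {
    abort_empty("cannot write an empty sequence set")
  }
  set <- Biostrings::BStringSet(stats::setNames(records$bases, records$id))
  tryCatch(
    Biostrings::writeXStringSet(set, path, width = 70L),
    error = function(e) abort_io(sprintf("cannot write FASTA %s: %s",
                                         path, conditionMessage(e)))
  )
  invisible(path)
}

#' Write an id-to-family table
#'
#' @param records a labeled `mir_seqs` data.frame.
#' @param path output path (two-column TSV, readable by
#'   [read_family_table()]).
#' @return `path`, invisibly.
#' @export
write_family_table <- function(records, path) {
  stopifnot(inherits(records, "mir_seqs"))
  keep <- !is.na(records$family)
  if (!any(keep)) {
    abort_empty("no labeled records to write")
  }
  writeLines(paste(records$id[keep], records$family[keep], sep = "\t"), path)
  invisible(path)
}

#' @export
print.mir_seqs <- function(x, ...) {
  n_fam <- length(unique(x$family[!is.na(x$family)]))
  cat(sprintf("<mir_seqs> %d sequence(s), %d famil%s, lengths %d-%d nt\n",
              nrow(x), n_fam, if (n_fam == 1L) "y" else "ies",
              if (nrow(x)) min(nchar(x$bases)) else 0L,
              if (nrow(x)) max(nchar(x$bases)) else 0L))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more row(s)\n", nrow(x) - 6L))
  invisible(x)
}
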