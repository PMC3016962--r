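#' @title Controlled vocabularies and category distributions
#' @name vocab
#' @description Normalizes free-text tissue / stage / sex / strain values to
#'   controlled vocabularies and tallies category distributions. Matching is
#'   exact after canonicalization (lowercase, trim, underscores and runs of
#'   whitespace folded to single spaces); no fuzzy matching, so every mapping
#'   is auditable.
NULL

VOCAB_AXES <- c("tissue", "stage", "sex", "strain")

canon_key <- function(x) {
  x <- tolower(trimws(x))
  gsub("[_[:space:]]+", " ", x)
}

#' Construct a controlled vocabulary
#'
#' @param axis one of `"tissue"`, `"stage"`, `"sex"`, `"strain"`.
#' @param terms ordered character vector of canonical terms. The order is
#'   biological (e.g. developmental stages in temporal order) and is used
#'   for all downstream tables and figures.
#' @param synonyms named list: canonical term -> character vector of
#'   synonyms. Keys are matched case-, whitespace- and underscore-
#'   insensitively.
#' @param unknown_label label assigned to empty or unmapped values.
#' @return An object of class `est_vocabulary`.
#' @export
vocabulary <- function(axis, terms, synonyms = list(),
                       unknown_label = "uncharacterized") {
  axis <- match.arg(axis, VOCAB_AXES)
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop("vocabulary: canonical terms must be unique")
  if (unknown_label %in% terms)
    stop("vocabulary: unknown_label must not be a canonical term")
  map <- stats::setNames(terms, canon_key(terms))
  for (term in names(synonyms)) {
    if (!term %in% terms) stop("vocabulary: synonym target not a term: ", term)
    keys <- canon_key(synonyms[[term]])
    clash <- keys %in% names(map) & map[keys] != term
    if (any(clash))
      stop("vocabulary: synonym maps to two terms: ", synonyms[[term]][clash][1])
    map[keys] <- term
  }
  structure(list(axis = axis, terms = terms, synonym_map = map,
                 unknown_label = unknown_label),
            class = "est_vocabulary")
}

#' Read a vocabulary from a YAML config file
#'
#' Expected layout: `axis`, optional `unknown_label`, and `terms`, a list of
#' stanzas each with a `term` and an optional `synonyms` list.
#'
#' @param path YAML file.
#' @return An [vocabulary()] object.
#' @export
read_vocabulary <- function(path) {
  cfg <- yaml::read_yaml(path)
  stanzas <- cfg$terms
  terms <- vapply(stanzas, function(s) as.character(s$term), character(1))
  syn <- lapply(stanzas, function(s) as.character(unlist(s$synonyms)))
  names(syn) <- terms
  vocabulary(cfg$axis, terms, syn[lengths(syn) > 0],
             cfg$unknown_label %||% "uncharacterized")
}

#' Default vocabulary shipped with the package
#'
#' Loads the built-in *Bombyx mori* vocabulary for one axis (28 tissues,
#' 31 developmental stages, 4 sexes, 10 strains). These lists are editable
#' data: point [read_vocabulary()] at your own files for other species.
#'
#' @param axis metadata axis.
#' @return An `est_vocabulary`.
#' @export
default_vocabulary <- function(axis = VOCAB_AXES) {
  axis <- match.arg(axis)
  read_vocabulary(system.file("extdata", "vocab", paste0(axis, ".yaml"),
                              package = "estprofiler", mustWork = TRUE))
}

#' @export
print.est_vocabulary <- function(x, ...) {
  cat(sprintf("Vocabulary [%s]: %d canonical terms, %d synonym keys, unknown = '%s'\n",
              x$axis, length(x$terms), length(x$synonym_map), x$unknown_label))
  invisible(x)
}

#' Normalize raw metadata values against a vocabulary
#'
#' Case-, whitespace- and underscore-insensitive exact lookup; empty or
#' unmapped values return the vocabulary's unknown label. Idempotent on
#' canonical terms. Vectorized.
#'
#' @param raw character vector of raw values.
#' @param vocab an `est_vocabulary`.
#' @return Character vector of canonical terms.
#' @export
normalize_term <- function(raw, vocab) {
  stopifnot(inherits(vocab, "est_vocabulary"))
  hit <- vocab$synonym_map[canon_key(raw)]
  hit[is.na(hit)] <- vocab$unknown_label
  unname(hit)
}

axis_raw_column <- function(corpus, axis) {
  corpus[[paste0(match.arg(axis, VOCAB_AXES), "_raw")]]
}

#' Tally a category distribution over one metadata axis
#'
#' Counts every record exactly once under [normalize_term()]. The unknown
#' label is a real category and is included.
#'
#' @param corpus a deduplicated [est_corpus()].
#' @param axis metadata axis.
#' @param vocab vocabulary for the axis; defaults to the shipped one.
#' @return A `category_distribution`: data frame with columns `term`,
#'   `count`, `proportion`, terms in vocabulary order (unknown last), plus
#'   `axis` and `total` attributes.
#' @export
tally <- function(corpus, axis, vocab = default_vocabulary(axis)) {
  stopifnot(inherits(corpus, "est_corpus"))
  axis <- match.arg(axis, VOCAB_AXES)
  lv <- c(vocab$terms, vocab$unknown_label)
  if (!nrow(corpus)) {
    warning("tally: empty corpus")
    out <- data.frame(term = character(0), count = integer(0),
                      proportion = numeric(0))
  } else {
    counts <- table(factor(normalize_term(axis_raw_column(corpus, axis), vocab),
                           levels = lv))
    counts <- counts[counts > 0]
    out <- data.frame(term = names(counts), count = as.integer(counts),
                      proportion = as.integer(counts) / nrow(corpus))
  }
  rownames(out) <- NULL
  structure(out, axis = axis, total = nrow(corpus),
            class = c("category_distribution", "data.frame"))
}

#' @export
print.category_distribution <- function(x, ...) {
  cat(sprintf("Category distribution over %s (%d records):\n",
              attr(x, "axis"), attr(x, "total")))
  df <- as.data.frame(x)
  df$proportion <- sprintf("%.1f%%", 100 * df$proportion)
  print(df[order(-x$count), ], row.names = FALSE)
  invisible(x)
}

#' Cross-tabulate two metadata axes
#'
#' Cell (a, b) counts the records normalizing to term `a` on the first axis
#' and `b` on the second. Row and column sums reproduce the single-axis
#' [tally()] counts.
#'
#' @param corpus a deduplicated [est_corpus()].
#' @param axis_a,axis_b the two axes.
#' @param vocab_a,vocab_b their vocabularies.
#' @return Integer matrix (terms of axis_a x terms of axis_b, vocabulary
#'   order, unknown last, zero margins dropped).
#' @export
cross_tally <- function(corpus, axis_a, axis_b,
                        vocab_a = default_vocabulary(axis_a),
                        vocab_b = default_vocabulary(axis_b)) {
  stopifnot(inherits(corpus, "est_corpus"))
  a <- factor(normalize_term(axis_raw_column(corpus, axis_a), vocab_a),
              levels = c(vocab_a$terms, vocab_a$unknown_label))
  b <- factor(normalize_term(axis_raw_column(corpus, axis_b), vocab_b),
              levels = c(vocab_b$terms, vocab_b$unknown_label))
  m <- unclass(table(a, b, dnn = NULL))
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

#' Write a category distribution as TSV
#'
#' Columns `term`, `count`, `proportion`.
#'
#' @param dist a `category_distribution`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distribution_tsv <- function(dist, path) {
  utils::write.table(as.data.frame(dist), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
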