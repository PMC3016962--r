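#' @title EST corpus containers and readers
#' @name est_io
#' @description Readers and writers for the two supported EST representations:
#'   dbEST-style FASTA with free-text deflines, and the flat "EST Source"
#'   format (one EST per line, whitespace-separated accession / tissue /
#'   stage / sex / strain fields).
NULL

CORPUS_FIELDS <- c("accession", "tissue_raw", "stage_raw", "sex_raw",
                   "strain_raw", "library_id", "sequence")

#' Construct an EST corpus
#'
#' An `est_corpus` is a data frame with one row per EST and character columns
#' `accession`, `tissue_raw`, `stage_raw`, `sex_raw`, `strain_raw`,
#' `library_id` and `sequence` (the latter two `NA` when absent). Raw
#' metadata is stored verbatim; vocabulary normalization happens downstream.
#'
#' @param records data frame holding at least an `accession` column; missing
#'   metadata columns are filled with empty strings.
#' @param provenance list of parse statistics (source path, records read,
#'   records skipped, duplicate count).
#' @return An object of class `est_corpus`.
#' @export
est_corpus <- function(records, provenance = list()) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"accession" %in% names(records))
    stop("est_corpus: 'accession' column is required")
  if (any(!nzchar(records$accession)) || anyNA(records$accession))
    stop("est_corpus: accessions must be non-empty")
  for (f in setdiff(CORPUS_FIELDS, c("accession", "library_id", "sequence")))
    if (is.null(records[[f]])) records[[f]] <- rep("", nrow(records))
  for (f in c("library_id", "sequence"))
    if (is.null(records[[f]])) records[[f]] <- rep(NA_character_, nrow(records))
  records <- records[, CORPUS_FIELDS]
  seqs <- records$sequence[!is.na(records$sequence)]
  if (length(seqs) && any(grepl("[^ACGTUMRWSYKVHDBN]", toupper(seqs))))
    stop("est_corpus: sequences must contain only IUPAC nucleotide codes")
  rownames(records) <- NULL
  structure(records,
            provenance = utils::modifyList(
              list(source = NA_character_, n_read = nrow(records),
                   n_skipped = 0L, n_duplicates = 0L),
              provenance),
            class = c("est_corpus", "data.frame"))
}

#' @export
print.est_corpus <- function(x, ...) {
  pv <- attr(x, "provenance")
  cat(sprintf("EST corpus: %d records (%d read, %d skipped, %d duplicates removed)\n",
              nrow(x), pv$n_read, pv$n_skipped, pv$n_duplicates))
  if (!is.na(pv$source[1])) cat("source:", paste(pv$source, collapse = ", "), "\n")
  if (nrow(x)) {
    utils::head(as.data.frame(x)[, 1:5], 5) |> print()
    if (nrow(x) > 5) cat("...", nrow(x) - 5, "more\n")
  }
  invisible(x)
}

#' Read the flat "EST Source" format
#'
#' One EST per line; the first whitespace-separated token is the accession,
#' tokens 2--5 are tissue, developmental stage, sex and strain. Missing
#' trailing tokens yield empty fields; the placeholder `-` also reads as an
#' empty field (it is what [write_est_source()] emits for internal empties).
#' Underscores inside values stand for spaces and are kept verbatim here;
#' vocabulary matching folds them later.
#'
#' @param path path to a text file (UTF-8, LF or CRLF line endings).
#' @return An [est_corpus()]; lines with zero tokens are skipped and counted
#'   in the provenance.
#' @export
parse_est_source <- function(path) {
  if (!file.exists(path)) stop("parse_est_source: cannot read ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  toks <- strsplit(trimws(lines), "[ \t]+")
  keep <- vapply(toks, function(t) length(t) > 0L && nzchar(t[1]), logical(1))
  n_skip <- sum(!keep)
  toks <- toks[keep]
  if (!length(toks)) {
    warning("parse_est_source: no records in ", path)
    return(est_corpus(data.frame(accession = character(0)),
                      list(source = path, n_read = 0L, n_skipped = n_skip)))
  }
  field <- function(i) vapply(toks, function(t) {
    v <- if (length(t) >= i) t[i] else ""
    if (identical(v, "-")) "" else v
  }, character(1))
  est_corpus(data.frame(accession = field(1), tissue_raw = field(2),
                        stage_raw = field(3), sex_raw = field(4),
                        strain_raw = field(5), stringsAsFactors = FALSE),
             list(source = path, n_read = length(toks), n_skipped = n_skip))
}

#' Default defline extraction rules
#'
#' Ordered regular expressions (first match wins) covering the two common
#' dbEST defline dialects: `/key="value"` attributes and `key: value;`
#' clauses. Each pattern must carry exactly one capture group.
#'
#' @return A list with one character vector of patterns per metadata field
#'   plus `library_id` patterns.
#' @export
default_defline_rules <- function() {
  list(
    tissue_raw = c('/tissue="([^"]*)"', '(?:^|[ ;])tissue:[ ]*([^;]+)'),
    stage_raw  = c('/dev_stage="([^"]*)"', '(?:^|[ ;])dev_stage:[ ]*([^;]+)'),
    sex_raw    = c('/sex="([^"]*)"', '(?:^|[ ;])sex:[ ]*([^;]+)'),
    strain_raw = c('/strain="([^"]*)"', '(?:^|[ ;])strain:[ ]*([^;]+)'),
    library_id = c('/clone_lib="([^"]*)"', '(?:^|[ ;])clone_lib:[ ]*([^;]+)')
  )
}

#' Read defline extraction rules from a YAML config
#'
#' The file maps field names (`tissue_raw`, `stage_raw`, `sex_raw`,
#' `strain_raw`, `library_id`) to ordered lists of regex patterns, each with
#' one capture group.
#'
#' @param path YAML file.
#' @return Rule list as in [default_defline_rules()].
#' @export
read_defline_rules <- function(path) {
  rules <- yaml::read_yaml(path)
  if (!is.list(rules) || !length(rules))
    stop("read_defline_rules: invalid rule file ", path)
  lapply(rules, function(p) vapply(p, as.character, character(1)))
}

extract_first_match <- function(defline, patterns) {
  for (p in patterns) {
    m <- regexec(p, defline, perl = TRUE)[[1]]
    if (m[1] != -1L && length(m) >= 2L)
      return(trimws(substring(defline, m[2], m[2] + attr(m, "match.length")[2] - 1L)))
  }
  ""
}

#' Read a dbEST-style FASTA file
#'
#' One EST per FASTA entry; the accession is the first whitespace-separated
#' token of the defline and library metadata is extracted from the rest of
#' the defline by ordered regular-expression rules. When a `library_id` is
#' found and a lookup table is supplied, fields the defline leaves empty are
#' filled from the table.
#'
#' @param path FASTA file.
#' @param defline_rules rule list as from [default_defline_rules()] or
#'   [read_defline_rules()].
#' @param library_table optional data frame with columns `library_id`,
#'   `tissue`, `stage`, `sex`, `strain` used as a fallback for deflines that
#'   carry only a clone-library id.
#' @return An [est_corpus()] with sequences retained.
#' @export
parse_dbest_fasta <- function(path, defline_rules = default_defline_rules(),
                              library_table = NULL) {
  if (!file.exists(path)) stop("parse_dbest_fasta: cannot read ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("parse_dbest_fasta: malformed FASTA in ",
                                           path, ": ", conditionMessage(e)))
  deflines <- names(set)
  acc <- sub("\\s.*$", "", deflines)
  fields <- c("tissue_raw", "stage_raw", "sex_raw", "strain_raw")
  meta <- vapply(deflines, function(d) {
    c(vapply(fields, function(f)
        extract_first_match(d, defline_rules[[f]] %||% character(0)), character(1)),
      library_id = extract_first_match(d, defline_rules$library_id %||% character(0)))
  }, character(5))
  meta <- as.data.frame(t(meta), stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  if (!is.null(library_table) && nrow(library_table)) {
    idx <- match(meta$library_id, library_table$library_id)
    lut_col <- c(tissue_raw = "tissue", stage_raw = "stage",
                 sex_raw = "sex", strain_raw = "strain")
    for (f in fields) {
      fill <- !is.na(idx) & !nzchar(meta[[f]])
      meta[[f]][fill] <- library_table[[lut_col[[f]]]][idx[fill]]
    }
  }
  meta$library_id[!nzchar(meta$library_id)] <- NA_character_
  est_corpus(data.frame(accession = acc, meta,
                        sequence = as.character(set), stringsAsFactors = FALSE),
             list(source = path, n_read = length(set), n_skipped = 0L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove redundant EST records
#'
#' Keeps the first occurrence of each accession, preserving input order, and
#' records the number of duplicates dropped in the corpus provenance.
#' Idempotent.
#'
#' @param corpus an [est_corpus()].
#' @return Deduplicated `est_corpus`.
#' @export
deduplicate <- function(corpus) {
  stopifnot(inherits(corpus, "est_corpus"))
  pv <- attr(corpus, "provenance")
  keep <- !duplicated(corpus$accession)
  pv$n_duplicates <- pv$n_duplicates + sum(!keep)
  est_corpus(as.data.frame(corpus)[keep, , drop = FALSE], pv)
}

#' Write a corpus in the flat "EST Source" format
#'
#' One line per record: accession then tissue, stage, sex, strain. Internal
#' whitespace in a value is replaced by underscores (the format is
#' space-delimited) and empty fields are written as `-`, so that
#' [parse_est_source()] recovers the corpus exactly.
#'
#' @param corpus an [est_corpus()].
#' @param path output file (written UTF-8, LF).
#' @return `path`, invisibly.
#' @export
write_est_source <- function(corpus, path) {
  stopifnot(inherits(corpus, "est_corpus"))
  enc <- function(x) {
    x <- gsub("\\s+", "_", trimws(x))
    x[!nzchar(x)] <- "-"
    x
  }
  lines <- paste(enc(corpus$accession), enc(corpus$tissue_raw),
                 enc(corpus$stage_raw), enc(corpus$sex_raw),
                 enc(corpus$strain_raw))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
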