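#' @title End-to-end pipeline
#' @name pipeline
#' @description Wires the stages together, file-in/file-out: ingest and
#'   deduplicate a corpus, tally the four metadata axes, build per-gene
#'   spatio-temporal profiles, classify specificity, pick BLAST best hits
#'   and summarize GO categories. Every output is a TSV; a manifest records
#'   each file with its SHA-256 hash and producing stage, so two runs on
#'   identical inputs are bit-identical and auditable. No stage mutates its
#'   inputs and no analysis stage draws random numbers.
NULL

#' Assemble a pipeline run configuration
#'
#' Paths may be `NULL` to skip the stages that need them (e.g. no BLAST
#' file: annotation and GO stages are skipped).
#'
#' @param corpus path to an EST Source file (or FASTA if `format="fasta"`).
#' @param out_dir output directory.
#' @param format `"est_source"` or `"fasta"`.
#' @param clusters optional cluster-table TSV; enables profiles and calls.
#' @param blast,obo,protein2go optional annotation inputs; all three enable
#'   the GO summary.
#' @param go_datasets optional named list of accession vectors for the GO
#'   summary; default is one dataset holding the whole corpus.
#' @param profile_clusters cluster ids to write profile TSVs for (default:
#'   all clusters).
#' @param vocab_dir directory holding `tissue.yaml` etc.; default is the
#'   shipped vocabulary.
#' @param params thresholds from [specificity_params()].
#' @param evalue_cutoff BLAST e-value cutoff.
#' @param go_level GO rollup level.
#' @return A validated `run_config` list.
#' @export
run_config <- function(corpus, out_dir, format = c("est_source", "fasta"),
                       clusters = NULL, blast = NULL, obo = NULL,
                       protein2go = NULL, go_datasets = NULL,
                       profile_clusters = NULL, vocab_dir = NULL,
                       params = specificity_params(),
                       evalue_cutoff = 1e-10, go_level = 2) {
  format <- match.arg(format)
  stopifnot(evalue_cutoff > 0, go_level >= 1)
  for (p in c(corpus, clusters, blast, obo, protein2go,
              if (!is.null(vocab_dir)) vocab_dir))
    if (!file.exists(p)) stop("run_config: path does not exist: ", p)
  structure(list(corpus = corpus, out_dir = out_dir, format = format,
                 clusters = clusters, blast = blast, obo = obo,
                 protein2go = protein2go, go_datasets = go_datasets,
                 profile_clusters = profile_clusters, vocab_dir = vocab_dir,
                 params = params, evalue_cutoff = evalue_cutoff,
                 go_level = go_level),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; threshold parameters live
#' under a `params` mapping.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pr <- do.call(specificity_params, y$params %||% list())
  run_config(corpus = y$corpus, out_dir = y$out_dir,
             format = y$format %||% "est_source", clusters = y$clusters,
             blast = y$blast, obo = y$obo, protein2go = y$protein2go,
             profile_clusters = y$profile_clusters, vocab_dir = y$vocab_dir,
             params = pr, evalue_cutoff = y$evalue_cutoff %||% 1e-10,
             go_level = y$go_level %||% 2)
}

load_vocab_set <- function(vocab_dir) {
  if (is.null(vocab_dir)) {
    stats::setNames(lapply(VOCAB_AXES, default_vocabulary), VOCAB_AXES)
  } else {
    stats::setNames(lapply(VOCAB_AXES, function(a)
      read_vocabulary(file.path(vocab_dir, paste0(a, ".yaml")))), VOCAB_AXES)
  }
}

#' Run the full pipeline
#'
#' Executes the configured stages in order and returns a manifest of every
#' file written (path, SHA-256, producing stage), also saved as
#' `manifest.tsv`. The first failing stage aborts the run with its error.
#'
#' @param config a `run_config` (or path to a YAML config).
#' @param quiet suppress per-stage record-count messages.
#' @return Invisibly, a list with `manifest` (data frame) and `counts`
#'   (per-stage record counts).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  outputs <- list(); counts <- list()
  emit <- function(path, stage) outputs[[length(outputs) + 1]] <<-
    list(file = path, stage = stage)

  vocabs <- load_vocab_set(config$vocab_dir)
  corpus <- if (config$format == "fasta") parse_dbest_fasta(config$corpus)
            else parse_est_source(config$corpus)
  corpus <- deduplicate(corpus)
  counts$corpus <- nrow(corpus)
  say("ingest: %d unique records (%d duplicates removed)", nrow(corpus),
      attr(corpus, "provenance")$n_duplicates)
  clean <- file.path(config$out_dir, "corpus_dedup.txt")
  write_est_source(corpus, clean); emit(clean, "ingest")

  for (axis in VOCAB_AXES) {
    d <- tally(corpus, axis, vocabs[[axis]])
    p <- file.path(config$out_dir, paste0("distribution_", axis, ".tsv"))
    write_distribution_tsv(d, p); emit(p, "tally")
  }
  ct <- cross_tally(corpus, "tissue", "stage", vocabs$tissue, vocabs$stage)
  p <- file.path(config$out_dir, "cross_tissue_stage.tsv")
  utils::write.table(ct, p, sep = "\t", quote = FALSE, col.names = NA)
  emit(p, "tally")

  if (!is.null(config$clusters)) {
    table <- load_cluster_table(config$clusters)
    pools <- pool_sizes(corpus, vocabs$tissue, vocabs$stage)
    ids <- config$profile_clusters %||% names(table$clusters)
    prof_dir <- file.path(config$out_dir, "profiles")
    dir.create(prof_dir, showWarnings = FALSE)
    for (id in ids) {
      prof <- suppressWarnings(build_profile(
        extract_gene(corpus, table, id), corpus, vocabs$tissue, vocabs$stage,
        pool_min = config$params$pool_min, pools = pools))
      p <- file.path(prof_dir, paste0("profile_", gsub("[^A-Za-z0-9._-]", "_", id),
                                      ".tsv"))
      write_profile_tsv(prof, p); emit(p, "profile")
    }
    counts$profiles <- length(ids)
    calls <- classify_all(corpus, table, vocabs$tissue, vocabs$stage,
                          config$params)
    counts$calls <- nrow(calls)
    say("classify: %d clusters", nrow(calls))
    p <- file.path(config$out_dir, "specificity_calls.tsv")
    write_calls_tsv(calls, p); emit(p, "classify")
  }

  if (!is.null(config$blast)) {
    hits <- parse_blast_tab(config$blast)
    best <- best_hit_per_query(filter_hits(hits, config$evalue_cutoff))
    counts$best_hits <- nrow(best)
    say("annotate: %d hits -> %d best hits", nrow(hits), nrow(best))
    p <- file.path(config$out_dir, "best_hits.tsv")
    utils::write.table(format_tsv_num(as.data.frame(best)), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(p, "annotate")
    if (!is.null(config$obo) && !is.null(config$protein2go)) {
      ont <- load_obo(config$obo)
      p2g <- read_protein2go(config$protein2go)
      datasets <- config$go_datasets %||% list(all = corpus$accession)
      gs <- summarize_go(best, p2g, ont, config$go_level, datasets)
      counts$go_terms <- nrow(gs)
      p <- file.path(config$out_dir, "go_summary.tsv")
      write_go_summary_tsv(gs, p); emit(p, "gosummary")
    }
  }

  manifest <- data.frame(
    file = vapply(outputs, `[[`, character(1), "file"),
    sha256 = vapply(outputs, function(o)
      digest::digest(o$file, algo = "sha256", file = TRUE), character(1)),
    stage = vapply(outputs, `[[`, character(1), "stage"),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(manifest = manifest, counts = counts))
}
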