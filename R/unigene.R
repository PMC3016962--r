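#' @title UniGene-style cluster tables
#' @name unigene
#' @description A cluster table attributes each EST accession to at most one
#'   gene-oriented cluster; resolving a cluster against a corpus yields the
#'   per-gene EST set whose counts drive the expression profile.
NULL

#' Construct a cluster table
#'
#' @param cluster_ids character vector of cluster ids, parallel to
#'   `accessions`.
#' @param accessions character vector of EST accessions.
#' @param titles optional named character vector: cluster id -> gene title.
#' @return An object of class `cluster_table`: named list cluster id ->
#'   ordered accession vector. Duplicate (cluster, accession) pairs collapse;
#'   an accession claimed by two clusters is a validation error.
#' @export
cluster_table <- function(cluster_ids, accessions, titles = NULL) {
  stopifnot(length(cluster_ids) == length(accessions))
  keep <- !duplicated(paste0(cluster_ids, "\r", accessions))
  cluster_ids <- cluster_ids[keep]; accessions <- accessions[keep]
  dup <- duplicated(accessions)
  if (any(dup)) {
    a <- accessions[dup][1]
    stop("cluster_table: accession ", a, " claimed by clusters ",
         paste(unique(cluster_ids[accessions == a]), collapse = " and "))
  }
  clusters <- split(accessions, factor(cluster_ids, levels = unique(cluster_ids)))
  structure(list(clusters = clusters, titles = titles),
            class = "cluster_table")
}

#' Load a cluster table from a two-column TSV
#'
#' Native format: `cluster_id<TAB>accession`, one membership per line,
#' `#` comments allowed. (UniGene `.data` stanza files can be converted to
#' this layout with any text tool; the retired UniGene build formats are not
#' parsed directly.)
#'
#' @param path TSV file.
#' @return A [cluster_table()].
#' @export
load_cluster_table <- function(path) {
  if (!file.exists(path)) stop("load_cluster_table: cannot read ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines))
    return(cluster_table(character(0), character(0)))
  toks <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(toks) < 2L)
  if (length(bad))
    stop("load_cluster_table: line ", bad[1], " has fewer than 2 columns")
  cluster_table(vapply(toks, `[`, character(1), 1),
                vapply(toks, `[`, character(1), 2))
}

#' @export
print.cluster_table <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("Cluster table: %d clusters, %d accessions (sizes %s)\n",
              length(sizes), sum(sizes),
              if (length(sizes)) paste0(min(sizes), "-", max(sizes)) else "-"))
  invisible(x)
}

#' Resolve one cluster against a corpus
#'
#' A pure lookup: returns the corpus records whose accessions belong to the
#' cluster (in cluster-file order) and lists the accessions the corpus does
#' not contain. Missing accessions are reported, never silently dropped.
#'
#' @param corpus a deduplicated [est_corpus()].
#' @param table a [cluster_table()].
#' @param cluster_id the cluster to resolve.
#' @return A `gene_est_set`: list with `cluster_id`, `records` (an
#'   `est_corpus` subset) and `missing` (character).
#' @export
extract_gene <- function(corpus, table, cluster_id) {
  stopifnot(inherits(corpus, "est_corpus"), inherits(table, "cluster_table"))
  members <- table$clusters[[cluster_id]]
  if (is.null(members)) stop("extract_gene: unknown cluster ", cluster_id)
  idx <- match(members, corpus$accession)
  records <- est_corpus(as.data.frame(corpus)[idx[!is.na(idx)], , drop = FALSE],
                        attr(corpus, "provenance"))
  structure(list(cluster_id = cluster_id, records = records,
                 missing = members[is.na(idx)]),
            class = "gene_est_set")
}

#' @export
print.gene_est_set <- function(x, ...) {
  cat(sprintf("Gene EST set %s: %d ESTs found, %d missing from corpus\n",
              x$cluster_id, nrow(x$records), length(x$missing)))
  invisible(x)
}
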