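#' @title Expression-specificity classification
#' @name specificity
#' @description Rule-based calls from a gene's spatio-temporal profile:
#'   `ubiquitous` (housekeeping-like: detected across nearly all sampled
#'   tissues, e.g. a ribosomal protein), `tissue_specific` (EST mass
#'   concentrated in one tissue, e.g. a sericin in the middle silk gland),
#'   `stage_specific` (one developmental stage, e.g. a chorion protein in
#'   the pupa), `mixed`, or `insufficient_data`. Two statistics drive the
#'   call on each axis: dominance (largest single-category share of the
#'   gene's ESTs) and breadth (fraction of well-sampled pools where the gene
#'   is detected at all). The unknown-label pool is excluded from both — an
#'   EST whose library did not state its tissue is evidence for no tissue —
#'   and only pools with at least `pool_min` ESTs count toward breadth,
#'   since an unsampled tissue cannot count against ubiquity.
NULL

#' Default classification thresholds
#'
#' @param min_support minimum gene EST count for any call (default 3).
#' @param dominance minimal dominant-category share for a specific call
#'   (default 0.95).
#' @param breadth minimal detected fraction of qualifying tissue pools for a
#'   ubiquitous call (default 0.80).
#' @param pool_min minimum pool total for a pool to qualify for breadth
#'   (default 30).
#' @return Named list of thresholds.
#' @export
specificity_params <- function(min_support = 3, dominance = 0.95,
                               breadth = 0.80, pool_min = 30) {
  stopifnot(min_support >= 0, dominance > 0, dominance <= 1,
            breadth > 0, breadth <= 1, pool_min >= 0)
  list(min_support = min_support, dominance = dominance,
       breadth = breadth, pool_min = pool_min)
}

axis_stats <- function(counts_margin, pool_margin, unknown_label, pool_min) {
  known <- setdiff(names(counts_margin), unknown_label)
  n <- counts_margin[known]
  tot <- sum(n)
  dominance <- if (tot > 0) max(n) / tot else 0
  target <- if (tot > 0) known[which.max(n)] else NA_character_
  qual <- pool_margin[known] >= pool_min & pool_margin[known] > 0
  breadth <- if (any(qual)) mean(n[qual] > 0) else 0
  list(dominance = dominance, target = target, breadth = breadth)
}

#' Classify one profile
#'
#' Deterministic decision ladder: support below `min_support` gives
#' `insufficient_data`; otherwise tissue dominance at or above the dominance
#' threshold gives `tissue_specific` (tissue takes precedence over stage
#' when both pass — EST libraries confound the two axes and the tie is
#' auditable from the reported dominances); otherwise stage dominance gives
#' `stage_specific`; otherwise tissue breadth at or above the breadth
#' threshold gives `ubiquitous`; otherwise `mixed`.
#'
#' @param profile an `st_profile` from [build_profile()].
#' @param params thresholds from [specificity_params()].
#' @return A `specificity_call`: one-row data frame with columns
#'   `cluster_id`, `call`, `target`, `support`, `dominance_tissue`,
#'   `breadth_tissue`, `dominance_stage`, `breadth_stage`.
#' @export
classify <- function(profile, params = specificity_params()) {
  stopifnot(inherits(profile, "st_profile"))
  unknown_t <- rownames(profile$counts)[nrow(profile$counts)]
  unknown_s <- colnames(profile$counts)[ncol(profile$counts)]
  ts <- axis_stats(rowSums(profile$counts), profile$pools$tissue,
                   unknown_t, params$pool_min)
  ss <- axis_stats(colSums(profile$counts), profile$pools$stage,
                   unknown_s, params$pool_min)
  support <- sum(profile$counts)
  call <- if (support < params$min_support) "insufficient_data"
          else if (ts$dominance >= params$dominance) "tissue_specific"
          else if (ss$dominance >= params$dominance) "stage_specific"
          else if (ts$breadth >= params$breadth) "ubiquitous"
          else "mixed"
  target <- switch(call, tissue_specific = ts$target,
                   stage_specific = ss$target, NA_character_)
  structure(data.frame(cluster_id = profile$cluster_id, call = call,
                       target = target, support = support,
                       dominance_tissue = ts$dominance,
                       breadth_tissue = ts$breadth,
                       dominance_stage = ss$dominance,
                       breadth_stage = ss$breadth,
                       stringsAsFactors = FALSE),
            class = c("specificity_call", "data.frame"))
}

#' Classify every cluster of a table
#'
#' Builds each gene's profile against shared pools and classifies it.
#' Output rows are sorted by cluster id, so the table is stable regardless
#' of cluster-file order.
#'
#' @param corpus a deduplicated [est_corpus()].
#' @param table a [cluster_table()].
#' @param vocab_tissue,vocab_stage vocabularies.
#' @param params thresholds from [specificity_params()].
#' @return A `specificity_calls` data frame (one row per cluster) with a
#'   class-count summary attribute.
#' @export
classify_all <- function(corpus, table,
                         vocab_tissue = default_vocabulary("tissue"),
                         vocab_stage = default_vocabulary("stage"),
                         params = specificity_params()) {
  stopifnot(inherits(table, "cluster_table"))
  pools <- pool_sizes(corpus, vocab_tissue, vocab_stage)
  ids <- sort(names(table$clusters))
  calls <- lapply(ids, function(id) {
    gene <- extract_gene(corpus, table, id)
    prof <- suppressWarnings(
      build_profile(gene, corpus, vocab_tissue, vocab_stage,
                    pool_min = params$pool_min, pools = pools))
    classify(prof, params)
  })
  out <- do.call(rbind, lapply(calls, as.data.frame))
  rownames(out) <- NULL
  structure(out, summary = table(out$call),
            class = c("specificity_calls", "data.frame"))
}

#' @export
print.specificity_calls <- function(x, ...) {
  cat("Specificity calls for", nrow(x), "clusters:\n")
  print(attr(x, "summary"))
  invisible(x)
}

#' Write specificity calls as TSV
#'
#' @param calls a `specificity_calls` table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(format_tsv_num(as.data.frame(calls)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
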