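#' @title BLAST best-hit annotation and GO category rollup
#' @name goannot
#' @description Consumes precomputed BLASTx tabular output (the 12-column
#'   format), filters hits at an e-value cutoff, selects the best hit per
#'   EST, maps subjects to Gene Ontology terms, and summarizes GO categories
#'   at a fixed ontology level for one or more EST datasets in a single
#'   WEGO-style table/plot. BLAST itself is never executed here; the module
#'   is file-in/file-out.
NULL

BLAST_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Parse BLAST tabular output
#'
#' Standard 12-column tab-separated format (`-outfmt 6`); `#` comment lines
#' (`-outfmt 7`) are skipped; columns beyond the twelfth are retained
#' opaquely in an `extra` column.
#'
#' @param path BLAST tabular file.
#' @return A `blast_hits` data frame with the standard column names; numeric
#'   fields validated (a non-numeric e-value or bit score is a parse error
#'   naming the line).
#' @export
parse_blast_tab <- function(path) {
  if (!file.exists(path)) stop("parse_blast_tab: cannot read ", path)
  lines <- readLines(path, warn = FALSE)
  data_ln <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (!length(data_ln)) {
    out <- data.frame(matrix(nrow = 0, ncol = 12,
                             dimnames = list(NULL, BLAST_COLS)))
    return(structure(out, class = c("blast_hits", "data.frame")))
  }
  toks <- strsplit(lines[data_ln], "\t", fixed = TRUE)
  short <- which(lengths(toks) < 12L)
  if (length(short))
    stop("parse_blast_tab: line ", data_ln[short[1]], " has fewer than 12 columns")
  col <- function(i) vapply(toks, `[`, character(1), i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(col(i)))
    bad <- which(is.na(v))
    if (length(bad))
      stop("parse_blast_tab: non-numeric ", what, " on line ", data_ln[bad[1]])
    v
  }
  out <- data.frame(qseqid = col(1), sseqid = col(2),
                    pident = num(3, "pident"), length = num(4, "length"),
                    mismatch = num(5, "mismatch"), gapopen = num(6, "gapopen"),
                    qstart = num(7, "qstart"), qend = num(8, "qend"),
                    sstart = num(9, "sstart"), send = num(10, "send"),
                    evalue = num(11, "e-value"), bitscore = num(12, "bit score"),
                    stringsAsFactors = FALSE)
  if (any(out$evalue < 0)) stop("parse_blast_tab: negative e-value")
  extra <- vapply(toks, function(t)
    if (length(t) > 12L) paste(t[-(1:12)], collapse = "\t") else NA_character_,
    character(1))
  if (any(!is.na(extra))) out$extra <- extra
  structure(out, class = c("blast_hits", "data.frame"))
}

#' Filter hits at an e-value cutoff
#'
#' Retains hits with e-value at or below the cutoff (inclusive: "cutoff"
#' conventionally includes the boundary), preserving order. Idempotent.
#'
#' @param hits a `blast_hits` data frame.
#' @param cutoff e-value cutoff (> 0; default `1e-10`).
#' @return Filtered `blast_hits`.
#' @export
filter_hits <- function(hits, cutoff = 1e-10) {
  stopifnot(cutoff > 0)
  out <- hits[hits$evalue <= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the most meaningful match per query
#'
#' Per query: the hit with the minimum e-value; ties broken by maximum bit
#' score, then by lexicographically smallest subject id. Fully
#' deterministic.
#'
#' @param hits a (typically filtered) `blast_hits` data frame.
#' @return `blast_hits` with exactly one row per distinct query, ordered by
#'   query id.
#' @export
best_hit_per_query <- function(hits) {
  if (!nrow(hits)) return(hits)
  ord <- order(hits$qseqid, hits$evalue, -hits$bitscore, hits$sseqid)
  out <- hits[ord, , drop = FALSE]
  out <- out[!duplicated(out$qseqid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load a Gene Ontology graph from an OBO file
#'
#' Parses `[Term]` stanzas of an OBO 1.2-style file: id, name, namespace and
#' `is_a` parents. Obsolete terms are excluded; only `is_a` edges are kept
#' (no `part_of`). The graph must be acyclic over `is_a`; every kept term
#' must carry a namespace.
#'
#' @param path OBO file.
#' @return A `go_ontology`: list with `terms` (data frame `id`, `name`,
#'   `namespace`, `level`), `parents` and `children` (named lists of id
#'   vectors). `level` is 1 at a namespace root and grows by the shortest
#'   `is_a` path from the root.
#' @export
load_obo <- function(path) {
  if (!file.exists(path)) stop("load_obo: cannot read ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "[Term]")
  if (!length(starts)) stop("load_obo: no [Term] stanzas in ", path)
  bounds <- c(which(startsWith(lines, "[")), length(lines) + 1L)
  terms <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    from <- starts[k] + 1L
    to <- min(bounds[bounds > starts[k]]) - 1L
    chunk <- lines[from:to]
    val <- function(key) {
      v <- sub(paste0("^", key, ": "), "", chunk[startsWith(chunk, paste0(key, ": "))])
      sub(" ! .*$", "", v)
    }
    if (any(val("is_obsolete") == "true")) next
    id <- val("id")
    ns <- val("namespace")
    if (!length(ns)) stop("load_obo: term ", id[1], " has no namespace")
    terms[[k]] <- list(id = id[1], name = val("name")[1] %||% NA_character_,
                       namespace = ns[1], parents = val("is_a"))
  }
  terms <- terms[!vapply(terms, is.null, logical(1))]
  ids <- vapply(terms, `[[`, character(1), "id")
  parents <- lapply(terms, function(t) intersect(t$parents, ids))
  names(parents) <- ids
  edges <- do.call(rbind, lapply(ids, function(i)
    if (length(parents[[i]])) cbind(i, parents[[i]])))
  if (!is.null(edges)) {
    g <- igraph::graph_from_edgelist(edges, directed = TRUE)
    if (!igraph::is_dag(g)) stop("load_obo: is_a graph is cyclic")
  }
  children <- lapply(stats::setNames(ids, ids), function(i) character(0))
  for (i in ids) for (p in parents[[i]]) children[[p]] <- c(children[[p]], i)
  df <- data.frame(id = ids,
                   name = vapply(terms, function(t) t$name, character(1)),
                   namespace = vapply(terms, `[[`, character(1), "namespace"),
                   stringsAsFactors = FALSE)
  bad_ns <- setdiff(unique(df$namespace),
                    c("biological_process", "molecular_function",
                      "cellular_component"))
  if (length(bad_ns)) stop("load_obo: unknown namespace ", bad_ns[1])
  # breadth-first from the namespace roots: level = 1 + shortest is_a path
  level <- stats::setNames(rep(NA_real_, length(ids)), ids)
  roots <- ids[lengths(parents) == 0L]
  level[roots] <- 1
  frontier <- roots
  while (length(frontier)) {
    nxt <- unique(unlist(children[frontier], use.names = FALSE))
    nxt <- nxt[is.na(level[nxt])]
    level[nxt] <- min(level[frontier]) + 1
    frontier <- nxt
  }
  df$level <- as.integer(unname(level[df$id]))
  structure(list(terms = df, parents = parents, children = children),
            class = "go_ontology")
}

#' @export
print.go_ontology <- function(x, ...) {
  cat(sprintf("GO ontology: %d terms (%s), max level %d\n", nrow(x$terms),
              paste(names(table(x$terms$namespace)), collapse = ", "),
              max(x$terms$level, na.rm = TRUE)))
  invisible(x)
}

#' All is_a ancestors of a term
#'
#' @param ontology a `go_ontology`.
#' @param id term id.
#' @return Character vector of ancestor ids (excluding the term itself).
#' @export
go_ancestors <- function(ontology, id) {
  seen <- character(0)
  frontier <- ontology$parents[[id]]
  if (is.null(frontier)) stop("go_ancestors: unknown term ", id)
  while (length(frontier)) {
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
    frontier <- unique(unlist(ontology$parents[frontier], use.names = FALSE))
  }
  seen
}

level_slice <- function(ontology, id, level) {
  fam <- c(id, go_ancestors(ontology, id))
  fam[!is.na(match(fam, ontology$terms$id)) &
        ontology$terms$level[match(fam, ontology$terms$id)] == level]
}

#' Read a protein-to-GO mapping table
#'
#' Two-column TSV `subject_id<TAB>GO:id`; `#` comments allowed; duplicate
#' rows are harmless (summaries count distinct ESTs).
#'
#' @param path TSV file.
#' @return Data frame with columns `subject_id`, `go_id`.
#' @export
read_protein2go <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          col.names = c("subject_id", "go_id"),
                          stringsAsFactors = FALSE)
  df
}

#' Summarize GO categories for one or more datasets
#'
#' An EST is annotated when its best hit maps to at least one GO term known
#' to the ontology. Each mapped term is rolled up to the ancestors (or the
#' term itself) sitting at ontology level `level`; per rolled-up term the
#' summary counts distinct annotated ESTs, and the percentage is relative
#' to the dataset's annotated-EST count. An EST can contribute to several
#' categories, so percentages need not sum to 100.
#'
#' @param best_hits one-hit-per-query `blast_hits` from
#'   [best_hit_per_query()].
#' @param protein2go mapping from [read_protein2go()] (or any data frame
#'   with `subject_id`, `go_id`).
#' @param ontology a `go_ontology`.
#' @param level ontology level of the rollup (>= 1; level 2 is the classic
#'   WEGO view).
#' @param datasets named list of EST-accession character vectors.
#' @return A `go_summary` data frame: `go_id`, `namespace`, `name`, then
#'   `count_<label>` and `pct_<label>` per dataset; attribute `annotated`
#'   holds the per-dataset annotated-EST counts.
#' @export
summarize_go <- function(best_hits, protein2go, ontology, level = 2, datasets) {
  stopifnot(level >= 1, is.list(datasets), length(names(datasets)) > 0)
  p2g <- unique(protein2go[, c("subject_id", "go_id")])
  unknown <- setdiff(unique(p2g$go_id), ontology$terms$id)
  if (length(unknown)) {
    warning("summarize_go: skipping ", length(unknown),
            " GO ids not in the ontology (e.g. ", unknown[1], ")")
    p2g <- p2g[!p2g$go_id %in% unknown, , drop = FALSE]
  }
  slice_cache <- new.env(parent = emptyenv())
  slice <- function(id) {
    if (is.null(slice_cache[[id]]))
      assign(id, level_slice(ontology, id, level), envir = slice_cache)
    slice_cache[[id]]
  }
  per_dataset <- lapply(datasets, function(accs) {
    hits <- best_hits[best_hits$qseqid %in% accs, , drop = FALSE]
    rows <- p2g[p2g$subject_id %in% hits$sseqid, , drop = FALSE]
    est_terms <- merge(hits[, c("qseqid", "sseqid")], rows,
                       by.x = "sseqid", by.y = "subject_id")
    annotated <- unique(est_terms$qseqid)
    pairs <- unique(do.call(rbind, lapply(seq_len(nrow(est_terms)), function(r) {
      up <- slice(est_terms$go_id[r])
      if (length(up)) data.frame(est = est_terms$qseqid[r], term = up) else NULL
    })))
    counts <- if (is.null(pairs)) integer(0) else table(pairs$term)
    list(annotated = length(annotated), counts = counts)
  })
  all_terms <- sort(unique(unlist(lapply(per_dataset, function(d) names(d$counts)))))
  idx <- match(all_terms, ontology$terms$id)
  out <- data.frame(go_id = all_terms,
                    namespace = ontology$terms$namespace[idx],
                    name = ontology$terms$name[idx],
                    stringsAsFactors = FALSE)
  for (lab in names(datasets)) {
    d <- per_dataset[[lab]]
    cnt <- as.integer(d$counts[all_terms])
    cnt[is.na(cnt)] <- 0L
    out[[paste0("count_", lab)]] <- cnt
    out[[paste0("pct_", lab)]] <- if (d$annotated > 0) 100 * cnt / d$annotated else 0
  }
  out <- out[order(out$namespace, out$go_id), ]
  rownames(out) <- NULL
  structure(out, level = level,
            annotated = vapply(per_dataset, `[[`, integer(1), "annotated"),
            class = c("go_summary", "data.frame"))
}

#' @export
print.go_summary <- function(x, ...) {
  ann <- attr(x, "annotated")
  cat(sprintf("GO level-%d summary over %d terms; annotated ESTs: %s\n",
              attr(x, "level"), nrow(x),
              paste(names(ann), ann, sep = "=", collapse = ", ")))
  print(as.data.frame(utils::head(x, 12)), row.names = FALSE)
  invisible(x)
}

#' Write a GO summary as TSV
#'
#' @param summary a `go_summary`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_go_summary_tsv <- function(summary, path) {
  utils::write.table(format_tsv_num(as.data.frame(summary)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a GO summary as a grouped bar chart
#'
#' One group of bars per GO term, grouped by namespace, one bar per dataset,
#' percentage of annotated ESTs on a log-scaled axis (the conventional
#' multi-dataset GO category view).
#'
#' @param x a `go_summary`.
#' @param cols bar colors, recycled over datasets.
#' @param ... ignored.
#' @return Invisibly, the plotted percentage matrix.
#' @export
plot.go_summary <- function(x, cols = c("steelblue3", "tomato3", "seagreen3"),
                            ...) {
  pct_cols <- grep("^pct_", names(x), value = TRUE)
  m <- t(as.matrix(x[, pct_cols, drop = FALSE]))
  rownames(m) <- sub("^pct_", "", pct_cols)
  colnames(m) <- paste0(x$name, " [", substr(x$namespace, 1, 1), "]")
  floor_pct <- 0.1   # log axis cannot show zero
  op <- graphics::par(mar = c(10, 4, 3, 1)); on.exit(graphics::par(op))
  graphics::barplot(pmax(m, floor_pct), beside = TRUE, log = "y",
                    col = cols[seq_len(nrow(m))], las = 2, cex.names = 0.6,
                    ylab = "% of annotated ESTs",
                    main = sprintf("GO categories (level %d)", attr(x, "level")))
  graphics::legend("topright", legend = rownames(m), fill = cols[seq_len(nrow(m))],
                   bty = "n")
  invisible(m)
}
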