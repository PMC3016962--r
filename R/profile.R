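#' @title Spatio-temporal expression profiles
#' @name profile
#' @description Per-gene expression profiles over tissues and developmental
#'   stages. The expression measure is transcripts per million (TPM): one
#'   million times the gene's EST count in a pool divided by the pool's total
#'   EST count. Tissue pools and stage pools give the two marginal TPM
#'   vectors; the (tissue, stage) joint pool gives the cell-level TPM, which
#'   degenerates to the marginal definitions on the margins and is the only
#'   denominator that makes cells mutually comparable.
NULL

#' Pool totals for a corpus
#'
#' The TPM denominators: total ESTs per normalized tissue, per normalized
#' stage and per (tissue, stage) cell, unknown-label pools included.
#'
#' @param corpus a deduplicated [est_corpus()].
#' @param vocab_tissue,vocab_stage vocabularies.
#' @return A `pool_sizes` object: list with `tissue` and `stage` named
#'   integer vectors (full vocabulary order plus unknown) and `cell`, an
#'   integer matrix tissue x stage.
#' @export
pool_sizes <- function(corpus, vocab_tissue = default_vocabulary("tissue"),
                       vocab_stage = default_vocabulary("stage")) {
  stopifnot(inherits(corpus, "est_corpus"))
  lt <- c(vocab_tissue$terms, vocab_tissue$unknown_label)
  ls <- c(vocab_stage$terms, vocab_stage$unknown_label)
  ti <- factor(normalize_term(corpus$tissue_raw, vocab_tissue), levels = lt)
  st <- factor(normalize_term(corpus$stage_raw, vocab_stage), levels = ls)
  cell <- unclass(table(ti, st, dnn = NULL))
  storage.mode(cell) <- "integer"
  structure(list(tissue = rowSums(cell), stage = colSums(cell), cell = cell),
            class = "pool_sizes")
}

#' Transcripts per million
#'
#' `1e6 * n / N` in exact floating arithmetic, no rounding. A pool with
#' `N = 0` has no TPM value (no library sampled it) and is an error here;
#' profile builders represent such cells as `NA` instead of calling this.
#'
#' @param n gene EST count in the pool (0 <= n <= N).
#' @param N pool total (> 0). Recycled against `n`.
#' @return Numeric TPM value(s).
#' @export
tpm <- function(n, N) {
  if (any(N <= 0)) stop("tpm: pool total N must be > 0 (N = 0 is 'no data', not TPM 0)")
  if (any(n < 0) || any(n > N)) stop("tpm: need 0 <= n <= N")
  1e6 * n / N
}

#' Build the spatio-temporal profile of one gene
#'
#' Counts the gene's ESTs in every (tissue, stage) cell and converts counts
#' to TPM against the tissue pools, the stage pools and the joint cell
#' pools. Records whose tissue or stage is unmapped fall into the
#' unknown-label row/column, so the cell counts always sum to the gene's
#' EST count. Cells whose pool is smaller than `pool_min` are flagged
#' low-confidence (EST coverage too thin to trust the ratio) but never
#' suppressed; cells with an empty pool carry `NA` TPM.
#'
#' @param gene a `gene_est_set` from [extract_gene()].
#' @param corpus the corpus the pools are computed from (must be the corpus
#'   the gene was extracted from).
#' @param vocab_tissue,vocab_stage vocabularies.
#' @param pool_min minimum pool total for a confident TPM (default 30).
#' @param pools optional precomputed [pool_sizes()] for `corpus`.
#' @return An `st_profile`: list with `cluster_id`, `counts` (tissue x stage
#'   integer matrix), `pools`, `tpm_tissue`, `tpm_stage`, `tpm_cell`,
#'   `low_confidence` (logical matrix) and `pool_min`.
#' @export
build_profile <- function(gene, corpus,
                          vocab_tissue = default_vocabulary("tissue"),
                          vocab_stage = default_vocabulary("stage"),
                          pool_min = 30, pools = NULL) {
  stopifnot(inherits(gene, "gene_est_set"))
  if (is.null(pools)) pools <- pool_sizes(corpus, vocab_tissue, vocab_stage)
  lt <- rownames(pools$cell); ls <- colnames(pools$cell)
  rec <- gene$records
  if (!nrow(rec)) warning("build_profile: gene ", gene$cluster_id,
                          " has no ESTs in the corpus; all-zero profile")
  ti <- factor(normalize_term(rec$tissue_raw, vocab_tissue), levels = lt)
  st <- factor(normalize_term(rec$stage_raw, vocab_stage), levels = ls)
  counts <- unclass(table(ti, st, dnn = NULL))
  storage.mode(counts) <- "integer"
  safe_tpm <- function(n, N) ifelse(N > 0, 1e6 * n / ifelse(N > 0, N, NA), NA_real_)
  structure(list(
    cluster_id = gene$cluster_id,
    counts = counts,
    pools = pools,
    tpm_tissue = safe_tpm(rowSums(counts), pools$tissue),
    tpm_stage = safe_tpm(colSums(counts), pools$stage),
    tpm_cell = matrix(safe_tpm(counts, pools$cell), nrow(counts),
                      dimnames = dimnames(counts)),
    low_confidence = pools$cell > 0 & pools$cell < pool_min,
    pool_min = pool_min),
    class = "st_profile")
}

#' @export
print.st_profile <- function(x, ...) {
  n <- sum(x$counts)
  cat(sprintf("Spatio-temporal profile of %s: %d ESTs over %d tissue x %d stage cells\n",
              x$cluster_id, n, nrow(x$counts), ncol(x$counts)))
  nz <- which(x$counts > 0, arr.ind = TRUE)
  if (nrow(nz)) {
    df <- data.frame(tissue = rownames(x$counts)[nz[, 1]],
                     stage = colnames(x$counts)[nz[, 2]],
                     count = x$counts[nz],
                     tpm = round(x$tpm_cell[nz], 2))
    print(df[order(-df$count), ], row.names = FALSE)
  }
  invisible(x)
}

#' Flatten a profile to a TSV table
#'
#' One row per (tissue, stage) cell with columns `tissue`, `stage`, `count`,
#' `pool`, `tpm`, `low_confidence`, plus marginal rows using the
#' pseudo-label `(all)` on the collapsed axis, so the written file carries
#' the full profile and [read_profile_tsv()] can reconstruct it exactly.
#' Header comments record the cluster id and `pool_min`.
#'
#' @param profile an `st_profile`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  p <- profile
  cells <- expand.grid(tissue = rownames(p$counts), stage = colnames(p$counts),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- data.frame(cells,
                   count = as.vector(p$counts),
                   pool = as.vector(p$pools$cell),
                   tpm = as.vector(p$tpm_cell),
                   low_confidence = as.vector(p$low_confidence))
  marg_t <- data.frame(tissue = names(p$pools$tissue), stage = "(all)",
                       count = rowSums(p$counts), pool = unname(p$pools$tissue),
                       tpm = unname(p$tpm_tissue), low_confidence = NA)
  marg_s <- data.frame(tissue = "(all)", stage = names(p$pools$stage),
                       count = colSums(p$counts), pool = unname(p$pools$stage),
                       tpm = unname(p$tpm_stage), low_confidence = NA)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# cluster_id=%s", p$cluster_id),
               sprintf("# pool_min=%s", format(p$pool_min))), con)
  utils::write.table(format_tsv_num(rbind(df, marg_t, marg_s)), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

format_tsv_num <- function(df) {
  for (col in names(df))
    if (is.double(df[[col]])) {
      v <- sprintf("%.15g", df[[col]])
      v[is.na(df[[col]])] <- "NA"
      df[[col]] <- v
    }
  df
}

#' Re-ingest a profile TSV
#'
#' Inverse of [write_profile_tsv()]: rebuilds the `st_profile` (counts,
#' pools, all three TPM maps, low-confidence flags) from the flat table.
#'
#' @param path TSV written by [write_profile_tsv()].
#' @return An `st_profile`.
#' @export
read_profile_tsv <- function(path) {
  hdr <- readLines(path, n = 2)
  cluster_id <- sub("^# cluster_id=", "", hdr[1])
  pool_min <- as.numeric(sub("^# pool_min=", "", hdr[2]))
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  cells <- df[df$tissue != "(all)" & df$stage != "(all)", ]
  lt <- unique(cells$tissue); ls <- unique(cells$stage)
  as_mat <- function(v, mode = "integer") {
    m <- matrix(v, length(lt), length(ls), dimnames = list(lt, ls))
    if (mode == "integer") storage.mode(m) <- "integer"
    m
  }
  counts <- as_mat(cells$count)
  cellpool <- as_mat(cells$pool)
  marg_t <- df[df$stage == "(all)", ]
  marg_s <- df[df$tissue == "(all)", ]
  pools <- structure(list(
    tissue = stats::setNames(as.integer(marg_t$pool), marg_t$tissue)[lt],
    stage = stats::setNames(as.integer(marg_s$pool), marg_s$stage)[ls],
    cell = cellpool), class = "pool_sizes")
  structure(list(
    cluster_id = cluster_id, counts = counts, pools = pools,
    tpm_tissue = stats::setNames(as.numeric(marg_t$tpm), marg_t$tissue)[lt],
    tpm_stage = stats::setNames(as.numeric(marg_s$tpm), marg_s$stage)[ls],
    tpm_cell = as_mat(as.numeric(cells$tpm), "double"),
    low_confidence = as_mat(as.logical(cells$low_confidence), "logical"),
    pool_min = pool_min), class = "st_profile")
}

#' Plot a profile as a three-dimensional columnar graph
#'
#' Draws one column per (tissue, stage) cell with height proportional to the
#' cell TPM, in an isometric projection; axis order follows the vocabulary
#' (biological) order. Cells with no data draw nothing; low-confidence
#' columns are hatched. Tissues and stages with no signal anywhere are
#' dropped from the axes to keep the graph readable.
#'
#' @param x an `st_profile`.
#' @param col column fill color.
#' @param main title; defaults to the cluster id.
#' @param ... ignored.
#' @return Invisibly, the matrix of plotted TPM values.
#' @export
plot.st_profile <- function(x, col = "steelblue3", main = NULL, ...) {
  z <- x$tpm_cell
  keep_r <- rowSums(x$counts) > 0; keep_c <- colSums(x$counts) > 0
  if (!any(keep_r) || !any(keep_c)) {
    warning("plot.st_profile: empty profile, nothing to draw")
    return(invisible(z))
  }
  z <- z[keep_r, keep_c, drop = FALSE]
  lc <- x$low_confidence[keep_r, keep_c, drop = FALSE]
  z[is.na(z)] <- 0
  nr <- nrow(z); nc <- ncol(z)
  zmax <- max(z); if (zmax <= 0) zmax <- 1
  # isometric projection: u = col - row * 0.5, v = height + (row + col) * slope
  px <- function(i, j) j - 0.45 * i
  py <- function(i, j, h) 0.25 * (i + j) + 2.2 * h / zmax
  op <- graphics::par(mar = c(6, 1, 3, 1)); on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(px(nr, 0) - 1, px(0, nc) + 1),
                 ylim = c(0, py(nr, nc, zmax) + 0.5),
                 axes = FALSE, xlab = "", ylab = "",
                 main = main %||% paste("Spatio-temporal TPM profile:", x$cluster_id))
  w <- 0.35
  for (i in nr:1) for (j in seq_len(nc)) {       # back-to-front
    h <- z[i, j]; if (h <= 0) next
    x0 <- px(i, j); y0 <- py(i, j, 0); y1 <- py(i, j, h)
    dens <- if (lc[i, j]) 25 else NA
    graphics::polygon(c(x0 - w, x0 + w, x0 + w, x0 - w),
                      c(y0, y0, y1, y1), col = col, border = "grey20",
                      density = dens)
    graphics::polygon(c(x0 - w, x0, x0 + w, x0),
                      c(y1, y1 + 0.08, y1, y1 - 0.08),
                      col = "grey85", border = "grey20")
  }
  for (j in seq_len(nc))
    graphics::text(px(nr + 1, j), py(nr + 1.5, j, 0), colnames(z)[j],
                   srt = 45, adj = 1, cex = 0.7, xpd = NA)
  for (i in seq_len(nr))
    graphics::text(px(i, 0) - 0.3, py(i, 0, 0), rownames(z)[i],
                   adj = 1, cex = 0.7, xpd = NA)
  graphics::mtext(sprintf("max TPM = %.1f", max(x$tpm_cell, na.rm = TRUE)),
                  side = 3, cex = 0.8)
  invisible(z)
}
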