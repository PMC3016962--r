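#' @title Seeded synthetic input generator
#' @name synthgen
#' @description Generates every input format the pipeline consumes —
#'   dbEST-style FASTA in three defline dialects, flat EST Source text,
#'   cluster tables with designed expression classes, BLAST tabular files,
#'   OBO ontologies and protein-to-GO maps — together with machine-readable
#'   truth tables, so every stage is testable without any download. All
#'   randomness flows from one integer seed; a fixed seed regenerates
#'   byte-identical files.
NULL

#' Synthetic-corpus configuration
#'
#' Defaults emulate the shape of the public *B. mori* EST collection: 28
#' tissues / 31 stages / 4 sexes / 10 strains with heavy-tailed categorical
#' distributions peaking at three tissues (ovary, wing disk, silk gland) and
#' at the 5th-instar day 3 stage, a 7% record-duplication rate and a 5%
#' missing-metadata rate. All of it is overridable.
#'
#' @param seed integer root seed.
#' @param n_background number of background (non-gene) ESTs.
#' @param genes gene design data frame from [gene_designs()] (or `NULL`).
#' @param tissue_probs,stage_probs,sex_probs,strain_probs named probability
#'   vectors over canonical terms (must sum to 1 within 1e-9). `NULL` uses
#'   the heavy-tailed defaults over the shipped vocabularies.
#' @param dup_rate fraction of records re-emitted as duplicates.
#' @param missing_rate per-background-record probability of one blanked
#'   metadata field.
#' @param noise_rate per-gene-EST probability that the tissue and stage
#'   strings are corrupted to unrecognized tokens (normalizing to the
#'   unknown label) — the messy-submission noise real dbEST records show.
#' @param dialect_probs probabilities of the three defline dialects
#'   (`attr`: `/key="value"`; `colon`: `key: value;`; `library`: clone-library
#'   id plus lookup table).
#' @param seq_len_range min/max synthetic sequence length (sequences are
#'   decorative, for parser tests).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_background = 5000L, genes = NULL,
                         tissue_probs = NULL, stage_probs = NULL,
                         sex_probs = NULL, strain_probs = NULL,
                         dup_rate = 0.07, missing_rate = 0.05,
                         noise_rate = 0,
                         dialect_probs = c(attr = 0.4, colon = 0.4,
                                           library = 0.2),
                         seq_len_range = c(60L, 120L)) {
  heavy_tail <- function(terms, heads) {
    rest <- setdiff(terms, names(heads))
    w <- 0.75 ^ seq_along(rest)
    p <- c(heads, stats::setNames((1 - sum(heads)) * w / sum(w), rest))
    p[terms]
  }
  if (is.null(tissue_probs))
    tissue_probs <- heavy_tail(default_vocabulary("tissue")$terms,
                               c(ovary = 0.149, `wing disk` = 0.146,
                                 `silk gland` = 0.124))
  if (is.null(stage_probs))
    stage_probs <- heavy_tail(default_vocabulary("stage")$terms,
                              c(`5th instar day 3` = 0.312,
                                `5th instar to spinning` = 0.168,
                                `4th instar day 2` = 0.092))
  if (is.null(sex_probs))
    sex_probs <- c(female = 0.27, male = 0.2, mixed = 0.493,
                   undetermined = 0.037)
  if (is.null(strain_probs))
    strain_probs <- heavy_tail(default_vocabulary("strain")$terms,
                               c(Dazao = 0.853))
  for (p in list(tissue_probs, stage_probs, sex_probs, strain_probs))
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0))
      stop("synth_config: axis probabilities must be non-negative and sum to 1")
  for (r in c(dup_rate, missing_rate, noise_rate))
    if (r < 0 || r > 1) stop("synth_config: rates must lie in [0, 1]")
  structure(list(seed = as.integer(seed), n_background = as.integer(n_background),
                 genes = genes, tissue_probs = tissue_probs,
                 stage_probs = stage_probs, sex_probs = sex_probs,
                 strain_probs = strain_probs, dup_rate = dup_rate,
                 missing_rate = missing_rate, noise_rate = noise_rate,
                 dialect_probs = dialect_probs / sum(dialect_probs),
                 seq_len_range = seq_len_range),
            class = "synth_config")
}

#' Design a set of synthetic genes
#'
#' Builds the gene-design table [generate_corpus()] realizes. Classes:
#' `ubiquitous` (two ESTs in every tissue), `tissue_specific` (all ESTs in
#' one target tissue), `stage_specific` (all ESTs in one target stage,
#' spread over four tissues), `mixed` (three tissues x three stages), and
#' `peaked` (60% of ESTs in one designated (tissue, stage) hotspot cell —
#' the catalase-like profile shape).
#'
#' @param n_ubiquitous,n_tissue_specific,n_stage_specific,n_mixed,n_peaked
#'   genes per class.
#' @param support_range min/max ESTs per gene for the non-ubiquitous classes
#'   (ubiquitous genes get two per tissue).
#' @return Data frame with columns `gene_id`, `class`, `target_tissue`,
#'   `target_stage`, `n_est` (`NA` entries are sampled at generation time).
#' @export
gene_designs <- function(n_ubiquitous = 0, n_tissue_specific = 0,
                         n_stage_specific = 0, n_mixed = 0, n_peaked = 0,
                         support_range = c(8L, 20L)) {
  cls <- rep(c("ubiquitous", "tissue_specific", "stage_specific", "mixed",
               "peaked"),
             c(n_ubiquitous, n_tissue_specific, n_stage_specific, n_mixed,
               n_peaked))
  n <- length(cls)
  data.frame(gene_id = sprintf("Syn.%04d", seq_len(n)), class = cls,
             target_tissue = NA_character_, target_stage = NA_character_,
             n_est = NA_integer_,
             support_min = support_range[1], support_max = support_range[2],
             stringsAsFactors = FALSE)
}

sample_terms <- function(n, probs) {
  if (n == 0) return(character(0))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

rand_seq <- function(n, len_range) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"),
                 sample(len_range[1]:len_range[2], 1), replace = TRUE),
          collapse = ""), character(1))
}

realize_gene <- function(design, cfg) {
  tiss <- names(cfg$tissue_probs); stg <- names(cfg$stage_probs)
  n <- design$n_est
  if (is.na(n)) n <- sample(design$support_min:design$support_max, 1)
  tt <- design$target_tissue; ts <- design$target_stage
  switch(design$class,
    ubiquitous = {
      t_lab <- rep(tiss, each = 2)
      data.frame(tissue = t_lab,
                 stage = sample_terms(length(t_lab), cfg$stage_probs))
    },
    tissue_specific = {
      if (is.na(tt)) tt <- sample(tiss, 1, prob = cfg$tissue_probs)
      data.frame(tissue = rep(tt, n), stage = sample_terms(n, cfg$stage_probs))
    },
    stage_specific = {
      if (is.na(ts)) ts <- sample(stg, 1, prob = cfg$stage_probs)
      spread <- sample(tiss, 4)
      data.frame(tissue = rep_len(spread, n), stage = rep(ts, n))
    },
    mixed = {
      data.frame(tissue = rep_len(sample(tiss, 3), n),
                 stage = rep_len(sample(stg, 3), max(n, 1))[seq_len(n)])
    },
    peaked = {
      if (is.na(tt)) tt <- sample(tiss, 1)
      if (is.na(ts)) ts <- sample(stg, 1)
      k <- ceiling(0.6 * n)
      other_t <- sample(setdiff(tiss, tt), n - k, replace = TRUE)
      other_s <- sample_terms(n - k, cfg$stage_probs)
      data.frame(tissue = c(rep(tt, k), other_t),
                 stage = c(rep(ts, k), other_s))
    },
    stop("realize_gene: unknown class ", design$class))
}

write_synth_fasta <- function(records, path, dialect) {
  q <- function(x) ifelse(nzchar(x), x, "")
  defline <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    defline[i] <- switch(dialect[i],
      attr = sprintf('%s /tissue="%s" /dev_stage="%s" /sex="%s" /strain="%s"',
                     r$accession, q(r$tissue_raw), q(r$stage_raw),
                     q(r$sex_raw), q(r$strain_raw)),
      colon = sprintf("%s tissue: %s; dev_stage: %s; sex: %s; strain: %s",
                      r$accession, q(r$tissue_raw), q(r$stage_raw),
                      q(r$sex_raw), q(r$strain_raw)),
      library = sprintf('%s /clone_lib="%s"', r$accession, r$library_id))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0(">", defline, "\n", records$sequence), con, sep = "\n",
             useBytes = TRUE)
  invisible(path)
}

#' Generate a synthetic EST corpus with truth tables
#'
#' Realizes the configured gene designs and background distribution into a
#' corpus written both as flat EST Source text and as FASTA (mixing the
#' three defline dialects), plus a cluster table attributing gene ESTs to
#' their clusters, a clone-library lookup table for the library dialect,
#' and truth TSVs recording every record's true labels and every gene's
#' class and hotspot. Duplicated records are interleaved at a configured
#' rate; gene-EST label noise and background missing-metadata follow the
#' configured rates.
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if needed).
#' @return Invisible list: `paths` (named file paths), `records` (truth data
#'   frame, one row per unique record), `genes` (truth per gene, including
#'   the designed hotspot cell), `n_duplicates`.
#' @export
generate_corpus <- function(config, dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  cfg <- config

  gene_rows <- list(); gene_truth <- list()
  if (!is.null(cfg$genes) && nrow(cfg$genes)) {
    for (g in seq_len(nrow(cfg$genes))) {
      placement <- realize_gene(cfg$genes[g, ], cfg)
      placement$gene_id <- cfg$genes$gene_id[g]
      gene_rows[[g]] <- placement
      cell <- paste(placement$tissue, placement$stage, sep = "\r")
      top <- sort(table(cell), decreasing = TRUE)
      hot <- if (length(top) == 1L || top[1] > top[2])
        strsplit(names(top)[1], "\r", fixed = TRUE)[[1]] else c(NA, NA)
      gene_truth[[g]] <- data.frame(
        gene_id = cfg$genes$gene_id[g], class = cfg$genes$class[g],
        n_est = nrow(placement),
        target_tissue = if (cfg$genes$class[g] == "tissue_specific")
          placement$tissue[1] else cfg$genes$target_tissue[g],
        target_stage = if (cfg$genes$class[g] == "stage_specific")
          placement$stage[1] else cfg$genes$target_stage[g],
        hotspot_tissue = hot[1], hotspot_stage = hot[2],
        stringsAsFactors = FALSE)
      if (cfg$genes$class[g] == "peaked") {
        gene_truth[[g]]$target_tissue <- placement$tissue[1]
        gene_truth[[g]]$target_stage <- placement$stage[1]
      }
    }
  }
  gene_df <- if (length(gene_rows)) do.call(rbind, gene_rows) else
    data.frame(tissue = character(0), stage = character(0),
               gene_id = character(0))

  bg <- data.frame(tissue = sample_terms(cfg$n_background, cfg$tissue_probs),
                   stage = sample_terms(cfg$n_background, cfg$stage_probs),
                   gene_id = rep(NA_character_, cfg$n_background),
                   stringsAsFactors = FALSE)
  rec <- rbind(gene_df[, c("tissue", "stage", "gene_id")], bg)
  n <- nrow(rec)
  rec$sex <- sample_terms(n, cfg$sex_probs)
  rec$strain <- sample_terms(n, cfg$strain_probs)
  rec$accession <- sprintf("SYN%07d", seq_len(n))

  # emitted (raw) strings start as the true canonical labels
  rec$tissue_raw <- rec$tissue; rec$stage_raw <- rec$stage
  rec$sex_raw <- rec$sex; rec$strain_raw <- rec$strain

  is_gene <- !is.na(rec$gene_id)
  noisy <- is_gene & stats::runif(n) < cfg$noise_rate
  rec$tissue_raw[noisy] <- sprintf("unclassified_t%03d", which(noisy))
  rec$stage_raw[noisy] <- sprintf("unclassified_s%03d", which(noisy))
  blank <- !is_gene & stats::runif(n) < cfg$missing_rate
  for (i in which(blank)) {
    f <- sample(c("tissue_raw", "stage_raw", "sex_raw", "strain_raw"), 1)
    rec[[f]][i] <- ""
  }
  rec$noisy <- noisy

  lib_key <- paste(rec$tissue_raw, rec$stage_raw, rec$sex_raw, rec$strain_raw,
                   sep = "\r")
  lib_ids <- stats::setNames(sprintf("LIB%05d", seq_along(unique(lib_key))),
                             unique(lib_key))
  rec$library_id <- unname(lib_ids[lib_key])
  rec$sequence <- rand_seq(n, cfg$seq_len_range)
  rec$dialect <- sample(names(cfg$dialect_probs), n, replace = TRUE,
                        prob = cfg$dialect_probs)

  n_dup <- floor(cfg$dup_rate * n)
  dup_idx <- if (n_dup) sample(n, n_dup) else integer(0)
  emit <- rec[sample(c(seq_len(n), dup_idx)), , drop = FALSE]

  paths <- list(
    est_source = file.path(dir, "est_source.txt"),
    fasta = file.path(dir, "corpus.fasta"),
    clusters = file.path(dir, "clusters.tsv"),
    library_table = file.path(dir, "library_table.tsv"),
    truth_records = file.path(dir, "truth_records.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"))

  write_est_source(est_corpus(emit[, CORPUS_FIELDS]), paths$est_source)
  write_synth_fasta(emit, paths$fasta, emit$dialect)

  parts <- lapply(strsplit(names(lib_ids), "\r", fixed = TRUE),
                  function(p) c(p, rep("", 4 - length(p))))
  lib_tab <- data.frame(library_id = unname(lib_ids), do.call(rbind, parts))
  names(lib_tab)[2:5] <- c("tissue", "stage", "sex", "strain")
  utils::write.table(lib_tab, paths$library_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  cl <- rec[is_gene, c("gene_id", "accession")]
  con <- file(paths$clusters, open = "wb")
  writeLines(paste(cl$gene_id, cl$accession, sep = "\t"), con)
  close(con)

  genes <- if (length(gene_truth)) do.call(rbind, gene_truth) else NULL
  truth <- rec[, c("accession", "gene_id", "tissue", "stage", "sex", "strain",
                   "tissue_raw", "stage_raw", "sex_raw", "strain_raw",
                   "library_id", "dialect", "noisy")]
  utils::write.table(truth, paths$truth_records, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(genes))
    utils::write.table(genes, paths$truth_genes, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(list(paths = paths, records = truth, genes = genes,
                 n_duplicates = n_dup))
}

#' Synthetic BLAST + GO configuration
#'
#' @param seed integer seed (independent of the corpus seed).
#' @param n_proteins number of synthetic protein subjects.
#' @param hit_rate probability a query has any BLAST hit.
#' @param max_decoys maximal number of extra (worse) hits per query.
#' @param tie_rate probability the top e-value is tied between two subjects
#'   (resolved by bit score, occasionally also tied to exercise the
#'   lexicographic rule).
#' @param above_cutoff_rate probability a decoy's e-value exceeds `1e-10`
#'   (so cutoff filtering matters).
#' @param depth is_a depth of each namespace subtree (root = level 1, so
#'   leaves sit at level `depth`).
#' @param branching children per internal term.
#' @param terms_per_protein min/max GO terms mapped per protein.
#' @param enrich_branch_weight multiplier for the designated
#'   molecular-function branch when drawing hits for the first dataset (the
#'   designed enrichment).
#' @param enrich_base_prob probability that a non-enriched query's best hit
#'   falls in the designated branch.
#' @return A `synth_blast_config` list.
#' @export
synth_blast_config <- function(seed = 1L, n_proteins = 60L, hit_rate = 0.9,
                               max_decoys = 4L, tie_rate = 0.1,
                               above_cutoff_rate = 0.25,
                               depth = 4L, branching = 3L,
                               terms_per_protein = c(1L, 3L),
                               enrich_branch_weight = 3,
                               enrich_base_prob = 0.2) {
  structure(as.list(environment()), class = "synth_blast_config")
}

build_synth_ontology <- function(depth, branching) {
  namespaces <- c(biological_process = "GO:1000000",
                  molecular_function = "GO:2000000",
                  cellular_component = "GO:3000000")
  terms <- list(); k <- 0L
  for (ns in names(namespaces)) {
    root <- namespaces[[ns]]
    terms[[root]] <- list(id = root, name = paste(ns, "root"),
                          namespace = ns, parents = character(0), level = 1L)
    frontier <- root
    for (lev in seq_len(depth - 1L)) {
      nxt <- character(0)
      for (p in frontier) for (b in seq_len(branching)) {
        k <- k + 1L
        id <- sprintf("GO:%07d", k)
        terms[[id]] <- list(id = id, name = sprintf("synthetic term %d", k),
                            namespace = ns, parents = p, level = lev + 1L)
        nxt <- c(nxt, id)
      }
      # a few extra is_a edges keep the graph a DAG but not a tree;
      # an extra parent from the same upper level preserves shortest-path levels
      if (length(frontier) > 1L)
        for (id in nxt[seq_len(min(2L, length(nxt)))])
          terms[[id]]$parents <- unique(c(terms[[id]]$parents,
                                          sample(frontier, 1)))
      frontier <- nxt
    }
  }
  terms
}

write_synth_obo <- function(terms, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in terms) {
    writeLines(c("", "[Term]", paste0("id: ", t$id), paste0("name: ", t$name),
                 paste0("namespace: ", t$namespace),
                 if (length(t$parents))
                   paste0("is_a: ", t$parents, " ! parent")), con)
  }
  # one obsolete decoy term, excluded by the loader
  writeLines(c("", "[Term]", "id: GO:9999999", "name: obsolete decoy",
               "namespace: biological_process", "is_obsolete: true"), con)
  invisible(path)
}

#' Generate synthetic BLAST tabular, OBO and protein-to-GO inputs
#'
#' Builds a regular-depth GO DAG over the three namespaces (with a few extra
#' `is_a` edges so it is not a tree), maps synthetic proteins to leaf terms,
#' and emits BLAST tabular hits for the given query sets with a designed
#' best hit per query (engineered e-value and bit-score ties at the
#' configured rate, decoys partly above the e-value cutoff). The first
#' dataset's best hits are biased toward one designated molecular-function
#' branch by `enrich_branch_weight` — the designed enrichment the GO summary
#' should recover.
#'
#' @param config a [synth_blast_config()].
#' @param dir output directory.
#' @param datasets named list of query-accession character vectors; the
#'   first is the enriched one.
#' @return Invisible list: `paths`, `truth_hits` (per query the designed
#'   best subject), `truth_terms` (per term its namespace, level and
#'   parents), `enriched_branch` (ids of the designated branch), plus the
#'   protein grouping.
#' @export
generate_blast_and_go <- function(config, dir, datasets) {
  stopifnot(inherits(config, "synth_blast_config"), length(datasets) >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  terms <- build_synth_ontology(config$depth, config$branching)
  ids <- names(terms)
  level <- vapply(terms, `[[`, integer(1), "level")
  ns <- vapply(terms, `[[`, character(1), "namespace")
  leaves <- ids[level == config$depth]

  # designated enriched branch: descendants of the first child of the MF root
  mf_root <- ids[ns == "molecular_function" & level == 1L]
  mf_children <- ids[vapply(terms, function(t)
    mf_root %in% t$parents, logical(1))]
  branch_head <- sort(mf_children)[1]
  in_branch <- function(id) {
    while (length(id)) {
      if (branch_head %in% id) return(TRUE)
      id <- unique(unlist(lapply(id, function(i) terms[[i]]$parents)))
    }
    FALSE
  }
  branch_terms <- ids[vapply(ids, in_branch, logical(1))]

  prot <- sprintf("PROT%04d", seq_len(config$n_proteins))
  branch_leaves <- intersect(leaves, branch_terms)
  other_leaves <- setdiff(leaves, branch_terms)
  n_branch_prot <- max(2L, round(0.25 * config$n_proteins))
  prot_group <- rep(c("branch", "other"),
                    c(n_branch_prot, config$n_proteins - n_branch_prot))
  p2g <- do.call(rbind, lapply(seq_along(prot), function(i) {
    pool <- if (prot_group[i] == "branch") branch_leaves else other_leaves
    k <- sample(config$terms_per_protein[1]:config$terms_per_protein[2], 1)
    data.frame(subject_id = prot[i],
               go_id = sample(pool, min(k, length(pool))))
  }))

  all_queries <- unique(unlist(datasets, use.names = FALSE))
  enriched <- datasets[[1]]
  hits <- list(); truth <- list()
  for (q in all_queries) {
    if (stats::runif(1) > config$hit_rate) {
      truth[[q]] <- data.frame(qseqid = q, best_subject = NA_character_)
      next
    }
    p_branch <- if (q %in% enriched)
      min(1, config$enrich_base_prob * config$enrich_branch_weight)
    else config$enrich_base_prob
    grp <- if (stats::runif(1) < p_branch) "branch" else "other"
    best <- sample(prot[prot_group == grp], 1)
    e_best <- 10 ^ -stats::runif(1, 15, 40)
    b_best <- round(stats::runif(1, 250, 500), 1)
    rows <- data.frame(qseqid = q, sseqid = best, evalue = e_best,
                       bitscore = b_best)
    if (stats::runif(1) < config$tie_rate) {
      rival <- sample(setdiff(prot, best), 1)
      # same e-value; usually a lower bit score, occasionally a bit-score
      # tie as well so the lexicographic subject rule decides
      tie_bits <- if (stats::runif(1) < 0.2) b_best else b_best - 10
      rows <- rbind(rows, data.frame(qseqid = q, sseqid = rival,
                                     evalue = e_best, bitscore = tie_bits))
      if (tie_bits == b_best && rival < best) best <- rival
    }
    n_dec <- sample(0:config$max_decoys, 1)
    if (n_dec) {
      above <- stats::runif(n_dec) < config$above_cutoff_rate
      e_dec <- ifelse(above, 10 ^ -stats::runif(n_dec, 1, 9),
                      pmin(1e-10, e_best * 10 ^ stats::runif(n_dec, 1, 5)))
      rows <- rbind(rows, data.frame(qseqid = q,
                                     sseqid = sample(prot, n_dec, replace = TRUE),
                                     evalue = e_dec,
                                     bitscore = round(stats::runif(n_dec, 50,
                                                                   b_best - 20), 1)))
    }
    rows <- rows[sample(nrow(rows)), , drop = FALSE]
    hits[[q]] <- rows
    truth[[q]] <- data.frame(qseqid = q, best_subject = best)
  }
  hit_df <- do.call(rbind, hits)
  paths <- list(blast = file.path(dir, "blast.tsv"),
                obo = file.path(dir, "ontology.obo"),
                protein2go = file.path(dir, "protein2go.tsv"),
                truth_hits = file.path(dir, "truth_hits.tsv"),
                truth_terms = file.path(dir, "truth_terms.tsv"))
  blast_lines <- if (is.null(hit_df)) character(0) else
    sprintf("%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3e\t%.1f",
            hit_df$qseqid, hit_df$sseqid, 90, 100L, 5L, 1L, 1L, 100L, 1L,
            100L, hit_df$evalue, hit_df$bitscore)
  con <- file(paths$blast, open = "wb")
  writeLines(c("# synthetic BLAST tabular output", blast_lines), con)
  close(con)
  write_synth_obo(terms, paths$obo)
  utils::write.table(p2g, paths$protein2go, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  truth_hits <- do.call(rbind, truth)
  utils::write.table(truth_hits, paths$truth_hits, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_terms <- data.frame(id = ids, namespace = unname(ns),
                            level = unname(level),
                            parents = vapply(terms, function(t)
                              paste(t$parents, collapse = "|"), character(1)))
  utils::write.table(truth_terms, paths$truth_terms, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(paths = paths, truth_hits = truth_hits,
                 truth_terms = truth_terms, enriched_branch = branch_terms,
                 proteins = data.frame(subject_id = prot, group = prot_group),
                 protein2go = p2g))
}
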