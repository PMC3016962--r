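blast_line <- function(q, s, e, b)
  sprintf("%s\t%s\t95.0\t100\t5\t0\t1\t100\t1\t100\t%g\t%g", q, s, e, b)

test_that("BLAST tabular parsing maps the 12 standard columns and skips comments", {
  f <- withr::local_tempfile(lines = c(
    "# BLASTX 2.x", blast_line("E1", "P1", 1e-20, 300),
    paste0(blast_line("E2", "P2", 1e-5, 80), "\tqcov=0.9")))
  hits <- parse_blast_tab(f)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$qseqid, c("E1", "E2"))
  expect_equal(hits$evalue, c(1e-20, 1e-5))
  expect_equal(hits$bitscore, c(300, 80))
  expect_equal(hits$pident, c(95, 95))
  expect_equal(hits$extra, c(NA, "qcov=0.9"))

  only_comments <- withr::local_tempfile(lines = c("# a", "# b"))
  expect_equal(nrow(parse_blast_tab(only_comments)), 0)

  bad <- withr::local_tempfile(lines = c(
    "# ok", blast_line("E1", "P1", 1e-20, 300),
    "E2\tP2\t95\t100\t5\t0\t1\t100\t1\t100\tnot_a_number\t80"))
  expect_error(parse_blast_tab(bad), "line 3")
})

test_that("e-value filtering is inclusive at the cutoff and idempotent", {
  f <- withr::local_tempfile(lines = c(
    blast_line("E1", "P1", 1e-12, 200), blast_line("E2", "P2", 1e-9, 200),
    blast_line("E3", "P3", 1e-10, 200)))
  hits <- parse_blast_tab(f)
  kept <- filter_hits(hits, 1e-10)
  expect_equal(kept$qseqid, c("E1", "E3"))   # exactly-at-cutoff is kept
  expect_equal(as.data.frame(filter_hits(kept, 1e-10)), as.data.frame(kept))
  # brute-force comprehension oracle
  expect_equal(kept$qseqid, hits$qseqid[hits$evalue <= 1e-10])
})

test_that("best-hit selection applies the e-value, bit-score, subject-id ladder", {
  f <- withr::local_tempfile(lines = c(
    blast_line("E1", "Pworse", 1e-15, 300), blast_line("E1", "Pbest", 1e-20, 200),
    blast_line("E2", "Plow", 1e-15, 250), blast_line("E2", "Phigh", 1e-15, 300),
    blast_line("E3", "Pzed", 1e-15, 300), blast_line("E3", "Pabc", 1e-15, 300)))
  best <- best_hit_per_query(parse_blast_tab(f))
  expect_equal(best$sseqid[best$qseqid == "E1"], "Pbest")   # min e-value
  expect_equal(best$sseqid[best$qseqid == "E2"], "Phigh")   # then max bit score
  expect_equal(best$sseqid[best$qseqid == "E3"], "Pabc")    # then lexicographic
})

test_that("filter and best-hit agree with a per-query sort oracle on 500 queries", {
  bc <- synth_blast_config(seed = 61, n_proteins = 80, tie_rate = 0.25)
  qs <- sprintf("Q%04d", 1:500)
  g <- generate_blast_and_go(bc, withr::local_tempdir(),
                             list(A = qs[1:250], B = qs[251:500]))
  hits <- parse_blast_tab(g$paths$blast)
  best <- best_hit_per_query(filter_hits(hits, 1e-10))
  expect_equal(nrow(best), length(unique(filter_hits(hits, 1e-10)$qseqid)))
  # oracle: full sort per query over the filtered hits
  flt <- hits[hits$evalue <= 1e-10, ]
  for (q in unique(flt$qseqid)) {
    h <- flt[flt$qseqid == q, ]
    h <- h[order(h$evalue, -h$bitscore, h$sseqid), ]
    expect_equal(best$sseqid[best$qseqid == q], h$sseqid[1])
  }
  # and against the generator's designed best subjects
  truth <- g$truth_hits[!is.na(g$truth_hits$best_subject), ]
  expect_equal(best$sseqid[match(truth$qseqid, best$qseqid)],
               truth$best_subject)
})

test_that("OBO loading builds levels and ancestors, excluding obsolete terms", {
  f <- withr::local_tempfile(lines = c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:1", "name: root", "namespace: molecular_function", "",
    "[Term]", "id: GO:2", "name: mid", "namespace: molecular_function",
    "is_a: GO:1 ! root", "",
    "[Term]", "id: GO:3", "name: child", "namespace: molecular_function",
    "is_a: GO:2 ! mid", "",
    "[Term]", "id: GO:9", "name: gone", "namespace: molecular_function",
    "is_obsolete: true"))
  ont <- load_obo(f)
  expect_setequal(ont$terms$id, c("GO:1", "GO:2", "GO:3"))
  expect_equal(sort(go_ancestors(ont, "GO:3")), c("GO:1", "GO:2"))
  expect_equal(ont$terms$level[ont$terms$id == "GO:3"], 3L)

  cyc <- withr::local_tempfile(lines = c(
    "[Term]", "id: GO:1", "name: a", "namespace: molecular_function",
    "is_a: GO:2", "",
    "[Term]", "id: GO:2", "name: b", "namespace: molecular_function",
    "is_a: GO:1"))
  expect_error(load_obo(cyc), "cyclic")

  no_ns <- withr::local_tempfile(lines = c("[Term]", "id: GO:1", "name: a"))
  expect_error(load_obo(no_ns), "namespace")
})

test_that("ancestor sets on a synthetic DAG equal the transitive-closure oracle", {
  bc <- synth_blast_config(seed = 62, depth = 5, branching = 3)  # 363 terms
  g <- generate_blast_and_go(bc, withr::local_tempdir(), list(A = "Q1"))
  ont <- load_obo(g$paths$obo)
  parents <- strsplit(setNames(g$truth_terms$parents, g$truth_terms$id), "|",
                      fixed = TRUE)
  closure <- function(id) {     # brute-force reachability
    seen <- character(0); frontier <- parents[[id]]
    while (length(frontier)) {
      frontier <- setdiff(frontier, seen)
      seen <- union(seen, frontier)
      frontier <- unique(unlist(parents[frontier]))
    }
    seen
  }
  for (id in sample(g$truth_terms$id, 60)) {
    expect_setequal(go_ancestors(ont, id), closure(id))
  }
  # levels match the generator's by-construction truth
  expect_equal(ont$terms$level[match(g$truth_terms$id, ont$terms$id)],
               g$truth_terms$level)
})

test_that("GO summaries count distinct ESTs and tolerate duplicate mappings", {
  obo <- withr::local_tempfile(lines = c(
    "[Term]", "id: GO:1", "name: root", "namespace: molecular_function", "",
    "[Term]", "id: GO:2", "name: L2", "namespace: molecular_function",
    "is_a: GO:1", "",
    "[Term]", "id: GO:3", "name: leafA", "namespace: molecular_function",
    "is_a: GO:2", "",
    "[Term]", "id: GO:4", "name: leafB", "namespace: molecular_function",
    "is_a: GO:2"))
  ont <- load_obo(obo)
  hits <- parse_blast_tab(withr::local_tempfile(lines = c(
    blast_line("E1", "P1", 1e-20, 300))))
  # one EST, two leaf terms sharing one level-2 ancestor: counted once
  p2g <- data.frame(subject_id = c("P1", "P1", "P1"),
                    go_id = c("GO:3", "GO:4", "GO:3"))
  gs <- summarize_go(hits, p2g, ont, level = 2, datasets = list(D = "E1"))
  expect_equal(nrow(gs), 1)
  expect_equal(gs$go_id, "GO:2")
  expect_equal(gs$count_D, 1L)
  expect_equal(gs$pct_D, 100)
  # duplicating mapping rows changes nothing
  gs2 <- summarize_go(hits, rbind(p2g, p2g), ont, 2, list(D = "E1"))
  expect_equal(as.data.frame(gs2), as.data.frame(gs))
  # unknown GO ids are skipped with a warning
  expect_warning(
    summarize_go(hits, rbind(p2g, data.frame(subject_id = "P1",
                                             go_id = "GO:404")),
                 ont, 2, list(D = "E1")), "GO:404")
})

test_that("a level-1 summary reduces to the namespace roots at full coverage", {
  bc <- synth_blast_config(seed = 63, n_proteins = 40, hit_rate = 1,
                           tie_rate = 0)
  qs <- sprintf("Q%03d", 1:60)
  g <- generate_blast_and_go(bc, withr::local_tempdir(), list(A = qs))
  ont <- load_obo(g$paths$obo)
  best <- best_hit_per_query(filter_hits(parse_blast_tab(g$paths$blast)))
  gs <- summarize_go(best, g$protein2go, ont, level = 1, list(A = qs))
  roots <- ont$terms$id[ont$terms$level == 1]
  expect_true(all(gs$go_id %in% roots))
  # per namespace: the root's count is every annotated EST mapping into it
  p2g <- unique(g$protein2go)
  ns_of <- setNames(ont$terms$namespace, ont$terms$id)
  for (r in gs$go_id) {
    ns <- ns_of[[r]]
    expected <- sum(vapply(seq_len(nrow(best)), function(i) {
      terms <- p2g$go_id[p2g$subject_id == best$sseqid[i]]
      any(ns_of[terms] == ns)
    }, logical(1)))
    expect_equal(gs[[paste0("count_A")]][gs$go_id == r], expected)
  }
})

test_that("GO summary plotting draws a grouped log-scale chart", {
  bc <- synth_blast_config(seed = 64)
  qs <- sprintf("Q%03d", 1:40)
  g <- generate_blast_and_go(bc, withr::local_tempdir(),
                             list(A = qs[1:20], B = qs[21:40]))
  ont <- load_obo(g$paths$obo)
  best <- best_hit_per_query(filter_hits(parse_blast_tab(g$paths$blast)))
  gs <- summarize_go(best, g$protein2go, ont, 2,
                     list(A = qs[1:20], B = qs[21:40]))
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f, width = 700, height = 500)
  m <- plot(gs)
  grDevices::dev.off()
  expect_equal(rownames(m), c("A", "B"))
  expect_true(file.size(f) > 0)
})
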