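test_that("pool totals agree with cross-tally marginals", {
  corpus <- mk_corpus(c("ovary", "ovary", "middle silk gland"),
                      c("pupa", "spinning", "pupa"))
  ps <- pool_sizes(corpus)
  expect_equal(ps$tissue[["ovary"]], 2)
  expect_equal(ps$tissue[["middle silk gland"]], 1)
  expect_equal(ps$stage[["pupa"]], 2)
  expect_equal(sum(ps$cell), nrow(corpus))
  ct <- cross_tally(corpus, "tissue", "stage")
  expect_equal(ps$cell[rownames(ct), colnames(ct)], ct)
  # margins of the cell table reproduce the axis totals
  expect_equal(rowSums(ps$cell), ps$tissue)
  expect_equal(colSums(ps$cell), ps$stage)
})

test_that("TPM is 1e6 * n / N with the stated edge behavior", {
  expect_identical(tpm(5, 50000), 100)
  expect_identical(tpm(0, 1000), 0)
  expect_identical(tpm(1000, 1000), 1e6)
  expect_error(tpm(1, 0), "N")
  expect_error(tpm(5, 4), "n <= N")
  # monotone in n at fixed N
  expect_true(all(diff(tpm(0:10, 100)) > 0))
})

test_that("profiles place counts and TPM per cell, margins and unknown routing included", {
  bg <- mk_background(30)   # every tissue pool = 30, well above none
  gene_rec <- mk_corpus(rep("fat body", 2), rep("5th instar day 3", 2), prefix = "G")
  corpus <- bind_corpora(bg, gene_rec)
  tab <- cluster_table(rep("g1", 2), tail(corpus$accession, 2))
  prof <- build_profile(extract_gene(corpus, tab, "g1"), corpus)
  n_cell <- prof$counts["fat body", "5th instar day 3"]
  N_cell <- prof$pools$cell["fat body", "5th instar day 3"]
  expect_equal(n_cell, 2L)
  expect_equal(prof$tpm_cell["fat body", "5th instar day 3"], 1e6 * n_cell / N_cell)
  expect_equal(prof$tpm_tissue[["fat body"]],
               1e6 * 2 / prof$pools$tissue[["fat body"]])
  expect_true(all(is.na(prof$tpm_cell[prof$pools$cell == 0])))
  expect_equal(sum(prof$counts), 2)

  # a record with unmapped stage routes to the unknown column, not nowhere
  odd <- bind_corpora(bg, mk_corpus("head", "not a stage", prefix = "G"))
  tab2 <- cluster_table("g2", tail(odd$accession, 1))
  prof2 <- build_profile(extract_gene(odd, tab2, "g2"), odd)
  expect_equal(prof2$counts["head", "uncharacterized"], 1L)
  expect_equal(sum(prof2$counts), 1)
  expect_equal(rowSums(prof2$counts)[["head"]], 1)

  # low-confidence flag marks thin pools without suppressing them
  expect_true(all(prof$low_confidence[prof$pools$cell > 0 &
                                        prof$pools$cell < 30]))
  expect_false(any(prof$low_confidence[prof$pools$cell >= 30]))
})

test_that("zero-EST genes give a valid all-zero profile with a warning", {
  corpus <- mk_background(5)
  tab <- cluster_table("gx", "ABSENT1")
  expect_warning(prof <- build_profile(extract_gene(corpus, tab, "gx"), corpus),
                 "no ESTs")
  expect_equal(sum(prof$counts), 0)
})

test_that("per-gene TPM sums to one million over a fully partitioned pool", {
  # every EST of the ovary/pupa cell belongs to exactly one of three genes
  cell_rec <- mk_corpus(rep("ovary", 60), rep("pupa", 60), prefix = "G")
  corpus <- bind_corpora(mk_background(30), cell_rec)
  accs <- tail(corpus$accession, 60)
  tab <- cluster_table(rep(c("gA", "gB", "gC"), c(10, 20, 30)), accs)
  cellN <- pool_sizes(corpus)$cell["ovary", "pupa"]
  tpms <- vapply(c("gA", "gB", "gC"), function(id)
    build_profile(extract_gene(corpus, tab, id), corpus)$tpm_cell["ovary", "pupa"],
    numeric(1))
  # background ESTs also sit in this cell, so gene TPMs sum below 1e6 ...
  expect_lte(sum(tpms), 1e6)
  # ... and ratios are exact for the partitioned part
  expect_equal(sum(tpms), 1e6 * 60 / cellN, tolerance = 1e-9)
  expect_equal(unname(tpms / sum(tpms)), c(10, 20, 30) / 60, tolerance = 1e-12)
})

test_that("TPM is invariant under whole-corpus duplication", {
  cfg <- synth_config(seed = 41, n_background = 800, dup_rate = 0,
                      genes = gene_designs(0, 2, 2, 2))
  g <- generate_corpus(cfg, withr::local_tempdir())
  corpus <- deduplicate(parse_est_source(g$paths$est_source))
  tab <- load_cluster_table(g$paths$clusters)
  # duplicate every record (fresh accessions) and every cluster membership
  df <- as.data.frame(corpus)
  twin <- df; twin$accession <- paste0(twin$accession, "dup")
  doubled <- est_corpus(rbind(df, twin))
  tab2 <- cluster_table(rep(rep(names(tab$clusters), lengths(tab$clusters)), 2),
                        c(unlist(tab$clusters),
                          paste0(unlist(tab$clusters), "dup")))
  for (id in names(tab$clusters)) {
    p1 <- build_profile(extract_gene(corpus, tab, id), corpus)
    p2 <- build_profile(extract_gene(doubled, tab2, id), doubled)
    expect_equal(p2$tpm_cell, p1$tpm_cell)
    expect_equal(p2$tpm_tissue, p1$tpm_tissue)
    expect_equal(p2$tpm_stage, p1$tpm_stage)
  }
})

test_that("profile counts equal a brute-force nested-loop recount", {
  cfg <- synth_config(seed = 42, n_background = 900, dup_rate = 0,
                      genes = gene_designs(1, 1, 1, 1))
  g <- generate_corpus(cfg, withr::local_tempdir())
  corpus <- deduplicate(parse_est_source(g$paths$est_source))
  expect_lte(nrow(corpus), 1000 + sum(table(g$records$gene_id)))
  tab <- load_cluster_table(g$paths$clusters)
  vt <- default_vocabulary("tissue"); vs <- default_vocabulary("stage")
  for (id in names(tab$clusters)) {
    prof <- build_profile(extract_gene(corpus, tab, id), corpus, vt, vs)
    oracle <- matrix(0L, nrow(prof$counts), ncol(prof$counts),
                     dimnames = dimnames(prof$counts))
    for (i in seq_len(nrow(corpus))) {
      if (!corpus$accession[i] %in% tab$clusters[[id]]) next
      a <- normalize_term(corpus$tissue_raw[i], vt)
      b <- normalize_term(corpus$stage_raw[i], vs)
      oracle[a, b] <- oracle[a, b] + 1L
    }
    expect_identical(prof$counts, oracle)
  }
})

test_that("designed hotspot cells are recovered as the profile argmax", {
  cfg <- synth_config(seed = 43, n_background = 2000, dup_rate = 0,
                      genes = gene_designs(n_peaked = 40,
                                           support_range = c(10, 16)))
  g <- generate_corpus(cfg, withr::local_tempdir())
  corpus <- deduplicate(parse_est_source(g$paths$est_source))
  tab <- load_cluster_table(g$paths$clusters)
  for (k in seq_len(nrow(g$genes))) {
    prof <- build_profile(extract_gene(corpus, tab, g$genes$gene_id[k]), corpus)
    top <- which(prof$counts == max(prof$counts), arr.ind = TRUE)
    expect_equal(nrow(top), 1)
    expect_equal(rownames(prof$counts)[top[1]], g$genes$hotspot_tissue[k])
    expect_equal(colnames(prof$counts)[top[2]], g$genes$hotspot_stage[k])
  }
})

test_that("a profile survives the TSV round trip exactly", {
  cfg <- synth_config(seed = 44, n_background = 600, dup_rate = 0,
                      genes = gene_designs(0, 1, 0, 1))
  g <- generate_corpus(cfg, withr::local_tempdir())
  corpus <- deduplicate(parse_est_source(g$paths$est_source))
  tab <- load_cluster_table(g$paths$clusters)
  prof <- build_profile(extract_gene(corpus, tab, "Syn.0001"), corpus)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(prof, f)
  back <- read_profile_tsv(f)
  expect_equal(back$cluster_id, prof$cluster_id)
  expect_equal(back$counts, prof$counts)
  expect_equal(back$pools$cell, prof$pools$cell)
  expect_equal(back$pools$tissue, prof$pools$tissue)
  expect_equal(back$pools$stage, prof$pools$stage)
  expect_equal(back$tpm_cell, prof$tpm_cell)
  expect_equal(back$tpm_tissue, prof$tpm_tissue)
  expect_equal(back$tpm_stage, prof$tpm_stage)
  expect_equal(back$low_confidence, prof$low_confidence)
  expect_equal(back$pool_min, prof$pool_min)
})

test_that("profile plotting draws without error and warns on empty profiles", {
  corpus <- bind_corpora(mk_background(10),
                         mk_corpus(rep("midgut", 3), rep("spinning", 3)))
  tab <- cluster_table(rep("g1", 3), tail(corpus$accession, 3))
  prof <- build_profile(extract_gene(corpus, tab, "g1"), corpus, pool_min = 5)
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f, width = 600, height = 400)
  expect_silent(plot(prof))
  grDevices::dev.off()
  expect_true(file.size(f) > 0)
  tab0 <- cluster_table("g0", "NOPE1")
  prof0 <- suppressWarnings(build_profile(extract_gene(corpus, tab0, "g0"), corpus))
  grDevices::png(withr::local_tempfile(fileext = ".png"))
  expect_warning(plot(prof0), "empty")
  grDevices::dev.off()
})
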