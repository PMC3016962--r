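# Shared fixture builders. All corpora are built in code; nothing is stored.

# est_corpus from parallel label vectors (raw strings = canonical labels)
mk_corpus <- function(tissues, stages, sexes = "mixed", strains = "Dazao",
                      prefix = "T") {
  n <- max(length(tissues), length(stages))
  est_corpus(data.frame(
    accession = sprintf("%s%05d", prefix, seq_len(n)),
    tissue_raw = rep_len(tissues, n), stage_raw = rep_len(stages, n),
    sex_raw = rep_len(sexes, n), strain_raw = rep_len(strains, n),
    stringsAsFactors = FALSE))
}

# deterministic background giving every tissue and stage a pool >= n_each;
# tissues and stages are crossed round-robin so cell pools are spread
mk_background <- function(n_each = 30,
                          tissues = default_vocabulary("tissue")$terms,
                          stages = default_vocabulary("stage")$terms) {
  tt <- rep(tissues, each = n_each)
  ss <- rep_len(stages, length(tt))
  mk_corpus(tt, ss, prefix = "BG")
}

# stack corpora, reassigning unique accessions
bind_corpora <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  df$accession <- sprintf("C%06d", seq_len(nrow(df)))
  est_corpus(df)
}

# independent recount of an axis tally from a generator truth table:
# blank or unrecognized raw values fall into the unknown label
oracle_axis_counts <- function(truth, axis, unknown = "uncharacterized") {
  raw <- truth[[paste0(axis, "_raw")]]
  lab <- ifelse(!nzchar(raw) | startsWith(raw, "unclassified"),
                unknown, truth[[axis]])
  counts <- integer(0)
  for (v in lab) {                       # deliberate brute-force loop
    if (is.na(counts[v])) counts[v] <- 0L
    counts[v] <- counts[v] + 1L
  }
  counts
}
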