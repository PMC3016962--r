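---
title: "Electronic spatio-temporal expression profiles from EST collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electronic spatio-temporal expression profiles from EST collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

An Expressed Sequence Tag (EST) is a single-pass read of a transcribed cDNA
clone. Under random cDNA sampling, the number of ESTs a gene contributes to
a library is, to first order, proportional to the gene's transcript
abundance in the library's source material. A collection of EST records
annotated with tissue and developmental stage therefore supports an
"electronic" expression profile: count the ESTs of a gene in each pool of
the collection and normalize by the pool's depth.

The expression measure is transcripts per million. For a gene with `n` ESTs
in a pool containing `N` ESTs in total,

```
TPM = 1e6 * n / N
```

computed in exact floating arithmetic with no rounding. Three families of
pools are used: per-tissue pools, per-stage pools, and the joint
(tissue, stage) cell pools. The two marginal TPM vectors are the classical
per-axis digital expression measures; the cell-level TPM uses the joint
pool as its denominator. That choice is deliberate: it is the only
denominator that makes cells mutually comparable, and it degenerates to the
marginal definitions when a profile is collapsed onto either axis. All
three are emitted side by side, so an analysis committed to either marginal
reading can reproduce it directly.

Two conventions matter for interpretation:

* A pool with `N = 0` has *no* TPM value (`NA`), never zero. Absence of a
  library is not absence of expression.
* Cells whose pool holds fewer than `pool_min` ESTs (default 30) are
  flagged low-confidence but never suppressed. EST sampling is shallow and
  uneven; the flag tells the reader which ratios rest on thin denominators
  while keeping the data visible.

## Metadata normalization

dbEST submissions carry free-text library metadata in inconsistent
dialects. Parsing and normalization are kept strictly separate:

* **Parsing** stores raw strings verbatim. FASTA deflines are matched by an
  ordered, configurable regular-expression rule set covering the
  `/tissue="..."` attribute style and the `tissue: ...;` clause style, with
  an optional clone-library lookup table as a fallback for deflines that
  carry only a library id. The flat "EST Source" format (one EST per line,
  space-separated accession / tissue / stage / sex / strain) is read and
  written losslessly: internal spaces become underscores on write and empty
  fields are written as `-`, so parse-after-write is the identity.
* **Normalization** maps raw strings onto controlled vocabularies by exact
  lookup after canonicalization (lowercase, trimmed, underscores and
  whitespace runs folded to single spaces). There is no fuzzy matching:
  every mapping is auditable, and an unmapped value becomes the unknown
  label `uncharacterized` — a real category in every tally, since
  uninformative submissions are part of the data. Labels such as
  `whole body` are canonical terms of their own, distinct from the unknown
  label, because they are genuine (if uninformative) annotations.

The shipped vocabularies cover *Bombyx mori* with 28 tissue types, 31
developmental stages in temporal order, 4 sex categories and 10 strains.
The named anchor terms (ovary, silk gland and its middle/posterior/anterior
subregions, wing disk, fat body, microbe-infected fat body, pheromone
gland, prothoracic gland, midgut, head, malpighian tubule, testis; the
instar/day stages, spinning, pupal days) reflect the tissues and stages
most heavily represented in the public silkworm EST collection; the
remainder of each list is a realistic synthetic complement chosen once to
reach those totals. Vocabularies are plain YAML data, so the engine applies
unchanged to any species.

Deduplication is accession-level: the first occurrence wins, the rest are
counted in the corpus provenance. Sequence-level redundancy removal
(collapsing distinct accessions with identical sequences) would be a
different operation and is deliberately out of scope.

## Specificity classification

Per gene, two statistics are computed on each axis from the profile:

* **dominance** — the largest single-category share of the gene's ESTs;
* **breadth** — the fraction of *qualifying* pools (total ≥ `pool_min`) in
  which the gene is detected at all.

The decision ladder is deterministic: support below `min_support` →
`insufficient_data`; tissue dominance ≥ `dominance` → `tissue_specific`;
stage dominance ≥ `dominance` → `stage_specific`; tissue breadth ≥
`breadth` → `ubiquitous`; otherwise `mixed`. Defaults: `min_support = 3`,
`dominance = 0.95`, `breadth = 0.80`, `pool_min = 30`; all four are exposed
as parameters because no quantitative consensus definition of
"exclusively expressed" or "nearly all tissues" exists.

Three design choices were genuinely open and are worth recording:

* **Tissue precedence.** When both dominances pass (a gene confined to one
  tissue sampled at a single stage), the call is `tissue_specific`. EST
  libraries confound the two axes — a tissue dissected at one time point
  dominates both margins — and tissue identity is the more reproducible
  attribute. Both dominances are reported in every call, so the tie remains
  auditable.
* **The unknown label is excluded from dominance and breadth.** An EST
  whose library did not state its tissue is evidence for no tissue; letting
  the `uncharacterized` pool compete as if it were a tissue would
  misclassify genes whose annotations are merely incomplete. Unknown-label
  ESTs still count toward support.
* **Breadth counts only well-sampled pools.** An unsampled or barely
  sampled tissue cannot count against ubiquity: detection in a pool of 5
  ESTs is a coin flip, so pools below `pool_min` are removed from the
  breadth denominator.

## BLAST annotation and GO rollup

The package consumes precomputed BLASTx tabular output (standard 12
columns, comments tolerated, extra columns retained opaquely); it never
executes BLAST. Filtering keeps hits with e-value ≤ the cutoff (inclusive —
"cutoff" conventionally includes the boundary; default `1e-10`). The best
hit per query is the minimum e-value, ties broken by maximum bit score,
then by lexicographically smallest subject id: a standard, fully
deterministic reading of "the most meaningful match".

GO category summaries follow the classic multi-dataset level plot. The
ontology is read from OBO (`[Term]` stanzas; obsolete terms dropped; only
`is_a` edges traversed, no `part_of`; the graph must be acyclic). A term's
level is one plus the shortest `is_a` distance from its namespace root —
the simplest defensible level semantics, exposed as a parameter so other
conventions can be swapped in. For a summary at level *L*, each mapped term
is rolled up to its level-*L* ancestors (or itself), and per rolled-up term
the count is of *distinct* ESTs, with percentages relative to the
dataset's annotated-EST count. Percentages need not sum to 100 (one EST can
sit under several categories), and duplicated mapping rows cannot inflate
anything. At level 1 the summary reduces to the three namespace roots
covering every EST annotated into each namespace — a useful self-check.
The plot is a grouped bar chart per namespace with the percentage axis
log-scaled, as is conventional for this view.

## The synthetic-data generator

The generator exists so that every stage of the pipeline is testable
against machine-readable truth without any download. Its defaults emulate
the documented shape of the public silkworm EST collection: heavy-tailed
categorical distributions with three dominant tissues (ovary ≈ 14.9%,
wing disk ≈ 14.6%, silk gland ≈ 12.4%), a dominant stage
(5th-instar day 3 ≈ 31.2%), one dominant strain (Dazao ≈ 85.3%), mixed sex
≈ 49.3%, a 7% duplicate-record rate and a 5% missing-metadata rate. These
defaults were fixed once, from the documented corpus structure, and are not
tuned thereafter.

Designed gene classes realize the specificity definitions directly:
ubiquitous genes place two ESTs in every tissue; tissue-specific genes put
every EST in one target tissue; stage-specific genes put every EST in one
stage spread over four tissues; mixed genes occupy three tissues × three
stages; "peaked" genes concentrate 60% of their ESTs in one designated
(tissue, stage) hotspot cell — the shape of a stress-response gene peaking
in the microbe-infected fat body. Truth tables record every record's true
labels and every gene's class and hotspot.

The label-noise model corrupts a gene EST's tissue and stage strings into
unrecognized tokens, which normalize to the unknown label. This emulates
the dominant real failure mode of EST metadata — heterogeneous submissions
with unparseable or missing fields — rather than cross-contamination
between correctly spelled labels, which dissection-based libraries rarely
produce. Under this model, and with the unknown label excluded from
dominance, the measured class recovery on 500 designed genes is 100%
noiseless and stays above 90% at a 10% corruption rate.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: correlated library structure (all ESTs
of one submission sharing one metadata vector and its idiosyncratic
spelling), sequencing error and chimeric reads (sequences are decorative
random nucleotides), cloning-bias between transcripts, and genuinely
ambiguous tissue terms that a curator would have to adjudicate. Real-data
performance hinges on vocabulary curation quality, which is exactly why
vocabularies are editable data rather than code.

All randomness flows from one integer seed through R's default generator
in a fixed consumption order, so a fixed seed regenerates byte-identical
files; analysis stages draw no random numbers at all, and the pipeline
writes a SHA-256 manifest so end-to-end determinism is checkable from the
outside. Figures are drawn by the S3 `plot` methods on request; the
file-based pipeline emits TSVs only, which keeps manifests bit-stable.

## Numerical choices and degenerate inputs

* TPM is computed as `1e6 * n / N` directly; no logarithms, pseudocounts
  or rounding anywhere in the pipeline.
* `tpm()` rejects `N = 0` and `n > N`; profile construction represents
  empty pools as `NA` instead of calling it.
* Empty corpora yield empty distributions with a warning, not errors;
  genes with zero mapped ESTs yield valid all-zero profiles with a warning
  and classify as `insufficient_data`.
* Ties in the best-hit ladder and in dominance argmaxes resolve
  deterministically (lexicographic subject id; vocabulary order).
* Profile TSVs print doubles with 15 significant digits, enough for exact
  round-trip re-ingestion at double precision.

## Problem sizes

The shipped tests run the tally oracle at 20,000 records, specificity
recovery at 500 genes (twice: noiseless and 10% noise), best-hit selection
at 500 queries, the ancestor oracle at 363 ontology terms, and the
enrichment-direction check over 100 seeded replicates — sizes at which
every property is measured comfortably on a single core while exercising
realistic skew.

## Known limitations

* EST counts are a biased expression estimate at low coverage; TPM
  normalization cannot repair a pool of ten ESTs. The low-confidence flag
  marks, but does not model, that uncertainty.
* Accession-level deduplication does not collapse resubmitted identical
  sequences under new accessions.
* No differential-expression statistics are computed between pools; the
  package profiles and classifies, it does not test.
* GO levels via shortest `is_a` paths disagree with conventions that use
  longest paths or include `part_of`; the level parameter and the pluggable
  ontology loader localize that choice.
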