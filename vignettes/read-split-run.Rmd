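---
title: "Detecting short non-canonical splice junctions with rsrun"
author: "rsrun authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting short non-canonical splice junctions with rsrun}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsrun)
```

## The problem

Spliceosomal splicing leaves recognisable signals — GT/AG dinucleotides,
annotated donor/acceptor sites — that spliced aligners exploit. Cytoplasmic,
enzyme-mediated excisions do not: the canonical example is IRE1α removing a
26 nt segment from *Xbp1* mRNA during the unfolded protein response. Reads
spanning such an excision are contiguous in the transcript but split on the
genome, carry no splice-site motif, and the excised segment is far shorter
than a typical intron. `rsrun` detects them from the one unambiguous signal
that remains: an otherwise unmappable read whose two pieces align colinearly
with a short genomic gap between them.

## The procedure and its assumptions

The pipeline has six stages (reference construction, first-pass alignment,
exhaustive splitting, second-pass alignment, matched-pair assembly,
clustering/filtering), plus a comparative subtraction and a
parameter-response model. The stages assume:

* **Uniform read length.** The split-enumeration arithmetic and the flank
  rule both presume one read length per run; input validation enforces it.
* **Ungapped end-to-end alignment.** Both passes place whole queries
  without indels. Half placement is exact-match in the builtin aligner; an
  external bowtie-1-compatible aligner may tolerate mismatches at the
  caller's discretion.
* **Colinearity.** The two halves of a splicing read occur on the same
  chromosome and strand, in read order. Trans-splicing, fusions and
  inversions are out of scope.
* **Coordinates.** 0-based, half-open everywhere internally and in BED
  output; knownGene input already uses this convention. A junction is the
  excised interval `[leftEnd, rightStart)`, so spliced length is exactly
  `rightStart - leftEnd` with no ±1 bookkeeping.

### Reference construction

Each adjacent exon pair of each gene yields one flank record: the terminal
`readLength - 4` bases of the upstream exon joined to the initial
`readLength - 4` bases of the downstream exon. Four bases short of the read
length means a read can only align to the record if it overhangs the
boundary by at least 5 bases on one side — a placement that genuinely
witnesses the annotated junction. Flanks are truncated at short exons
rather than extended into the intron (extension would fabricate chimeric
sequence), and junctions shared by overlapping isoforms are emitted once to
avoid self-inflicted multi-mapping. Only adjacent exon pairs are generated;
exon-skipping junction references are not, which keeps the pass-1 reference
small and matches the pipeline's focus on short excisions rather than
generic alternative splicing.

Flank ids embed gene, chromosome and both boundary coordinates
(`|jct|gene|chrom|leftEnd|rightStart`), so known-junction annotation needs
no side table; the `|jct|` prefix is reserved and cannot collide with
chromosome names.

## Parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `MS` (bp) | minimum split size: both halves of a split must be at least this long | 8 | below ~8 bp a half matches by chance too often to place; sensible values run up to a third of the read length |
| `MD` (bp) | maximum candidate distance: largest admissible gap | 40000 | of the order of an average gene length, on the premise that both halves land in one gene |
| `minCD` (bp) | minimum candidate distance, inclusive | 2 | a gap of 2 is the smallest reportable excision; both ends of the window are inclusive |
| `BB` (bp) | boundary buffer: positional tolerance when matched pairs support one another, when junctions are matched to the annotation, and when junction sets are compared | 5 | small boundary jitter tolerated; more would blur distinct events |
| `minSupport` | minimum distinct supporting reads | 2 | one read is never corroboration |
| `maxGoodAlignments` | suppression threshold for multi-mappers | 8 | a read placed more often is treated as ambiguous repeat sequence |

Defaults mirror the 33 bp thapsigargin-treatment configuration of the
motivating MEF experiments; 77 bp dithiothreitol-style runs would raise
`MS` accordingly.

Two deliberate semantic choices sit behind these knobs. First, a read with
more than `maxGoodAlignments` placements is *discarded*, not passed on as
unmapped: it is mapped, merely ambiguously, so it is not a splicing
candidate. Second, junction support counts **distinct reads**, not matched
pairs: one read splitting admissibly at several offsets around the same
junction contributes several matched pairs but only one independent
observation. (Whether the historical implementations counted pairs or reads
is not documented; distinct reads is the conservative reading, and anyone
reconciling against legacy output should check this first.)

## Numerical and algorithmic choices

* **Matched-pair search** is grouped by read and split offset, so cost is
  quadratic only within one read's placements instead of across the whole
  half pool; a brute-force all-pairs scan over every half alignment serves
  as the test oracle and the two are verified set-identical on randomized
  instances.
* **Clustering** is single linkage within each (chromosome, strand, spliced
  length) stratum: sort by left boundary, link while consecutive steps are
  at most `BB`. Equal spliced length is required exactly — a 26 nt and a
  27 nt excision at one locus are different events. The cluster
  representative is the modal (leftEnd, rightStart); ties break toward the
  smallest leftEnd, making output deterministic across platforms. With
  equal lengths enforced, bounding the left-boundary difference bounds the
  right one identically, so no separate right-boundary tolerance exists.
* **Strand handling.** On the reverse strand the read-order upstream half
  sits at the larger genomic coordinate; coordinates are normalised to
  genomic orientation before clustering, so case/control comparison is
  strand-agnostic.
* **Builtin aligner.** Exact substring search over both strands,
  implemented as a constant-width prefix index (`Biostrings` `PDict` over
  min-width prefixes) with vectorised full-length verification. It is
  deliberately mismatch-free: it doubles as the testing oracle, and the
  synthetic fixtures are error-free so that tests exercise the splitting
  logic rather than aligner heuristics. External bowtie-1-compatible
  aligners are supported behind the same contract (tabular and SAM output
  both parse to identical records).
* **Comparison tolerance** reuses `BB` rather than introducing a fourth
  spatial parameter, and subtraction is taken against the *filtered*
  control set: a control junction must itself be credible (pass
  `minSupport`) to cancel a case junction.
* **Degenerate inputs.** Reads shorter than `2*MS` produce zero splits;
  empty junction sets subtract and report cleanly; an empty flank set makes
  the expanded genome identical to the genome; rank-deficient model designs
  are refused naming the offending predictor.
* **Replicates** are processed per file and unioned after junction calling,
  with supporting reads pooled under replicate-prefixed ids; no merging
  rule before calling is assumed. Paired-end files are pooled as
  independent single-end reads — no mate-aware constraint is applied, since
  the gap test needs no insert-size model.
* **Per-chromosome chunking** exists for memory-bounded runs; matched pairs
  never span chromosomes, so chunked and unchunked runs are byte-identical
  (tested).

## The parameter-response model

Junction counts across a grid of (MS, MD, BB) settings are summarised by
ordinary least squares with identity link and main effects only:
`count = b0 + b1*MS + b2*MD + b3*BB`. This is a descriptive response
surface, not a count model — a log-link model is deliberately out of scope,
and no interactions are fitted. Any grid of at least 4 runs with a
full-rank design is accepted. Predictions are clipped at zero for
reporting. Grid runs share alignment passes: halves split at the smallest
MS serve every larger MS by offset filtering, which also guarantees the
fitted MS trend reflects candidate-set containment (counts cannot grow as
MS rises), hence `b1 <= 0` on pipeline-generated grids.

## What the synthetic generator emulates — and what it does not

`make_genome()` / `make_case_control_reads()` build: two 6 kb chromosomes
(rejection-sampled so every 33-mer is strand-unique, making exact alignment
unambiguous), a three-exon gene with canonical introns, a single-exon
target gene, and Het/KO read pools at 20× coverage in which only the Het
pool samples a transcript with a 26 nt segment excised at a fixed position.
Reads are exact substrings with constant Phred-40 qualities; the generator
checks and certifies its own guarantee (at least `minSupport` spanning
reads at two or more distinct offsets in Het, zero spliced-form reads in
KO) and the truth table records the engineered coordinates.

Passing tests on this fixture demonstrates coordinate-exact recovery of a
known excision under ideal conditions. It does **not** demonstrate
robustness to sequencing error, expression-level variation, repeat-dense
genomes, or aligner mismatch policies — real data add all four. Fixture
sizes (6 kb chromosomes, ~2000 reads, a 3×3×3 model grid and a 2×2×3
pipeline grid in the test suite) were chosen as the smallest at which every
pipeline stage, both comparison directions and the model fit are exercised
with non-trivial cardinalities.

## Known limitations

* Mismatch-intolerant matching in builtin mode understates support on
  error-prone data; use an external aligner there.
* Short halves near `MS = 8` multi-map in large genomes; the suppression
  threshold then governs sensitivity, and raising `MS` is usually the
  better lever.
* Junctions between non-adjacent exons are reported as novel, since the
  flank reference covers adjacent pairs only.
* The subtraction is presence/absence at a tolerance; it does not test
  differential support statistically.

## A complete run

```{r, eval = FALSE}
dir <- tempfile("rsr_")
paths <- make_synthetic_dataset(dir, seed = 26)
config <- rsr_config(mode = "comparative",
                     fastqA = paths$het, fastqB = paths$ko,
                     genome = paths$genome, knownGenes = paths$knownGenes,
                     params = rsr_params(), out = file.path(dir, "out"))
res <- run_pipeline(config)
res$uniqueToA          # the engineered junction, ranked first
read.delim(file.path(dir, "out", "comparison", "side_by_side.tsv"))
```
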