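# Shared fixtures and independent oracles for the test suite.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A handcrafted two-chromosome genome with one two-exon gene whose exons are
# long enough for untruncated 29 bp flanks (readLength 33).
toy_ref <- function() {
  set.seed(421)
  genome <- Biostrings::DNAStringSet(c(chrA = rand_dna(400),
                                       chrB = rand_dna(300)))
  genes <- data.frame(
    name = "g1", chrom = "chrA", strand = "+",
    txStart = 50L, txEnd = 250L, exonCount = 2L,
    exonStarts = I(list(c(50L, 150L))), exonEnds = I(list(c(100L, 250L))),
    stringsAsFactors = FALSE)
  list(genome = genome, genes = genes)
}

write_known_genes_text <- function(rows, path) {
  writeLines(rows, path)
  path
}

# Brute-force matched-pair oracle: all-pairs scan over every half alignment
# (no grouping), returning the canonical key set.
brute_force_pairs <- function(halfAln, params) {
  n <- nrow(halfAln)
  if (n < 2L) return(character())
  keys <- character()
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    same <- halfAln$readId[j] == halfAln$readId[i] &
      halfAln$splitOffset[j] == halfAln$splitOffset[i] &
      halfAln$side[j] != halfAln$side[i] &
      halfAln$refName[j] == halfAln$refName[i] &
      halfAln$strand[j] == halfAln$strand[i]
    for (k in j[same]) {
      L <- if (halfAln$side[i] == "L") i else k
      R <- if (halfAln$side[i] == "L") k else i
      if (halfAln$strand[L] == "+") {
        leftEnd <- halfAln$end[L]; rightStart <- halfAln$start[R]
      } else {
        leftEnd <- halfAln$end[R]; rightStart <- halfAln$start[L]
      }
      gap <- rightStart - leftEnd
      if (gap >= params$minCD && gap <= params$MD)
        keys <- c(keys, paste(halfAln$readId[i], halfAln$splitOffset[i],
                              halfAln$refName[i], halfAln$strand[i],
                              leftEnd, rightStart))
    }
  }
  sort(unique(keys))
}

pair_keys <- function(mp) {
  sort(unique(paste(mp$readId, mp$splitOffset, mp$chrom, mp$strand,
                    mp$leftEnd, mp$rightStart)))
}

# Random half-alignment tables for property tests: several reads, several
# split offsets, multi-placement halves on a few chromosomes.
random_half_alignments <- function(seed, nReads = 60L, nRowsMin = 1000L) {
  set.seed(seed)
  rows <- list()
  while (sum(vapply(rows, nrow, 0L)) < nRowsMin) {
    rid <- sprintf("r%03d", length(rows) %% nReads + 1L)
    off <- sample(8:25, 1L)
    side <- sample(c("L", "R"), 1L)
    w <- if (side == "L") off else 33L - off
    nPlace <- sample(1:4, 1L)
    start <- sample.int(50000L, nPlace)
    rows[[length(rows) + 1L]] <- data.frame(
      queryId = paste0(rid, "/", off, "/", side),
      refName = sample(paste0("chr", 1:3), nPlace, replace = TRUE),
      strand = sample(c("+", "-"), nPlace, replace = TRUE),
      start = start, end = start + w, mismatches = 0L,
      altCount = nPlace - 1L, readId = rid, splitOffset = off, side = side,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# The default synthetic comparative fixture and its pipeline run, generated
# once and shared across test files.
.fixture_cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (!is.null(.fixture_cache$fx)) return(.fixture_cache$fx)
  dir <- file.path(tempdir(), "rsrun-default-fixture")
  paths <- make_synthetic_dataset(dir, seed = 26)
  cfg <- rsr_config(mode = "comparative",
                    fastqA = paths$het, fastqB = paths$ko,
                    genome = paths$genome, knownGenes = paths$knownGenes,
                    params = rsr_params(), out = file.path(dir, "results"))
  res <- suppressWarnings(run_pipeline(cfg))
  genome <- Biostrings::readDNAStringSet(paths$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genes <- parse_known_genes(paths$knownGenes)
  flanks <- build_junction_flanks(genes, genome, 33)
  expanded <- build_expanded_genome(genome, flanks)
  hetReads <- read_fastq(paths$het)$seqs
  hetFp <- first_pass(hetReads, expanded, aligner_config())
  .fixture_cache$fx <- list(paths = paths, config = cfg, res = res,
                            dir = dir, genome = genome, genes = genes,
                            flanks = flanks, expanded = expanded,
                            hetReads = hetReads, hetFp = hetFp)
  .fixture_cache$fx
}
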