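#' Generate a toy genome with gene annotation
#'
#' Builds a small multi-chromosome genome carrying one multi-exon gene with
#' canonical introns (chr1) and one single-exon target gene (chr2) that will
#' host the engineered non-canonical excision. Sequences are rejection-
#' sampled until every k-mer of read length in the genome (and its reverse
#' complement) is unique, so exact alignment of reads and split halves is
#' unambiguous. Deterministic for a fixed seed.
#'
#' @param seed RNG seed; the documented default fixture uses 26.
#' @param nChrom number of chromosomes (>= 2; genes occupy the first two).
#' @param chromLength chromosome length in bp.
#' @param gcContent GC fraction of the random background.
#' @param readLength read length the uniqueness check protects (bp).
#' @return list with `genome` (named `DNAStringSet`), `genes` (gene-model
#'   data.frame as from [parse_known_genes()]) and `targetGene` (name of the
#'   single-exon gene).
#' @export
make_genome <- function(seed = 26L, nChrom = 2L, chromLength = 6000L,
                        gcContent = 0.5, readLength = 33L) {
  stopifnot(nChrom >= 2L, chromLength >= 10L * readLength,
            gcContent > 0, gcContent < 1)
  set.seed(seed)
  probs <- c(A = (1 - gcContent) / 2, C = gcContent / 2,
             G = gcContent / 2, T = (1 - gcContent) / 2)
  for (try in seq_len(25L)) {
    chroms <- vapply(seq_len(nChrom), function(i)
      paste(sample(names(probs), chromLength, replace = TRUE, prob = probs),
            collapse = ""), "")
    names(chroms) <- paste0("chr", seq_len(nChrom))
    if (.kmers_unique(chroms, readLength)) {
      genome <- DNAStringSet(chroms)
      genes <- .toy_genes(chromLength)
      return(list(genome = genome, genes = genes, targetGene = "tgtB"))
    }
  }
  stop("could not generate a genome with unique ", readLength,
       "-mers after 25 attempts; increase chromLength or adjust gcContent")
}

.kmers_unique <- function(chroms, k) {
  kmers <- unlist(lapply(chroms, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  rc <- as.character(reverseComplement(DNAStringSet(kmers)))
  # unique on the forward strand and never mirrored on the reverse strand
  !anyDuplicated(kmers) && !any(rc %in% kmers)
}

# fixed toy gene geometry: a 3-exon canonical gene on chr1 and the
# single-exon excision target on chr2
.toy_genes <- function(chromLength) {
  stopifnot(chromLength >= 3000L)
  data.frame(
    name = c("genA", "tgtB"),
    chrom = c("chr1", "chr2"),
    strand = c("+", "+"),
    txStart = c(1000L, 1000L),
    txEnd = c(2900L, 1600L),
    exonCount = c(3L, 1L),
    exonStarts = I(list(c(1000L, 1800L, 2600L), 1000L)),
    exonEnds = I(list(c(1200L, 2050L, 2900L), 1600L)),
    stringsAsFactors = FALSE)
}

#' Generate case (Het) and control (KO) read sets with ground truth
#'
#' Reads are exact substrings (no sequencing errors by default) of three
#' transcripts: the mature spliced mRNA of the canonical multi-exon gene,
#' the unspliced target-gene transcript, and — in the Het sample only — the
#' target transcript with a short segment (default 26 nt) excised
#' non-canonically. Start positions are uniform; qualities are constant
#' Phred 40, Phred+33. The generator verifies its own guarantee: the Het
#' pool must contain at least `minSupport` excision-spanning reads with at
#' least `MS` bases on each side at two or more distinct offsets, and it
#' errors with a coverage suggestion otherwise. The KO pool contains no
#' spliced-form target reads by construction.
#'
#' @param genomeObj result of [make_genome()].
#' @param truth optional truth junction override: list with `leftEnd` and
#'   `length` (genomic, 0-based half-open, inside the target gene). Default:
#'   26 nt at 287 bp into the target exon.
#' @param coverage mean fold-coverage per transcript.
#' @param readLength read length in bp.
#' @param seed RNG seed (default 26, the documented fixture seed).
#' @param MS,minSupport the split size and support the guarantee protects.
#' @param errorRate per-base substitution rate (default 0; the acceptance
#'   fixture is error-free).
#' @return list with `het` and `ko` (named character read vectors) and
#'   `truth` (data.frame: chrom, leftEnd, rightStart, length, minHetSupport,
#'   koSplicedReads, seed, coverage, readLength).
#' @export
make_case_control_reads <- function(genomeObj, truth = NULL, coverage = 20,
                                    readLength = 33L, seed = 26L,
                                    MS = 8L, minSupport = 2L,
                                    errorRate = 0) {
  set.seed(seed + 1L)
  genes <- genomeObj$genes
  tgt <- genes[genes$name == genomeObj$targetGene, ]
  stopifnot(nrow(tgt) == 1L, tgt$exonCount == 1L)
  if (is.null(truth))
    truth <- list(leftEnd = tgt$txStart + 287L, length = 26L)
  leftEnd <- as.integer(truth$leftEnd)
  exLen <- as.integer(truth$length)
  rightStart <- leftEnd + exLen
  stopifnot(leftEnd > tgt$txStart, rightStart < tgt$txEnd)

  chromSeq <- function(chrom) genomeObj$genome[[chrom]]
  gene_tx <- function(g) {
    s <- chromSeq(g$chrom)
    paste(vapply(seq_len(g$exonCount), function(j)
      as.character(subseq(s, g$exonStarts[[1L]][j] + 1L, g$exonEnds[[1L]][j])),
      ""), collapse = "")
  }
  txCanon <- gene_tx(genes[genes$name != genomeObj$targetGene, ][1L, ])
  txTarget <- gene_tx(tgt)
  cut <- leftEnd - tgt$txStart          # transcript-local excision point
  txSpliced <- paste0(substr(txTarget, 1L, cut),
                      substr(txTarget, cut + exLen + 1L, nchar(txTarget)))

  sample_tx <- function(tx, label, cov) {
    n <- ceiling(cov * nchar(tx) / readLength)
    starts <- sample.int(nchar(tx) - readLength + 1L, n, replace = TRUE)
    reads <- substring(tx, starts, starts + readLength - 1L)
    if (errorRate > 0) reads <- .mutate_reads(reads, errorRate)
    names(reads) <- sprintf("%s_%04d", label, seq_len(n))
    list(reads = reads, starts = starts - 1L)
  }

  hetCanon <- sample_tx(txCanon, "het_can", coverage)
  hetUnspl <- sample_tx(txTarget, "het_uns", coverage)
  hetSpl <- sample_tx(txSpliced, "het_spl", coverage)
  koCanon <- sample_tx(txCanon, "ko_can", coverage)
  koUnspl <- sample_tx(txTarget, "ko_uns", coverage)

  # guarantee: spanning reads with >= MS bases each side, >= 2 offsets
  lflank <- cut - hetSpl$starts
  ok <- lflank >= MS & (readLength - lflank) >= MS
  nSpan <- sum(ok)
  if (nSpan < minSupport || length(unique(lflank[ok])) < 2L)
    stop("coverage ", coverage, " left only ", nSpan,
         " usable excision-spanning reads at ",
         length(unique(lflank[ok])), " offset(s); coverage >= ",
         ceiling(coverage * max(2, minSupport + 2) / max(1, nSpan + 1)),
         " is suggested")

  truthDf <- data.frame(
    chrom = tgt$chrom, leftEnd = leftEnd, rightStart = rightStart,
    length = exLen, minHetSupport = nSpan, koSplicedReads = 0L,
    seed = seed, coverage = coverage, readLength = readLength,
    stringsAsFactors = FALSE)
  list(het = c(hetCanon$reads, hetUnspl$reads, hetSpl$reads),
       ko = c(koCanon$reads, koUnspl$reads),
       truth = truthDf)
}

.mutate_reads <- function(reads, rate) {
  vapply(reads, function(r) {
    b <- strsplit(r, "")[[1L]]
    hit <- which(stats::runif(length(b)) < rate)
    for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
    paste(b, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Write the complete synthetic fixture to a directory
#'
#' Emits genome FASTA, knownGene table, Het and KO FASTQ and the
#' machine-readable truth table, all plain text, and returns their paths.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed driving both genome and reads.
#' @param coverage,readLength as in [make_case_control_reads()].
#' @param ... further arguments to [make_case_control_reads()].
#' @return list of paths (`genome`, `knownGenes`, `het`, `ko`, `truth`) plus
#'   the `truth` data.frame.
#' @export
make_synthetic_dataset <- function(dir, seed = 26L, coverage = 20,
                                   readLength = 33L, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- make_genome(seed = seed, readLength = readLength)
  rd <- make_case_control_reads(g, coverage = coverage,
                                readLength = readLength, seed = seed, ...)
  paths <- list(genome = file.path(dir, "genome.fa"),
                knownGenes = file.path(dir, "known_genes.txt"),
                het = file.path(dir, "het.fastq"),
                ko = file.path(dir, "ko.fastq"),
                truth = file.path(dir, "truth.tsv"))
  write_fasta(g$genome, paths$genome)
  write_known_genes(g$genes, paths$knownGenes)
  write_fastq(rd$het, paths$het)
  write_fastq(rd$ko, paths$ko)
  utils::write.table(rd$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(paths, list(truthTable = rd$truth))
}
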