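#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement subseq matchPattern
#' @importFrom methods is
NULL

# Reserved prefix separating junction-flank records from chromosome names in
# the expanded genome.  Flank ids are self-describing:
#   |jct|<gene>|<chrom>|<leftEnd>|<rightStart>
# so downstream code recovers genomic coordinates of annotated junctions
# without a side table.
.JCT_PREFIX <- "|jct|"

#' Parse a UCSC knownGene-format gene table
#'
#' Reads a tab-separated gene table in UCSC knownGene layout (name, chrom,
#' strand, txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds,
#' ...). Coordinates are 0-based half-open, as in UCSC dumps; exon lists are
#' comma-terminated. Rows violating the exon invariants are reported with
#' their line numbers.
#'
#' @param path path to the tab-separated table (no header).
#' @return A data.frame of gene models with columns `name`, `chrom`,
#'   `strand`, `txStart`, `txEnd`, `exonCount` and list-columns `exonStarts`,
#'   `exonEnds` (integer vectors per gene).
#' @export
parse_known_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(name = character(), chrom = character(),
                      strand = character(), txStart = integer(),
                      txEnd = integer(), exonCount = integer(),
                      exonStarts = I(list()), exonEnds = I(list())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  parse_row <- function(f, ln) {
    if (length(f) < 10L)
      stop(sprintf("knownGene line %d: expected >= 10 tab-separated columns, got %d",
                   ln, length(f)))
    starts <- suppressWarnings(as.integer(strsplit(f[9L], ",", fixed = TRUE)[[1L]]))
    ends   <- suppressWarnings(as.integer(strsplit(f[10L], ",", fixed = TRUE)[[1L]]))
    n <- suppressWarnings(as.integer(f[8L]))
    if (is.na(n) || anyNA(starts) || anyNA(ends))
      stop(sprintf("knownGene line %d: non-numeric exon fields", ln))
    if (length(starts) != n || length(ends) != n)
      stop(sprintf("knownGene line %d: exonCount %d disagrees with exon list lengths (%d starts, %d ends)",
                   ln, n, length(starts), length(ends)))
    if (n > 0L && (any(starts >= ends) ||
                   (n > 1L && any(ends[-n] > starts[-1L]))))
      stop(sprintf("knownGene line %d: exon intervals not ascending and disjoint", ln))
    list(name = f[1L], chrom = f[2L], strand = f[3L],
         txStart = as.integer(f[4L]), txEnd = as.integer(f[5L]),
         exonCount = n, exonStarts = starts, exonEnds = ends)
  }
  rows <- Map(parse_row, fields, seq_along(fields))
  data.frame(
    name = vapply(rows, `[[`, "", "name"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    txStart = vapply(rows, `[[`, 0L, "txStart"),
    txEnd = vapply(rows, `[[`, 0L, "txEnd"),
    exonCount = vapply(rows, `[[`, 0L, "exonCount"),
    exonStarts = I(lapply(rows, `[[`, "exonStarts")),
    exonEnds = I(lapply(rows, `[[`, "exonEnds")),
    stringsAsFactors = FALSE)
}

#' Annotated introns of a gene table
#'
#' @param genes gene models from [parse_known_genes()].
#' @return data.frame with `chrom`, `leftEnd` (end of the upstream exon),
#'   `rightStart` (start of the downstream exon), `gene`; one row per
#'   adjacent exon pair, deduplicated by (chrom, leftEnd, rightStart).
#' @keywords internal
gene_introns <- function(genes) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    n <- genes$exonCount[i]
    if (n < 2L) next
    starts <- genes$exonStarts[[i]]
    ends <- genes$exonEnds[[i]]
    out[[length(out) + 1L]] <- data.frame(
      gene = genes$name[i], chrom = genes$chrom[i],
      leftEnd = ends[-n], rightStart = starts[-1L],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(gene = character(), chrom = character(),
                      leftEnd = integer(), rightStart = integer()))
  d <- do.call(rbind, out)
  d[!duplicated(d[c("chrom", "leftEnd", "rightStart")]), , drop = FALSE]
}

#' Build exon-exon junction flank records
#'
#' For every adjacent exon pair of every gene, concatenates the terminal
#' bases of the upstream exon with the initial bases of the downstream exon.
#' Each flank is `readLength - 4` bp, truncated to the exon where the exon is
#' shorter, so a read crossing the annotated junction with at least 5 bases
#' on each side aligns contiguously to the record. Junctions shared by
#' overlapping isoforms are emitted once.
#'
#' @param genes gene models from [parse_known_genes()].
#' @param genome named [Biostrings::DNAStringSet] of chromosomes.
#' @param readLength read length in bp (>= 6).
#' @return named `DNAStringSet` of flank records; names follow the reserved
#'   `|jct|gene|chrom|leftEnd|rightStart` format. Per-record flank lengths
#'   are attached as metadata columns `leftFlankLen`, `rightFlankLen`.
#' @export
build_junction_flanks <- function(genes, genome, readLength) {
  stopifnot(readLength >= 6L)
  flank <- as.integer(readLength) - 4L
  missing_chrom <- setdiff(genes$chrom, names(genome))
  if (length(missing_chrom))
    stop("gene(s) ", paste(genes$name[genes$chrom %in% missing_chrom], collapse = ", "),
         " reference chromosome(s) absent from genome: ",
         paste(missing_chrom, collapse = ", "))
  ids <- character(); seqs <- character()
  leftLens <- integer(); rightLens <- integer()
  for (i in seq_len(nrow(genes))) {
    n <- genes$exonCount[i]
    if (n < 2L) next
    starts <- genes$exonStarts[[i]]
    ends <- genes$exonEnds[[i]]
    chromSeq <- genome[[genes$chrom[i]]]
    for (j in seq_len(n - 1L)) {
      lLen <- min(flank, ends[j] - starts[j])
      rLen <- min(flank, ends[j + 1L] - starts[j + 1L])
      id <- paste0(.JCT_PREFIX, genes$name[i], "|", genes$chrom[i], "|",
                   ends[j], "|", starts[j + 1L])
      ids <- c(ids, id)
      seqs <- c(seqs, paste0(
        as.character(subseq(chromSeq, ends[j] - lLen + 1L, ends[j])),
        as.character(subseq(chromSeq, starts[j + 1L] + 1L, starts[j + 1L] + rLen))))
      leftLens <- c(leftLens, lLen)
      rightLens <- c(rightLens, rLen)
    }
  }
  # deduplicate isoform-shared junctions by (chrom, leftEnd, rightStart)
  key <- sub("^\\|jct\\|[^|]*\\|", "", ids)
  keep <- !duplicated(key)
  out <- DNAStringSet(seqs[keep])
  names(out) <- ids[keep]
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    leftFlankLen = leftLens[keep], rightFlankLen = rightLens[keep])
  out
}

#' Merge genome and junction flanks into an expanded genome
#'
#' The expanded genome is the reference for the first alignment pass: reads
#' mapping to a flank record span an annotated junction; reads mapping to a
#' chromosome are contiguous genomic reads; the remainder are the
#' non-canonical splicing candidates.
#'
#' @param genome named `DNAStringSet` of chromosomes.
#' @param flanks flank records from [build_junction_flanks()].
#' @return `DNAStringSet` with chromosomes first, flank records after.
#' @export
build_expanded_genome <- function(genome, flanks) {
  if (any(startsWith(names(genome), .JCT_PREFIX)))
    stop("chromosome names must not use the reserved junction prefix")
  if (anyDuplicated(names(flanks)))
    stop("duplicate flank ids: ",
         paste(unique(names(flanks)[duplicated(names(flanks))]), collapse = ", "))
  if (!is.null(S4Vectors::mcols(flanks))) S4Vectors::mcols(flanks) <- NULL
  out <- c(genome, DNAStringSet(flanks))
  if (anyDuplicated(names(out))) stop("name collision in expanded genome")
  out
}

#' Parse flank-record ids back to genomic junction coordinates
#'
#' @param ids character vector of flank-record ids.
#' @return data.frame with `gene`, `chrom`, `leftEnd`, `rightStart`, `length`.
#' @export
parse_flank_ids <- function(ids) {
  bad <- !startsWith(ids, .JCT_PREFIX)
  if (any(bad))
    stop("not a junction flank id: ", ids[which(bad)[1L]])
  parts <- strsplit(sub("^\\|jct\\|", "", ids), "|", fixed = TRUE)
  if (any(lengths(parts) != 4L))
    stop("malformed junction flank id: ", ids[which(lengths(parts) != 4L)[1L]])
  d <- data.frame(
    gene = vapply(parts, `[`, "", 1L),
    chrom = vapply(parts, `[`, "", 2L),
    leftEnd = as.integer(vapply(parts, `[`, "", 3L)),
    rightStart = as.integer(vapply(parts, `[`, "", 4L)),
    stringsAsFactors = FALSE)
  d$length <- d$rightStart - d$leftEnd
  d
}
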