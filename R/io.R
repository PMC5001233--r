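#' Read a FASTQ file
#'
#' @param path FASTQ file (uncompressed or gzipped).
#' @return list with `seqs` and `quals`, both named character vectors.
#' @export
read_fastq <- function(path) {
  x <- readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  seqs <- as.character(x)
  quals <- as.character(S4Vectors::mcols(x)$qualities)
  names(quals) <- names(seqs)
  list(seqs = seqs, quals = quals)
}

#' Write a FASTQ file
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param quals named character vector of quality strings; defaults to
#'   constant Phred 40 ("I") in Phred+33 encoding.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path, quals = NULL) {
  if (is.null(quals))
    quals <- vapply(nchar(seqs), function(n)
      paste(rep("I", n), collapse = ""), "")
  writeLines(paste0("@", names(seqs), "\n", unname(seqs), "\n+\n",
                    unname(quals)), path)
  invisible(path)
}

#' Write a named sequence set as FASTA
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  writeXStringSet(seqs, path)
  invisible(path)
}

#' Write gene models as a UCSC knownGene-format table
#'
#' Tab-separated, no header, comma-terminated exon lists, 0-based half-open
#' coordinates; the cds columns are set to the transcript bounds and the
#' trailing protein/align columns left blank, as the pipeline ignores them.
#'
#' @param genes gene models (as from [parse_known_genes()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_known_genes <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    paste(genes$name[i], genes$chrom[i], genes$strand[i],
          genes$txStart[i], genes$txEnd[i], genes$txStart[i], genes$txEnd[i],
          genes$exonCount[i],
          paste0(paste(genes$exonStarts[[i]], collapse = ","), ","),
          paste0(paste(genes$exonEnds[[i]], collapse = ","), ","),
          "", "", sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
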