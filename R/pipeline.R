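#' Pipeline run configuration
#'
#' Collects everything one end-to-end run needs. Comparative mode requires
#' two sample groups (case first, control second); each group may hold
#' several replicate FASTQ files, processed per-file and unioned after
#' junction calling. Paired-end files are pooled and processed as
#' independent single-end reads (mate ids suffixed `/1`, `/2` are made
#' safe); no mate-aware constraint is applied.
#'
#' @param mode `"comparative"` or `"non-comparative"`.
#' @param readsType `"single"` or `"paired"`.
#' @param fastqA character vector of FASTQ paths for the case group.
#' @param fastqB character vector for the control group (comparative mode).
#' @param genome path to the reference genome FASTA.
#' @param knownGenes path to the UCSC knownGene-format gene table.
#' @param params an [rsr_params()].
#' @param aligner `"builtin"` or `"external"`.
#' @param alignerPath external aligner executable (external mode only).
#' @param perChromosome process second-pass alignments chromosome by
#'   chromosome (bounds memory on large runs; results are identical).
#' @param keepIntermediates keep pass-1 alignments, unmapped pools and half
#'   alignments on disk; when `FALSE` they are deleted as soon as the next
#'   stage no longer needs them and the deletions are logged.
#' @param seed integer seed recorded in the manifest.
#' @param out output directory.
#' @return object of class `rsr_config`.
#' @export
rsr_config <- function(mode = c("comparative", "non-comparative"),
                       readsType = c("single", "paired"),
                       fastqA, fastqB = NULL, genome, knownGenes,
                       params = rsr_params(),
                       aligner = c("builtin", "external"),
                       alignerPath = NULL, perChromosome = FALSE,
                       keepIntermediates = FALSE, seed = 1L, out) {
  mode <- match.arg(mode)
  readsType <- match.arg(readsType)
  aligner <- match.arg(aligner)
  if (mode == "comparative" && (is.null(fastqB) || length(fastqB) == 0L))
    stop("comparative mode requires a second sample group (fastqB)")
  stopifnot(length(fastqA) >= 1L, inherits(params, "rsr_params"))
  structure(list(mode = mode, readsType = readsType,
                 fastqA = fastqA, fastqB = fastqB,
                 genome = genome, knownGenes = knownGenes, params = params,
                 aligner = aligner, alignerPath = alignerPath,
                 perChromosome = isTRUE(perChromosome),
                 keepIntermediates = isTRUE(keepIntermediates),
                 seed = as.integer(seed), out = out),
            class = "rsr_config")
}

#' Validate FASTQ inputs before running
#'
#' Detects the quality encoding of each file from its quality byte range
#' (any byte below 59 implies Phred+33; all bytes at 64 or above with some
#' above 74 implies Phred+64; anything else is ambiguous and treated as
#' Phred+33 with a warning) and enforces that every file in the run has one
#' common read length — the split arithmetic presumes it.
#'
#' @param config an [rsr_config()], or a character vector of FASTQ paths.
#' @return data.frame with one row per file: `file`, `readCount`,
#'   `readLength`, `encoding`.
#' @export
validate_inputs <- function(config) {
  files <- if (inherits(config, "rsr_config"))
    c(config$fastqA, config$fastqB) else config
  rep_rows <- lapply(files, function(fp) {
    fq <- read_fastq(fp)
    lens <- unique(nchar(fq$seqs))
    if (length(lens) != 1L)
      stop("unequal read lengths within ", fp, ": ",
           paste(sort(lens), collapse = ", "))
    bytes <- unique(unlist(lapply(fq$quals, function(q) utf8ToInt(q))))
    enc <- if (any(bytes < 59L)) "Phred+33"
    else if (all(bytes >= 64L) && any(bytes > 74L)) "Phred+64"
    else {
      warning("quality encoding of ", fp,
              " is ambiguous; assuming Phred+33")
      "Phred+33"
    }
    data.frame(file = fp, readCount = length(fq$seqs), readLength = lens,
               encoding = enc, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rep_rows)
  if (length(unique(report$readLength)) > 1L)
    stop("read lengths differ across input files: ",
         paste(sprintf("%s (%d bp)", report$file, report$readLength),
               collapse = ", "))
  report
}

#' Split an alignment table by chromosome
#'
#' Junction calling is separable per chromosome (matched pairs never span
#' chromosomes), so large second-pass outputs can be processed chunk by
#' chunk with identical results.
#'
#' @param alignments alignment data.frame with a `refName` column.
#' @return named list of per-chromosome data.frames (empty list for an
#'   empty input).
#' @export
chunk_by_chromosome <- function(alignments) {
  if (nrow(alignments) == 0L) return(list())
  split(alignments, alignments$refName)
}

#' Delete intermediates on the pipeline's schedule
#'
#' Stage `"post-unmapped"` removes the pass-1 alignment table (the unmapped
#' pool has been extracted); stage `"post-second-pass"` removes the unmapped
#' FASTA and half-alignment table. Final outputs and the manifest are never
#' touched. No-op when intermediates are kept.
#'
#' @param stage `"post-unmapped"` or `"post-second-pass"`.
#' @param sampleDir the per-sample output directory.
#' @param keepIntermediates if `TRUE`, delete nothing.
#' @return character vector of removed paths.
#' @export
cleanup_intermediates <- function(stage = c("post-unmapped",
                                            "post-second-pass"),
                                  sampleDir, keepIntermediates = FALSE) {
  stage <- match.arg(stage)
  if (keepIntermediates) return(character())
  victims <- switch(stage,
    "post-unmapped" = file.path(sampleDir, "pass1_alignments.tsv"),
    "post-second-pass" = file.path(sampleDir,
                                   c("unmapped.fa", "half_alignments.tsv")))
  removed <- victims[file.exists(victims)]
  unlink(removed)
  removed
}

# run one replicate file through pass 1, splitting, pass 2 and junction
# calling; writes intermediates into sampleDir and returns the junction set
.call_sample_file <- function(fastq, repTag, expanded, genome, flanks,
                              config, sampleDir, dlog) {
  p <- config$params
  cfg <- aligner_config(mode = config$aligner,
                        executablePath = config$alignerPath,
                        maxGoodAlignments = p$maxGoodAlignments)
  fq <- read_fastq(fastq)
  reads <- fq$seqs
  if (config$readsType == "paired")
    names(reads) <- gsub("/", "|", names(reads), fixed = TRUE)
  names(reads) <- paste0(repTag, ":", names(reads))
  readLength <- unique(nchar(reads))

  fp <- first_pass(reads, expanded, cfg)
  utils::write.table(fp$alignments,
                     file.path(sampleDir, "pass1_alignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(fp$unmapped, file.path(sampleDir, "unmapped.fa"))
  dlog(cleanup_intermediates("post-unmapped", sampleDir,
                             config$keepIntermediates))

  halves <- split_reads(fp$unmapped, p$MS)
  halfAln <- if (length(halves)) second_pass(halves, genome, cfg)
  else cbind(.empty_alignments(),
             data.frame(readId = character(), splitOffset = integer(),
                        side = character(), stringsAsFactors = FALSE))
  utils::write.table(halfAln, file.path(sampleDir, "half_alignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  chunks <- if (config$perChromosome) chunk_by_chromosome(halfAln)
            else list(all = halfAln)
  mp <- do.call(rbind, c(lapply(chunks, find_matched_pairs, params = p),
                         make.row.names = FALSE))
  if (is.null(mp) || nrow(mp) == 0L) mp <- .empty_matched_pairs()
  mp <- mp[order(mp$chrom, mp$leftEnd, mp$rightStart, mp$readId,
                 mp$splitOffset), , drop = FALSE]
  utils::write.table(mp, file.path(sampleDir, "matched_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dlog(cleanup_intermediates("post-second-pass", sampleDir,
                             config$keepIntermediates))

  j <- cluster_junctions(mp, p$BB)
  j <- filter_junctions(j, p$minSupport)
  annotate_known(j, flanks, p$BB)
}

# union replicate junction sets: one row per junction key, supporting reads
# pooled across replicates (read ids are replicate-prefixed, so distinct)
.union_replicates <- function(jlist) {
  all <- do.call(rbind, c(jlist, make.row.names = FALSE))
  if (nrow(all) == 0L) return(all)
  key <- paste(all$chrom, all$strand, all$leftEnd, all$rightStart)
  rows <- lapply(split(seq_len(nrow(all)), key), function(idx) {
    reads <- sort(unique(unlist(strsplit(all$supportingReadIds[idx], ","))))
    out <- all[idx[1L], , drop = FALSE]
    out$supportCount <- length(reads)
    out$supportingReadIds <- paste(reads, collapse = ",")
    out
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out <- out[order(out$chrom, out$leftEnd, out$rightStart), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.process_group <- function(files, label, expanded, genome, flanks,
                           config, dlog) {
  sampleDir <- file.path(config$out, label)
  dir.create(sampleDir, recursive = TRUE, showWarnings = FALSE)
  jlist <- lapply(seq_along(files), function(i)
    .call_sample_file(files[i], paste0("r", i), expanded, genome, flanks,
                      config, sampleDir, dlog))
  junctions <- .union_replicates(jlist)
  ranked <- rank_junctions(junctions)
  write_junction_bed(ranked, file.path(sampleDir, "junctions.bed"))
  write_junction_detail(ranked, file.path(sampleDir, "ranked_report.tsv"))
  ranked
}

#' Run the full Read-Split-Run pipeline
#'
#' Executes, per sample group: first-pass alignment against the expanded
#' genome, extraction of unmapped reads, exhaustive splitting, second-pass
#' alignment of the halves against the plain genome, matched-pair assembly,
#' boundary-buffer clustering, support filtering and known/novel
#' annotation. Comparative mode then subtracts the control junction set
#' from the case set and writes a side-by-side report. A manifest recording
#' parameters, inputs and versions is always written; on a stage failure a
#' `FAILED` marker is left next to the partial outputs and the error is
#' re-raised.
#'
#' @param config an [rsr_config()].
#' @return invisibly, a list with `junctionsA`, `junctionsB` (NULL in
#'   non-comparative mode), `uniqueToA`, `sideBySide`, `validation` and
#'   `outDir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "rsr_config"))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  deletionLog <- character()
  dlog <- function(paths) {
    if (length(paths))
      deletionLog <<- c(deletionLog, paths)
    invisible(NULL)
  }
  res <- tryCatch({
    validation <- validate_inputs(config)
    readLength <- validation$readLength[1L]
    genome <- readDNAStringSet(config$genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    genes <- parse_known_genes(config$knownGenes)
    flanks <- build_junction_flanks(genes, genome, readLength)
    expanded <- build_expanded_genome(genome, flanks)

    jA <- .process_group(config$fastqA, "sampleA", expanded, genome, flanks,
                         config, dlog)
    jB <- NULL; uniq <- NULL; sbs <- NULL
    if (config$mode == "comparative") {
      jB <- .process_group(config$fastqB, "sampleB", expanded, genome,
                           flanks, config, dlog)
      cmpDir <- file.path(config$out, "comparison")
      dir.create(cmpDir, showWarnings = FALSE)
      uniq <- subtract_junctions(jA, jB, config$params$BB)
      write_junction_bed(uniq, file.path(cmpDir, "unique_to_A.bed"))
      write_junction_detail(uniq, file.path(cmpDir, "unique_to_A_report.tsv"))
      sbs <- side_by_side_report(jA, jB, config$params$BB)
      write_side_by_side(sbs, file.path(cmpDir, "side_by_side.tsv"))
    }
    .write_manifest(config, readLength)
    if (length(deletionLog))
      writeLines(deletionLog, file.path(config$out, "deletion_log.txt"))
    list(junctionsA = jA, junctionsB = jB, uniqueToA = uniq,
         sideBySide = sbs, validation = validation, outDir = config$out)
  }, error = function(e) {
    writeLines(conditionMessage(e), file.path(config$out, "FAILED"))
    stop(e)
  })
  invisible(res)
}

.write_manifest <- function(config, readLength) {
  p <- config$params
  lines <- c(
    paste0("rsrun_version=", as.character(utils::packageVersion("rsrun"))),
    paste0("r_version=", R.version.string),
    paste0("mode=", config$mode),
    paste0("reads_type=", config$readsType),
    paste0("fastq_a=", paste(config$fastqA, collapse = ",")),
    paste0("fastq_b=", paste(config$fastqB, collapse = ",")),
    paste0("genome=", config$genome),
    paste0("known_genes=", config$knownGenes),
    paste0("read_length=", readLength),
    paste0("min_split_size=", p$MS),
    paste0("max_distance=", p$MD),
    paste0("min_distance=", p$minCD),
    paste0("boundary_buffer=", p$BB),
    paste0("min_support=", p$minSupport),
    paste0("max_alignments=", p$maxGoodAlignments),
    paste0("aligner=", config$aligner),
    paste0("per_chromosome=", config$perChromosome),
    paste0("keep_intermediates=", config$keepIntermediates),
    paste0("seed=", config$seed))
  writeLines(lines, file.path(config$out, "manifest.txt"))
}
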