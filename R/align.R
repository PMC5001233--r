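#' Aligner configuration
#'
#' The pipeline's two alignment passes run behind one contract: either an
#' external bowtie-1-compatible aligner, or the built-in exact-match aligner
#' (which doubles as the testing oracle). Both suppress reads with more than
#' `maxGoodAlignments` equally good placements ("-m" semantics: suppressed
#' reads are discarded, not routed to the unmapped pool).
#'
#' @param mode `"builtin"` or `"external"`.
#' @param executablePath path to the bowtie executable (external mode).
#' @param maxGoodAlignments suppression threshold, >= 1.
#' @param reportUnmapped keep unmapped reads for the splitting stage.
#' @return object of class `aligner_config`.
#' @export
aligner_config <- function(mode = c("builtin", "external"),
                           executablePath = NULL,
                           maxGoodAlignments = 8L,
                           reportUnmapped = TRUE) {
  mode <- match.arg(mode)
  stopifnot(maxGoodAlignments >= 1L)
  if (mode == "external") {
    if (is.null(executablePath) || !nzchar(Sys.which(executablePath)))
      stop("external aligner executable not found: ",
           if (is.null(executablePath)) "<unset>" else executablePath)
  }
  structure(list(mode = mode, executablePath = executablePath,
                 maxGoodAlignments = as.integer(maxGoodAlignments),
                 reportUnmapped = isTRUE(reportUnmapped)),
            class = "aligner_config")
}

.empty_alignments <- function() {
  data.frame(queryId = character(), refName = character(),
             strand = character(), start = integer(), end = integer(),
             mismatches = integer(), altCount = integer(),
             stringsAsFactors = FALSE)
}

#' Exact-match alignment of queries against a reference
#'
#' Reports every exact occurrence of each query on the forward strand and of
#' its reverse complement on the reverse strand, with 0-based half-open
#' coordinates. Queries with more than `maxHits` placements are suppressed;
#' queries with none are unmapped.
#'
#' @param queries named character vector (names are query ids).
#' @param ref named [Biostrings::DNAStringSet].
#' @param maxHits suppression threshold.
#' @return list with `alignments` (data.frame: queryId, refName, strand,
#'   start, end, mismatches, altCount), `unmapped` and `suppressed`
#'   (character ids).
#' @export
builtin_align <- function(queries, ref, maxHits = 8L) {
  stopifnot(length(queries) == 0L || !is.null(names(queries)))
  if (length(queries) == 0L)
    return(list(alignments = .empty_alignments(),
                unmapped = character(), suppressed = character()))
  stopifnot(all(nzchar(queries)))
  refNames <- names(ref)
  refChar <- as.character(ref)
  refLen <- nchar(refChar)
  qseq <- unname(queries)
  widths <- nchar(qseq)
  qrc <- as.character(reverseComplement(DNAStringSet(qseq)))
  # seed-and-verify: one constant-width prefix index per strand, candidate
  # placements confirmed by full-length exact comparison
  seedW <- min(widths)
  pdF <- Biostrings::PDict(DNAStringSet(substr(qseq, 1L, seedW)))
  pdR <- Biostrings::PDict(DNAStringSet(substr(qrc, 1L, seedW)))
  hits <- list()
  scan_strand <- function(pd, target, strand, ri) {
    sIdx <- Biostrings::startIndex(Biostrings::matchPDict(pd, ref[[ri]]))
    n <- lengths(sIdx)
    if (sum(n) == 0L) return(NULL)
    qi <- rep.int(seq_along(sIdx), n)
    s <- unlist(sIdx, use.names = FALSE)
    w <- widths[qi]
    ok <- s + w - 1L <= refLen[ri] &
      substring(refChar[ri], s, s + w - 1L) == target[qi]
    if (!any(ok)) return(NULL)
    data.frame(qi = qi[ok], refName = refNames[ri], strand = strand,
               start = s[ok] - 1L, end = s[ok] - 1L + w[ok],
               stringsAsFactors = FALSE)
  }
  for (ri in seq_along(ref)) {
    hits[[length(hits) + 1L]] <- scan_strand(pdF, qseq, "+", ri)
    hits[[length(hits) + 1L]] <- scan_strand(pdR, qrc, "-", ri)
  }
  hits <- do.call(rbind, hits[!vapply(hits, is.null, TRUE)])
  nhits <- integer(length(queries))
  if (!is.null(hits)) {
    tab <- tabulate(hits$qi, nbins = length(queries))
    nhits <- tab
    keep <- tab[hits$qi] <= maxHits
    hits <- hits[keep, , drop = FALSE]
  }
  aln <- if (is.null(hits) || nrow(hits) == 0L) .empty_alignments() else {
    hits <- hits[order(hits$qi, hits$refName, hits$strand, hits$start), ,
                 drop = FALSE]
    data.frame(queryId = names(queries)[hits$qi], refName = hits$refName,
               strand = hits$strand, start = hits$start, end = hits$end,
               mismatches = 0L, altCount = nhits[hits$qi] - 1L,
               stringsAsFactors = FALSE)
  }
  rownames(aln) <- NULL
  list(alignments = aln,
       unmapped = names(queries)[nhits == 0L],
       suppressed = names(queries)[nhits > maxHits])
}

#' First alignment pass: whole reads against the expanded genome
#'
#' Partitions the input reads into aligned, unmapped and suppressed
#' (ambiguous multi-mappers). Only the unmapped reads continue to the
#' splitting stage; suppressed reads are mapped (just ambiguously) and are
#' not splicing candidates.
#'
#' @param reads named character vector of read sequences (names = read ids).
#' @param ref the expanded genome (`DNAStringSet`).
#' @param cfg an [aligner_config()].
#' @return list with `alignments` (data.frame), `unmapped` (named character
#'   vector of read sequences) and `suppressed` (read ids).
#' @export
first_pass <- function(reads, ref, cfg = aligner_config()) {
  res <- .dispatch_align(reads, ref, cfg)
  list(alignments = res$alignments,
       unmapped = reads[res$unmapped],
       suppressed = res$suppressed)
}

#' Second alignment pass: split halves against the plain genome
#'
#' Halves are aligned against the chromosomes only (never the junction-flank
#' records, whose coordinates are not genomic). Each half's query id encodes
#' its origin read, split offset and side as `<readId>/<offset>/<L|R>`; the
#' returned table carries these parsed out.
#'
#' @param halves named character vector of half sequences; names follow the
#'   half-id convention.
#' @param ref genome-only `DNAStringSet`.
#' @param cfg an [aligner_config()].
#' @return data.frame of half alignments with additional columns `readId`,
#'   `splitOffset`, `side`.
#' @export
second_pass <- function(halves, ref, cfg = aligner_config()) {
  res <- .dispatch_align(halves, ref, cfg)
  aln <- res$alignments
  cbind(aln, parse_half_ids(aln$queryId))
}

.dispatch_align <- function(queries, ref, cfg) {
  if (cfg$mode == "builtin")
    builtin_align(queries, ref, maxHits = cfg$maxGoodAlignments)
  else
    .external_align(queries, ref, cfg)
}

#' @rdname second_pass
#' @param ids character vector of half ids.
#' @export
parse_half_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.*)/([0-9]+)/([LR])$", ids))
  bad <- lengths(m) != 4L
  if (any(bad))
    stop("unparseable half id: ", ids[which(bad)[1L]])
  data.frame(readId = vapply(m, `[`, "", 2L),
             splitOffset = as.integer(vapply(m, `[`, "", 3L)),
             side = vapply(m, `[`, "", 4L),
             stringsAsFactors = FALSE)
}

make_half_id <- function(readId, offset, side) {
  paste0(readId, "/", offset, "/", side)
}

# ---- external (bowtie-1-compatible) mode --------------------------------

.external_align <- function(queries, ref, cfg) {
  exe <- Sys.which(cfg$executablePath)
  if (!nzchar(exe))
    stop("external aligner executable not found: ", cfg$executablePath)
  build <- Sys.which(paste0(cfg$executablePath, "-build"))
  if (!nzchar(build))
    stop("external aligner index builder not found: ",
         paste0(cfg$executablePath, "-build"))
  dir <- tempfile("rsr_extaln_"); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  refFa <- file.path(dir, "ref.fa")
  writeXStringSet(ref, refFa)
  idx <- file.path(dir, "idx")
  st <- system2(build, c(shQuote(refFa), shQuote(idx)),
                stdout = FALSE, stderr = FALSE)
  if (st != 0L) stop("reference index build failed (exit ", st, ")")
  qFa <- file.path(dir, "reads.fa")
  writeLines(paste0(">", names(queries), "\n", unname(queries)), qFa)
  out <- file.path(dir, "aln.bowtie")
  unFa <- file.path(dir, "unmapped.fa")
  st <- system2(exe, c("-f", "-a", "-m", cfg$maxGoodAlignments,
                       "--un", shQuote(unFa), shQuote(idx), shQuote(qFa),
                       shQuote(out)),
                stdout = FALSE, stderr = FALSE)
  if (st != 0L) stop("external alignment failed (exit ", st, ")")
  aln <- parse_bowtie_default(readLines(out))
  mapped <- unique(aln$queryId)
  unmapped <- if (file.exists(unFa))
    names(readDNAStringSet(unFa)) else character()
  list(alignments = aln, unmapped = unmapped,
       suppressed = setdiff(names(queries), c(mapped, unmapped)))
}

#' Parse bowtie default tabular alignment output
#'
#' Bowtie's default format: query id, strand, reference, 0-based offset,
#' sequence, qualities, count of other equally placed reads, mismatch
#' descriptors. The placement is ungapped and end-to-end, so the interval is
#' `[offset, offset + length(seq))`.
#'
#' @param lines character vector of output lines.
#' @return data.frame of alignments.
#' @export
parse_bowtie_default <- function(lines) {
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(.empty_alignments())
  f <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(f) < 7L
  if (any(short))
    stop("truncated bowtie record at line ", which(short)[1L])
  mm <- vapply(f, function(x)
    if (length(x) >= 8L && nzchar(x[8L]))
      length(strsplit(x[8L], ",", fixed = TRUE)[[1L]]) else 0L, 0L)
  start <- as.integer(vapply(f, `[`, "", 4L))
  data.frame(queryId = vapply(f, `[`, "", 1L),
             refName = vapply(f, `[`, "", 3L),
             strand = vapply(f, `[`, "", 2L),
             start = start,
             end = start + nchar(vapply(f, `[`, "", 5L)),
             mismatches = mm,
             altCount = as.integer(vapply(f, `[`, "", 7L)),
             stringsAsFactors = FALSE)
}

#' Parse SAM alignment records
#'
#' Accepts the SAM encoding of the same placements bowtie reports: ungapped
#' end-to-end records. 1-based POS is converted to the 0-based half-open
#' convention; FLAG bit 0x10 gives the strand; FLAG 0x4 records are routed
#' to the unmapped set. Mismatches are taken from the NM tag, the
#' alternative-placement count from NH minus one (0 when absent).
#'
#' @param lines character vector of SAM lines (header lines allowed).
#' @return list with `alignments` (data.frame) and `unmapped` (query ids).
#' @export
parse_sam <- function(lines) {
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (length(lines) == 0L)
    return(list(alignments = .empty_alignments(), unmapped = character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(f) < 11L
  if (any(short))
    stop("truncated SAM record at line ", which(short)[1L])
  flag <- as.integer(vapply(f, `[`, "", 2L))
  unmapped_i <- bitwAnd(flag, 4L) != 0L
  tagval <- function(x, tag) {
    hit <- grep(paste0("^", tag, ":i:"), x[-(1:11)], value = TRUE)
    if (length(hit)) as.integer(sub(paste0(tag, ":i:"), "", hit[1L])) else NA_integer_
  }
  aln_f <- f[!unmapped_i]
  if (length(aln_f)) {
    cig <- vapply(aln_f, `[`, "", 6L)
    reflen <- vapply(cig, function(cg) {
      ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1L]]
      n <- as.integer(sub("[MIDNSHP=X]", "", ops))
      op <- sub("[0-9]+", "", ops)
      sum(n[op %in% c("M", "=", "X", "D", "N")])
    }, 0L)
    start <- as.integer(vapply(aln_f, `[`, "", 4L)) - 1L
    nm <- vapply(aln_f, tagval, 0L, tag = "NM")
    nh <- vapply(aln_f, tagval, 0L, tag = "NH")
    aln <- data.frame(
      queryId = vapply(aln_f, `[`, "", 1L),
      refName = vapply(aln_f, `[`, "", 3L),
      strand = ifelse(bitwAnd(flag[!unmapped_i], 16L) != 0L, "-", "+"),
      start = start, end = start + reflen,
      mismatches = ifelse(is.na(nm), 0L, nm),
      altCount = ifelse(is.na(nh), 0L, pmax(nh - 1L, 0L)),
      stringsAsFactors = FALSE)
  } else aln <- .empty_alignments()
  list(alignments = aln,
       unmapped = vapply(f[unmapped_i], `[`, "", 1L))
}
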