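#' Exhaustively split an unmapped read
#'
#' Splits a read of length L into (left, right) pairs at every offset where
#' both parts are at least `MS` bases, i.e. offsets `MS .. L - MS`: exactly
#' `max(0, L - 2*MS + 1)` pairs. Concatenating the two parts reconstructs
#' the read.
#'
#' @param read read sequence (single character string).
#' @param MS minimum split size in bp.
#' @param readId id used to label the pairs (defaults to the vector name).
#' @return data.frame with `readId`, `splitOffset` (bases in the left part),
#'   `leftSeq`, `rightSeq`; zero rows when the read is shorter than `2*MS`.
#' @export
split_read <- function(read, MS, readId = names(read)) {
  stopifnot(length(read) == 1L, MS >= 1L)
  if (is.null(readId)) readId <- "read"
  L <- nchar(read)
  if (L < 2L * MS)
    return(data.frame(readId = character(), splitOffset = integer(),
                      leftSeq = character(), rightSeq = character(),
                      stringsAsFactors = FALSE))
  offsets <- seq.int(MS, L - MS)
  data.frame(readId = readId, splitOffset = offsets,
             leftSeq = substring(read, 1L, offsets),
             rightSeq = substring(read, offsets + 1L, L),
             stringsAsFactors = FALSE)
}

#' Split a pool of unmapped reads into half queries
#'
#' @param reads named character vector of unmapped read sequences.
#' @param MS minimum split size.
#' @return named character vector of half sequences; names follow the
#'   `<readId>/<offset>/<L|R>` convention consumed by [second_pass()].
#' @export
split_reads <- function(reads, MS) {
  pieces <- lapply(seq_along(reads), function(i)
    split_read(reads[[i]], MS, readId = names(reads)[i]))
  pieces <- do.call(rbind, pieces)
  if (is.null(pieces) || nrow(pieces) == 0L) return(character())
  out <- c(pieces$leftSeq, pieces$rightSeq)
  names(out) <- c(make_half_id(pieces$readId, pieces$splitOffset, "L"),
                  make_half_id(pieces$readId, pieces$splitOffset, "R"))
  out
}

.empty_matched_pairs <- function() {
  data.frame(readId = character(), splitOffset = integer(),
             chrom = character(), strand = character(),
             leftEnd = integer(), rightStart = integer(), gap = integer(),
             stringsAsFactors = FALSE)
}

#' Assemble matched pairs from half alignments
#'
#' A matched pair is the evidence unit for a junction: a left-half and a
#' right-half alignment derived from the same split of the same read, placed
#' colinearly on the same chromosome and strand with a genomic gap within
#' `[minCD, MD]`. On the forward strand the left (5') part of the read maps
#' upstream; on the reverse strand it maps downstream, and coordinates are
#' reported in genomic orientation either way, so the excised region is
#' always `[leftEnd, rightStart)` with spliced length `rightStart - leftEnd`.
#'
#' Work is grouped by read (and split offset), so cost is quadratic only in
#' the placements of one read's halves, not in the whole half pool.
#'
#' @param halfAln half-alignment table from [second_pass()] (columns
#'   `readId`, `splitOffset`, `side`, `refName`, `strand`, `start`, `end`).
#' @param params an [rsr_params()].
#' @return data.frame of matched pairs, sorted by (chrom, leftEnd,
#'   rightStart, readId, splitOffset); independent of input row order.
#' @export
find_matched_pairs <- function(halfAln, params = rsr_params()) {
  needed <- c("readId", "splitOffset", "side", "refName", "strand",
              "start", "end")
  stopifnot(all(needed %in% names(halfAln)))
  if (nrow(halfAln) == 0L) return(.empty_matched_pairs())
  out <- vector("list", 64L); nout <- 0L
  by_read <- split(halfAln, halfAln$readId)
  for (h in by_read) {
    for (off in unique(h$splitOffset)) {
      lh <- h[h$side == "L" & h$splitOffset == off, , drop = FALSE]
      rh <- h[h$side == "R" & h$splitOffset == off, , drop = FALSE]
      if (nrow(lh) == 0L || nrow(rh) == 0L) next
      for (i in seq_len(nrow(lh))) for (j in seq_len(nrow(rh))) {
        if (lh$refName[i] != rh$refName[j] ||
            lh$strand[i] != rh$strand[j]) next
        if (lh$strand[i] == "+") {
          leftEnd <- lh$end[i]; rightStart <- rh$start[j]
        } else {
          # read-order upstream half sits at the larger genomic coordinate
          leftEnd <- rh$end[j]; rightStart <- lh$start[i]
        }
        gap <- rightStart - leftEnd
        if (gap < params$minCD || gap > params$MD) next
        nout <- nout + 1L
        if (nout > length(out)) out <- c(out, vector("list", length(out)))
        out[[nout]] <- data.frame(
          readId = h$readId[1L], splitOffset = off,
          chrom = lh$refName[i], strand = lh$strand[i],
          leftEnd = leftEnd, rightStart = rightStart, gap = gap,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (nout == 0L) return(.empty_matched_pairs())
  mp <- do.call(rbind, out[seq_len(nout)])
  mp <- mp[order(mp$chrom, mp$leftEnd, mp$rightStart, mp$readId,
                 mp$splitOffset), , drop = FALSE]
  rownames(mp) <- NULL
  mp
}

#' Cluster matched pairs into junctions
#'
#' Matched pairs support the same junction when their spliced regions have
#' the same length, lie on the same chromosome and strand, and their left
#' boundaries are within the boundary buffer `BB` of each other.
#' Single-linkage clustering is applied within each (chrom, strand, length)
#' stratum: sorted by left boundary, consecutive pairs are linked while the
#' step is at most `BB`. Each cluster is reported at its modal
#' (leftEnd, rightStart), ties broken toward the smallest leftEnd, and its
#' support is the number of *distinct* reads contributing (a read present
#' through several split offsets or placements counts once).
#'
#' @param matchedPairs table from [find_matched_pairs()].
#' @param BB boundary buffer in bp.
#' @return data.frame of junctions (`chrom`, `strand`, `leftEnd`,
#'   `rightStart`, `length`, `supportCount`, `supportingReadIds` comma-
#'   separated, `status` = NA until [annotate_known()]), sorted by
#'   (chrom, leftEnd).
#' @export
cluster_junctions <- function(matchedPairs, BB) {
  stopifnot(BB >= 0L)
  if (nrow(matchedPairs) == 0L)
    return(data.frame(chrom = character(), strand = character(),
                      leftEnd = integer(), rightStart = integer(),
                      length = integer(), supportCount = integer(),
                      supportingReadIds = character(), status = character(),
                      stringsAsFactors = FALSE))
  mp <- matchedPairs
  mp$length <- mp$rightStart - mp$leftEnd
  strata <- split(mp, list(mp$chrom, mp$strand, mp$length), drop = TRUE)
  rows <- list()
  for (s in strata) {
    s <- s[order(s$leftEnd, s$rightStart, s$readId), , drop = FALSE]
    brk <- c(0L, which(diff(s$leftEnd) > BB), nrow(s))
    for (k in seq_len(length(brk) - 1L)) {
      cl <- s[(brk[k] + 1L):brk[k + 1L], , drop = FALSE]
      tab <- table(cl$leftEnd)
      modal <- as.integer(names(tab)[tab == max(tab)])
      leftEnd <- min(modal)
      reads <- sort(unique(cl$readId))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cl$chrom[1L], strand = cl$strand[1L],
        leftEnd = leftEnd, rightStart = leftEnd + cl$length[1L],
        length = cl$length[1L], supportCount = length(reads),
        supportingReadIds = paste(reads, collapse = ","),
        status = NA_character_, stringsAsFactors = FALSE)
    }
  }
  j <- do.call(rbind, rows)
  j <- j[order(j$chrom, j$leftEnd, j$rightStart, j$strand), , drop = FALSE]
  rownames(j) <- NULL
  j
}

#' Filter junctions by supporting-read count
#'
#' @param junctions junction table.
#' @param minSupport minimum number of distinct supporting reads (inclusive).
#' @return the junctions with `supportCount >= minSupport`, order preserved.
#' @export
filter_junctions <- function(junctions, minSupport) {
  junctions[junctions$supportCount >= minSupport, , drop = FALSE]
}

#' Label junctions as known or novel against the annotation
#'
#' A junction is `known` when an annotated exon-exon boundary pair exists on
#' the same chromosome with the same spliced length and a left boundary
#' within `BB`; otherwise `novel`.
#'
#' @param junctions junction table.
#' @param flanks flank records from [build_junction_flanks()] (their ids
#'   carry the annotated coordinates), or a data.frame as returned by
#'   [parse_flank_ids()].
#' @param BB boundary buffer in bp.
#' @return the junctions with `status` filled in.
#' @export
annotate_known <- function(junctions, flanks, BB) {
  known <- if (is.data.frame(flanks)) flanks else parse_flank_ids(names(flanks))
  if (nrow(junctions) == 0L) return(junctions)
  junctions$status <- vapply(seq_len(nrow(junctions)), function(i) {
    hit <- known$chrom == junctions$chrom[i] &
      (known$rightStart - known$leftEnd) == junctions$length[i] &
      abs(known$leftEnd - junctions$leftEnd[i]) <= BB
    if (any(hit)) "known" else "novel"
  }, "")
  junctions
}

#' Rank junctions by support
#'
#' The most interesting junctions are those with the most supporting reads.
#'
#' @param junctions junction table.
#' @return junctions ordered by descending `supportCount`, ties by
#'   (chrom, leftEnd).
#' @export
rank_junctions <- function(junctions) {
  if (nrow(junctions) == 0L) return(junctions)
  out <- junctions[order(-junctions$supportCount, junctions$chrom,
                         junctions$leftEnd), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write junctions as BED6
#'
#' Coordinates are 0-based half-open; the interval is the excised region.
#' Names are `J<n>|<status>`, the score is the supporting-read count.
#'
#' @param junctions junction table (ranked or not).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_junction_bed <- function(junctions, path) {
  status <- ifelse(is.na(junctions$status), "novel", junctions$status)
  lines <- if (nrow(junctions) == 0L) character() else
    paste(junctions$chrom, junctions$leftEnd, junctions$rightStart,
          paste0("J", seq_len(nrow(junctions)), "|", status),
          junctions$supportCount, junctions$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write the per-junction supporting-read detail table
#'
#' @param junctions junction table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_junction_detail <- function(junctions, path) {
  header <- paste("chrom", "leftEnd", "rightStart", "length", "supportCount",
                  "status", "supportingReadIds", sep = "\t")
  lines <- if (nrow(junctions) == 0L) character() else
    paste(junctions$chrom, junctions$leftEnd, junctions$rightStart,
          junctions$length, junctions$supportCount,
          ifelse(is.na(junctions$status), "novel", junctions$status),
          junctions$supportingReadIds, sep = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}
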