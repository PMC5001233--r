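#' Junctions present in one sample and absent in the other
#'
#' Comparative mode: a junction of sample A is retained when no junction of
#' sample B lies on the same chromosome with the same spliced length and a
#' left boundary within the boundary buffer. This is the case/control
#' subtraction that isolates splicing present in the splicing-competent
#' sample and absent from the negative control. The retained set is ranked
#' by supporting-read count.
#'
#' @param A,B junction tables produced with identical parameters.
#' @param BB boundary buffer in bp (the comparison tolerance reuses the
#'   clustering buffer; no separate knob).
#' @return the unique-to-A junctions, ranked by [rank_junctions()].
#' @export
subtract_junctions <- function(A, B, BB) {
  if (nrow(A) == 0L) return(A)
  keep <- vapply(seq_len(nrow(A)), function(i) {
    !any(B$chrom == A$chrom[i] & B$length == A$length[i] &
           abs(B$leftEnd - A$leftEnd[i]) <= BB)
  }, TRUE)
  rank_junctions(A[keep, , drop = FALSE])
}

#' Side-by-side comparison of two junction sets
#'
#' One row per junction of A, carrying its best admissible match in B (the
#' admissible B junction with the smallest left-boundary difference) when
#' one exists. The symmetric report is obtained by swapping the arguments.
#'
#' @inheritParams subtract_junctions
#' @return data.frame with A columns (`A.*`), matched B columns (`B.*`, NA
#'   when unmatched) and a `verdict` of `"unique-to-A"` or `"shared"`.
#' @export
side_by_side_report <- function(A, B, BB) {
  acols <- c("chrom", "leftEnd", "rightStart", "length", "supportCount")
  out <- lapply(seq_len(nrow(A)), function(i) {
    adm <- which(B$chrom == A$chrom[i] & B$length == A$length[i] &
                   abs(B$leftEnd - A$leftEnd[i]) <= BB)
    row <- stats::setNames(A[i, acols], paste0("A.", acols))
    if (length(adm)) {
      best <- adm[which.min(abs(B$leftEnd[adm] - A$leftEnd[i]))]
      brow <- stats::setNames(B[best, acols], paste0("B.", acols))
      cbind(row, brow, verdict = "shared", stringsAsFactors = FALSE)
    } else {
      brow <- stats::setNames(
        data.frame(NA_character_, NA_integer_, NA_integer_, NA_integer_,
                   NA_integer_), paste0("B.", acols))
      cbind(row, brow, verdict = "unique-to-A", stringsAsFactors = FALSE)
    }
  })
  if (length(out) == 0L) {
    cols <- c(paste0("A.", acols), paste0("B.", acols), "verdict")
    out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                         cols))
    return(out)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write the side-by-side comparison as a tab-separated file
#'
#' @param report from [side_by_side_report()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_side_by_side <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
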