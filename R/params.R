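#' Pipeline parameters
#'
#' Bundle the six parameters that control junction discovery. Defaults mirror
#' the 33 bp thapsigargin-treatment configuration of the motivating study
#' (minimum split size 8, maximum candidate distance 40000, boundary buffer 5,
#' minimum candidate distance 2, minimum support 2, at most 8 equally good
#' alignments per read).
#'
#' @param MS minimum split size in bp: both halves of a split must be at
#'   least this long. Typical values run from 8 up to a third of the read
#'   length; smaller values admit more candidate splits.
#' @param MD maximum candidate distance in bp: the largest admissible gap
#'   between the two aligned halves of one read. Choose it near the average
#'   gene length of the organism.
#' @param minCD minimum candidate distance in bp (inclusive): the smallest
#'   reportable spliced length.
#' @param BB boundary buffer in bp: positional tolerance used when one
#'   matched pair supports another, when junctions are matched against the
#'   annotation, and when junction sets are compared between samples.
#' @param minSupport minimum number of distinct supporting reads a junction
#'   needs to be reported.
#' @param maxGoodAlignments reads (or halves) with more than this many
#'   equally good placements are discarded as ambiguous.
#' @return An object of class `rsr_params` (a validated named list).
#' @examples
#' rsr_params()
#' rsr_params(MS = 11, MD = 50000)
#' @export
rsr_params <- function(MS = 8L, MD = 40000L, minCD = 2L, BB = 5L,
                       minSupport = 2L, maxGoodAlignments = 8L) {
  p <- list(MS = as.integer(MS), MD = as.integer(MD),
            minCD = as.integer(minCD), BB = as.integer(BB),
            minSupport = as.integer(minSupport),
            maxGoodAlignments = as.integer(maxGoodAlignments))
  stopifnot(p$MS >= 1L, p$minCD > 0L, p$minCD <= p$MD, p$BB >= 0L,
            p$minSupport >= 1L, p$maxGoodAlignments >= 1L)
  structure(p, class = "rsr_params")
}

#' @export
print.rsr_params <- function(x, ...) {
  cat("Read-Split-Run parameters:\n")
  cat(sprintf("  min split size (MS):        %d bp\n", x$MS))
  cat(sprintf("  candidate distance:         [%d, %d] bp\n", x$minCD, x$MD))
  cat(sprintf("  boundary buffer (BB):       %d bp\n", x$BB))
  cat(sprintf("  min supporting reads:       %d\n", x$minSupport))
  cat(sprintf("  max good alignments/read:   %d\n", x$maxGoodAlignments))
  invisible(x)
}
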