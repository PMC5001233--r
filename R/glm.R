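#' Run the pipeline across a grid of (MS, MD, BB) parameter settings
#'
#' Executes junction calling for every grid point and records the resulting
#' junction count. The alignment passes are shared across grid points: the
#' pool of unmapped reads is split once at the smallest MS of the grid, the
#' halves are aligned once, and each grid point reuses the subset of halves
#' its MS admits (halves produced at MS = m serve every MS >= m). When a
#' control sample is supplied, the count is the number of case junctions
#' absent from the control (the comparative count the regression models).
#'
#' @param reads named character vector of case-sample read sequences.
#' @param genome named `DNAStringSet` of chromosomes.
#' @param genes gene models from [parse_known_genes()].
#' @param grid data.frame with columns `MS`, `MD`, `BB`; duplicated rows are
#'   dropped with a warning.
#' @param params an [rsr_params()] providing the fixed parameters (minCD,
#'   minSupport, maxGoodAlignments).
#' @param controlReads optional named character vector of control-sample
#'   reads; when given, counts are comparative (case minus control).
#' @param cfg an [aligner_config()].
#' @return data.frame with one row per distinct grid point: `MS`, `MD`,
#'   `BB`, `junctionCount`.
#' @export
run_parameter_grid <- function(reads, genome, genes, grid,
                               params = rsr_params(), controlReads = NULL,
                               cfg = aligner_config()) {
  stopifnot(all(c("MS", "MD", "BB") %in% names(grid)), nrow(grid) >= 1L)
  dup <- duplicated(grid[c("MS", "MD", "BB")])
  if (any(dup)) {
    warning(sum(dup), " duplicated grid point(s) dropped")
    grid <- grid[!dup, , drop = FALSE]
  }
  readLength <- unique(nchar(reads))
  stopifnot(length(readLength) == 1L)
  MSmin <- min(grid$MS)
  flanks <- build_junction_flanks(genes, genome, readLength)
  expanded <- build_expanded_genome(genome, flanks)
  state <- .grid_half_state(reads, expanded, genome, MSmin, cfg)
  stateB <- if (!is.null(controlReads))
    .grid_half_state(controlReads, expanded, genome, MSmin, cfg) else NULL
  counts <- integer(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    p <- rsr_params(MS = grid$MS[g], MD = grid$MD[g], minCD = params$minCD,
                    BB = grid$BB[g], minSupport = params$minSupport,
                    maxGoodAlignments = params$maxGoodAlignments)
    jA <- .call_from_halves(state$halfAln, readLength, p, flanks)
    counts[g] <- if (is.null(stateB)) nrow(jA) else {
      jB <- .call_from_halves(stateB$halfAln, readLength, p, flanks)
      nrow(subtract_junctions(jA, jB, p$BB))
    }
  }
  out <- grid[c("MS", "MD", "BB")]
  out$junctionCount <- counts
  rownames(out) <- NULL
  out
}

.grid_half_state <- function(reads, expanded, genome, MS, cfg) {
  fp <- first_pass(reads, expanded, cfg)
  halves <- split_reads(fp$unmapped, MS)
  halfAln <- if (length(halves))
    second_pass(halves, genome, cfg)
  else cbind(.empty_alignments(),
             data.frame(readId = character(), splitOffset = integer(),
                        side = character(), stringsAsFactors = FALSE))
  list(unmapped = fp$unmapped, halfAln = halfAln)
}

.call_from_halves <- function(halfAln, readLength, params, flanks) {
  keep <- halfAln$splitOffset >= params$MS &
    (readLength - halfAln$splitOffset) >= params$MS
  mp <- find_matched_pairs(halfAln[keep, , drop = FALSE], params)
  j <- cluster_junctions(mp, params$BB)
  j <- filter_junctions(j, params$minSupport)
  annotate_known(j, flanks, params$BB)
}

#' Fit the junction-count response model
#'
#' Ordinary least squares of the junction count on the three pipeline
#' parameters, `count = b0 + b1*MS + b2*MD + b3*BB`, with main effects only
#' and an identity link — the parameter-response model used to predict how
#' many spliced regions a parameter setting will yield.
#'
#' @param runs data.frame from [run_parameter_grid()] (columns `MS`, `MD`,
#'   `BB`, `junctionCount`), at least 4 rows spanning at least two distinct
#'   values of some predictor.
#' @return object of class `rsr_glm` with components `coefficients`
#'   (b0..b3), `rSquared`, `residuals`, `fitted`, `model` (the underlying
#'   [stats::lm] fit) and `runs`.
#' @seealso [predict_count()]
#' @export
fit_rsr_glm <- function(runs) {
  stopifnot(all(c("MS", "MD", "BB", "junctionCount") %in% names(runs)))
  if (nrow(runs) < 4L)
    stop("at least 4 grid runs are needed to fit 4 coefficients (got ",
         nrow(runs), ")")
  constant <- c("MS", "MD", "BB")[vapply(runs[c("MS", "MD", "BB")],
                                         function(v) length(unique(v)) == 1L,
                                         TRUE)]
  if (length(constant))
    stop("design matrix is rank-deficient; constant predictor(s): ",
         paste(constant, collapse = ", "))
  X <- cbind(1, runs$MS, runs$MD, runs$BB)
  colnames(X) <- c("(Intercept)", "MS", "MD", "BB")
  qrX <- qr(X)
  if (qrX$rank < 4L) {
    dropped <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    stop("design matrix is rank-deficient; collinear predictor(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm(junctionCount ~ MS + MD + BB, data = runs)
  res <- stats::residuals(fit)
  rss <- sum(res^2)
  tss <- sum((runs$junctionCount - mean(runs$junctionCount))^2)
  r2 <- if (tss == 0) 1 else max(0, min(1, 1 - rss / tss))
  structure(list(coefficients = stats::coef(fit), rSquared = r2,
                 residuals = res, fitted = stats::fitted(fit),
                 model = fit, runs = runs),
            class = "rsr_glm")
}

#' Predict a junction count from a fitted parameter-response model
#'
#' @param fit an `rsr_glm` object.
#' @param MS,MD,BB parameter values (vectors recycle as usual).
#' @return predicted counts, clipped below at 0 for reporting.
#' @export
predict_count <- function(fit, MS, MD, BB) {
  stopifnot(inherits(fit, "rsr_glm"))
  b <- fit$coefficients
  pmax(0, b[["(Intercept)"]] + b[["MS"]] * MS + b[["MD"]] * MD +
         b[["BB"]] * BB)
}

#' @export
coef.rsr_glm <- function(object, ...) object$coefficients

#' @export
residuals.rsr_glm <- function(object, ...) object$residuals

#' @export
predict.rsr_glm <- function(object, newdata = NULL, clip = TRUE, ...) {
  if (is.null(newdata)) {
    p <- object$fitted
  } else {
    p <- stats::predict(object$model, newdata = newdata)
  }
  if (clip) pmax(0, p) else p
}

#' @export
print.rsr_glm <- function(x, ...) {
  cat("Junction-count response model (OLS):\n")
  cat(sprintf("  count = %.4g + %.4g*MS + %.4g*MD + %.4g*BB\n",
              x$coefficients[["(Intercept)"]], x$coefficients[["MS"]],
              x$coefficients[["MD"]], x$coefficients[["BB"]]))
  cat(sprintf("  R-squared: %.4f over %d grid runs\n",
              x$rSquared, nrow(x$runs)))
  invisible(x)
}

#' @export
summary.rsr_glm <- function(object, ...) {
  s <- summary(object$model)
  cat("Junction-count response model over", nrow(object$runs),
      "grid runs\n\n")
  stats::printCoefmat(s$coefficients)
  cat(sprintf("\nR-squared: %.4f\n", object$rSquared))
  invisible(s)
}

#' Write grid runs and fit summary as tab-separated output
#'
#' @param runs grid-run table.
#' @param fit an `rsr_glm` object (optional).
#' @param path output file for the runs; the fit summary goes to
#'   `<path>.fit.tsv`.
#' @return `path`, invisibly.
#' @export
write_grid_report <- function(runs, fit = NULL, path) {
  utils::write.table(runs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(fit)) {
    co <- data.frame(term = names(fit$coefficients),
                     estimate = unname(fit$coefficients))
    co <- rbind(co, data.frame(term = "rSquared", estimate = fit$rSquared))
    utils::write.table(co, paste0(path, ".fit.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
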