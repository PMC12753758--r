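#' Dice score for one class
#'
#' \code{2 |P ∩ R| / (|P| + |R|)} where P and R are the predicted and
#' reference pixel sets of \code{classCode}. Pixels carrying the ignore
#' code in the reference are excluded from both sets. When
#' \code{|P| + |R| = 0} the score is undefined and \code{NA} is returned
#' (callers skip it rather than imputing 0 or 1).
#'
#' @param pred,ref [LabelMask-class] objects (or integer matrices) of the
#'   same shape; \code{ref} supplies the ignore convention when it is a
#'   LabelMask.
#' @param classCode integer class code to score.
#' @return Dice in [0, 1], or NA when undefined.
#' @examples
#' sc <- ClassScheme(c("bg", "tumor"), 0:1, tumorCodes = 1L)
#' a <- LabelMask(matrix(c(1L, 1L, 0L, 0L), 2), sc)
#' diceScore(a, a, 1L)  # 1
#' @export
diceScore <- function(pred, ref, classCode) {
  sets <- evalPixelSets(pred, ref, classCode)
  if (sets$nP + sets$nR == 0L) return(NA_real_)
  2 * sets$nI / (sets$nP + sets$nR)
}

#' Sensitivity (recall) and positive predictive value (precision)
#'
#' Sensitivity \code{|P ∩ R| / |R|} and PPV \code{|P ∩ R| / |P|}; each is
#' NA when its denominator is zero (undefined, skipped by aggregation).
#'
#' @inheritParams diceScore
#' @return named numeric vector \code{c(sensitivity=, ppv=)}.
#' @export
sensitivityPpv <- function(pred, ref, classCode) {
  sets <- evalPixelSets(pred, ref, classCode)
  c(sensitivity = if (sets$nR == 0L) NA_real_ else sets$nI / sets$nR,
    ppv = if (sets$nP == 0L) NA_real_ else sets$nI / sets$nP)
}

# Shared pixel-set counting with ignore exclusion and shape check.
evalPixelSets <- function(pred, ref, classCode) {
  p <- if (is(pred, "LabelMask")) pred@codes else pred
  r <- if (is(ref, "LabelMask")) ref@codes else ref
  if (!identical(dim(p), dim(r)))
    stop("prediction and reference masks differ in shape")
  if (is(ref, "LabelMask")) {
    keep <- r != ref@scheme@ignoreCode
    p <- p[keep]; r <- r[keep]
  }
  list(nI = sum(p == classCode & r == classCode),
       nP = sum(p == classCode), nR = sum(r == classCode))
}

#' Score a predicted mask against a reference over several classes
#'
#' @inheritParams diceScore
#' @param scheme [ClassScheme-class] naming the classes.
#' @param classes integer codes to score; defaults to all scheme codes.
#' @param unit identifier recorded in the output (e.g. a ROI or slide id).
#' @return data.frame with columns \code{unit}, \code{class} (label),
#'   \code{code}, \code{dice}, \code{sensitivity}, \code{ppv}; undefined
#'   scores are NA.
#' @export
scoreMask <- function(pred, ref, scheme, classes = scheme@codes,
                      unit = "unit") {
  rows <- lapply(classes, function(cd) {
    sp <- sensitivityPpv(pred, ref, cd)
    data.frame(unit = unit,
               class = scheme@labels[match(cd, scheme@codes)],
               code = cd, dice = diceScore(pred, ref, cd),
               sensitivity = sp[["sensitivity"]], ppv = sp[["ppv"]])
  })
  do.call(rbind, rows)
}

#' Aggregate per-unit Dice scores into a report
#'
#' Means are taken over units within each dataset, macro-averaged across
#' datasets, then mean and sample (n-1) standard deviation across
#' replicate runs. Undefined (NA) scores are skipped, never imputed. The
#' combined tumor + tumor-stroma series is the per-unit mean over the two
#' tumor classes — the series the paired t-test compares.
#'
#' @param scores data.frame with columns \code{unit}, \code{class},
#'   \code{dice}, and optionally \code{dataset} and \code{replicate}
#'   (missing columns are treated as a single dataset / replicate).
#' @param tumorClasses labels of the two tumor classes for the combined
#'   series.
#' @return a list of class \code{"DiceReport"}: \code{perUnit} (the input),
#'   \code{perClass} (class, mean, sd, n over replicates; sd 0 with n = 1),
#'   \code{combinedTumorStroma} (per unit-replicate combined means).
#' @export
aggregateScores <- function(scores,
                            tumorClasses = c("tumor", "tumor_stroma")) {
  if (!nrow(scores)) stop("no scores to aggregate")
  if (!"dataset" %in% names(scores)) scores$dataset <- "all"
  if (!"replicate" %in% names(scores)) scores$replicate <- 1L
  ok <- !is.na(scores$dice)
  if (!any(ok)) stop("all scores are undefined after skipping")
  sc <- scores[ok, , drop = FALSE]
  # class x replicate: mean over units within dataset, macro across datasets
  perDataset <- stats::aggregate(dice ~ class + replicate + dataset,
                                 data = sc, FUN = mean)
  perReplicate <- stats::aggregate(dice ~ class + replicate,
                                   data = perDataset, FUN = mean)
  agg <- do.call(rbind, lapply(split(perReplicate, perReplicate$class),
    function(g) data.frame(class = g$class[1L], mean = mean(g$dice),
                           sd = if (nrow(g) > 1L) stats::sd(g$dice) else 0,
                           n = nrow(g))))
  rownames(agg) <- NULL
  comb <- sc[sc$class %in% tumorClasses, , drop = FALSE]
  combined <- if (nrow(comb))
    stats::aggregate(dice ~ unit + replicate + dataset, data = comb,
                     FUN = mean)
  else comb
  structure(list(perUnit = scores, perClass = agg,
                 combinedTumorStroma = combined),
            class = "DiceReport")
}

#' @export
print.DiceReport <- function(x, ...) {
  cat("DiceReport\n")
  cat(sprintf("  %d unit-class scores, %d class(es)\n",
              nrow(x$perUnit), nrow(x$perClass)))
  for (i in seq_len(nrow(x$perClass)))
    cat(sprintf("  %-20s %.4f +/- %.4f (n=%d)\n", x$perClass$class[i],
                x$perClass$mean[i], x$perClass$sd[i], x$perClass$n[i]))
  invisible(x)
}

#' Paired t-test on two score series
#'
#' \code{t = mean(d) / (sd(d) / sqrt(n))} with \code{d = a - b} and
#' \code{n - 1} degrees of freedom; the two-sided p-value comes from the
#' t distribution. Used to compare the combined tumor + tumor-stroma Dice
#' series of two training paradigms over the same evaluation units.
#'
#' @param a,b numeric vectors of equal length n >= 2, paired by unit.
#' @return list with elements \code{t}, \code{p} (two-sided), \code{n},
#'   \code{df}, \code{meanDiff}.
#' @examples
#' pairedTTest(c(2, 3, 4), c(1, 1, 1))  # t ~ 3.4641, p ~ 0.07418
#' @export
pairedTTest <- function(a, b) {
  if (length(a) != length(b)) stop("series must have equal length")
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs")
  d <- a - b
  s <- stats::sd(d)
  if (s == 0) stop("zero-variance differences: paired t-test is degenerate")
  t <- mean(d) / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1L), n = n, df = n - 1L,
       meanDiff = mean(d))
}

#' Write an evaluation report as CSV and JSON
#'
#' @param report a \code{DiceReport} from [aggregateScores()].
#' @param csvPath per-unit scores CSV (unit, class, dice, sensitivity, ppv).
#' @param jsonPath summary JSON (per-class means/sds, optional test).
#' @param test optional result of [pairedTTest()] to embed.
#' @return invisibly, the report.
#' @export
writeDiceReport <- function(report, csvPath = NULL, jsonPath = NULL,
                            test = NULL) {
  if (!is.null(csvPath))
    utils::write.csv(report$perUnit, csvPath, row.names = FALSE)
  if (!is.null(jsonPath)) {
    out <- list(per_class = report$perClass)
    if (!is.null(test)) out$paired_t <- test
    jsonlite::write_json(out, jsonPath, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(report)
}
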