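# Confusion-matrix tallying and the seven splice-site evaluation metrics:
# sensitivity, specificity, accuracy, Matthews correlation coefficient,
# positive predictive value, performance coefficient (a Jaccard-style
# detection score TP/(TP+FN+FP)) and F1. All formulas are scale-invariant,
# so cells may be raw counts or percentages of the total.

#' Tally a 2x2 confusion matrix
#'
#' @param truth,predicted Binary (0/1 or logical) label vectors of equal
#'   length.
#' @param as_percent If \code{TRUE}, cells are expressed as percentage of
#'   the total rather than raw counts.
#' @return Object of class \code{confusion_counts} with fields \code{TP},
#'   \code{FP}, \code{FN}, \code{TN} and a \code{units} marker
#'   (\code{"count"} or \code{"percent"}).
#' @export
tally_confusion <- function(truth, predicted, as_percent = FALSE) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  if (!length(truth)) stop("empty label vectors")
  if (!all(truth %in% 0:1) || !all(predicted %in% 0:1))
    stop("labels must be binary 0/1")
  cc <- confusion_counts(TP = sum(truth == 1L & predicted == 1L),
                         FP = sum(truth == 0L & predicted == 1L),
                         FN = sum(truth == 1L & predicted == 0L),
                         TN = sum(truth == 0L & predicted == 0L))
  if (as_percent) {
    n <- length(truth)
    cc[c("TP", "FP", "FN", "TN")] <-
      lapply(cc[c("TP", "FP", "FN", "TN")], function(v) 100 * v / n)
    cc$units <- "percent"
  }
  cc
}

#' Construct confusion counts directly
#'
#' Cells may be fractional (e.g. percentage-of-total values printed in a
#' report); all derived metrics are invariant to a common scale factor.
#'
#' @param TP,FP,FN,TN Non-negative cell values.
#' @param units \code{"count"} or \code{"percent"}.
#' @return Object of class \code{confusion_counts}.
#' @export
confusion_counts <- function(TP, FP, FN, TN, units = "count") {
  vals <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("confusion cells must be finite and non-negative")
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN,
                 units = match.arg(units, c("count", "percent"))),
            class = "confusion_counts")
}

metric_names <- c("Sn", "Sp", "Acc", "Mcc", "Ppv", "Pc", "F1")

#' The seven evaluation metrics
#'
#' Computes, on a 0-100 scale (Mcc on -100..100):
#' \describe{
#'   \item{Sn}{TP/(TP+FN), sensitivity}
#'   \item{Sp}{TN/(TN+FP), specificity}
#'   \item{Acc}{(TP+TN)/(TP+FP+FN+TN), accuracy}
#'   \item{Mcc}{(TP*TN - FN*FP)/sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))}
#'   \item{Ppv}{TP/(TP+FP), positive predictive value}
#'   \item{Pc}{TP/(TP+FN+FP), performance coefficient}
#'   \item{F1}{2TP/(2TP+FP+FN), harmonic mean of Ppv and Sn}
#' }
#' Any metric whose denominator is zero is flagged invalid (rendered
#' \code{"-"}) rather than forced to a number. Single-class prediction
#' columns additionally raise the training-failure flag.
#'
#' @param c A \code{\link{confusion_counts}} object.
#' @return Object of class \code{metrics_report}: named \code{values}
#'   (full precision, \code{NA} when invalid), \code{valid} flags and
#'   \code{training_failure}.
#' @export
compute_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  # doubles throughout: the Mcc denominator overflows integer counts
  TP <- as.numeric(c$TP); FP <- as.numeric(c$FP)
  FN <- as.numeric(c$FN); TN <- as.numeric(c$TN)
  total <- TP + FP + FN + TN
  if (total <= 0) stop("all-zero confusion counts")
  safe <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  mcc_den <- (TP + FN) * (TN + FP) * (TP + FP) * (TN + FN)
  values <- c(Sn = safe(TP, TP + FN),
              Sp = safe(TN, TN + FP),
              Acc = safe(TP + TN, total),
              Mcc = if (mcc_den > 0) 100 * (TP * TN - FN * FP) / sqrt(mcc_den)
                    else NA_real_,
              Ppv = safe(TP, TP + FP),
              Pc = safe(TP, TP + FN + FP),
              F1 = safe(2 * TP, 2 * TP + FP + FN))
  structure(list(values = values, valid = !is.na(values),
                 training_failure = detect_training_failure(c)),
            class = "metrics_report")
}

#' Detect a degenerate (single-class) prediction column
#'
#' A training run that collapses to predicting only one class fills a single
#' prediction row of the confusion matrix (TP+FP equals the total, or
#' TN+FN does); such a column is not eligible for method comparison.
#'
#' @param c A \code{\link{confusion_counts}} object.
#' @return Logical flag.
#' @export
detect_training_failure <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$TP + c$FP + c$FN + c$TN
  if (total <= 0) stop("all-zero confusion counts")
  (c$TP + c$FP) == total || (c$TN + c$FN) == total
}

#' Render a metrics report as a fixed one-decimal text table
#'
#' Invalid metrics print as \code{"-"}; a training failure is marked with
#' \code{"*"} on the header line.
#'
#' @param r A \code{metrics_report}.
#' @return Character vector of table lines (also usable via
#'   \code{cat(format_report(r), sep = "\n")}).
#' @export
format_report <- function(r) {
  stopifnot(inherits(r, "metrics_report"))
  vals <- vapply(metric_names, function(m)
    if (r$valid[[m]]) sprintf("%.1f", r$values[[m]]) else "-", character(1L))
  header <- paste0("metric\tvalue", if (r$training_failure) "\t*" else "")
  c(header, paste(metric_names, vals, sep = "\t"))
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Parse a table produced by \code{\link{format_report}}
#'
#' @param lines Character vector of report lines.
#' @return Named numeric vector of the seven metrics (NA where invalid),
#'   with attribute \code{training_failure}.
#' @export
parse_report <- function(lines) {
  body <- lines[-1L]
  parts <- strsplit(body, "\t", fixed = TRUE)
  vals <- vapply(parts, function(p)
    if (identical(p[2L], "-")) NA_real_ else as.numeric(p[2L]), numeric(1L))
  names(vals) <- vapply(parts, `[[`, character(1L), 1L)
  attr(vals, "training_failure") <- grepl("\\*$", lines[1L])
  vals
}

#' Export a metrics report to TSV or JSON
#'
#' @param r A \code{metrics_report}.
#' @param path Output path; format chosen by extension (\code{.json} or TSV
#'   otherwise).
#' @export
write_report <- function(r, path) {
  stopifnot(inherits(r, "metrics_report"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    vals <- as.list(round(r$values, 1))
    vals[!r$valid] <- list(NULL)
    jsonlite::write_json(c(vals, list(training_failure = r$training_failure)),
                         path, auto_unbox = TRUE, null = "null", digits = NA)
  } else {
    writeLines(format_report(r), path)
  }
  invisible(path)
}
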