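#' Confusion counts for binary screening
#'
#' CHD is the positive class; a predicted probability at or above the
#' threshold counts as positive.
#'
#' @param labels Vector in `{0, 1}` (1 = CHD) or `"normal"`/`"chd"`.
#' @param predictions Probabilities in `[0, 1]`.
#' @param threshold Decision threshold.
#' @return Named integer vector `c(TP, FN, TN, FP)`.
#' @export
confusion_counts <- function(labels, predictions, threshold = 0.5) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.integer(tolower(as.character(labels)) == "chd")
  }
  if (length(labels) != length(predictions)) {
    stop("labels and predictions must have equal length")
  }
  if (any(!labels %in% c(0, 1))) stop("labels must be 0/1 or normal/chd")
  pos <- predictions >= threshold
  c(TP = sum(labels == 1 & pos), FN = sum(labels == 1 & !pos),
    TN = sum(labels == 0 & !pos), FP = sum(labels == 0 & pos))
}

#' Screening evaluation report
#'
#' Computes sensitivity `Se = TP/(TP+FN)`, specificity
#' `Sp = TN/(TN+FP)`, accuracy `Acc = (TP+TN)/N` (all in percent), the
#' mean accuracy `MAcc = (Se+Sp)/2` (equal 0.5 weights on both terms),
#' and the F-score `F_beta = (1+beta^2) Sp Se / (beta^2 Sp + Se)`.
#' Metrics are computed at full precision; rounding to two decimals
#' happens only when printing. A metric whose denominator class is empty
#' is reported as `NA` rather than zero.
#'
#' @param TP,FN,TN,FP Non-negative counts, or a single named vector from
#'   [confusion_counts()] passed as `TP`.
#' @param beta F-score weight (default 1).
#' @return An `eval_report` list with the counts and metrics (percent).
#' @export
eval_report <- function(TP, FN = NULL, TN = NULL, FP = NULL, beta = 1) {
  if (length(TP) == 4L && is.null(FN)) {
    cc <- TP
    TP <- cc[["TP"]]; FN <- cc[["FN"]]; TN <- cc[["TN"]]; FP <- cc[["FP"]]
  }
  counts <- c(TP, FN, TN, FP)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  se <- if (TP + FN > 0) TP / (TP + FN) * 100 else NA_real_
  sp <- if (TN + FP > 0) TN / (TN + FP) * 100 else NA_real_
  acc <- if (sum(counts) > 0) (TP + TN) / sum(counts) * 100 else NA_real_
  macc <- metric_macc(se, sp)
  fb <- metric_fbeta(se, sp, beta)
  structure(
    list(TP = TP, FN = FN, TN = TN, FP = FP,
         Se = se, Sp = sp, Acc = acc, MAcc = macc, F_beta = fb,
         beta = beta),
    class = "eval_report"
  )
}

#' Mean accuracy and F-score from printed sensitivity/specificity
#'
#' Worked-example helpers: combine an Se/Sp pair (percent) exactly as
#' the evaluation defines them. `metric_macc` is the unweighted mean
#' with 0.5 coefficients on each term; `metric_fbeta` is the
#' beta-weighted harmonic-style combination of Sp and Se.
#'
#' @param se,sp Sensitivity and specificity in percent.
#' @param beta Weight (default 1).
#' @export
metric_macc <- function(se, sp) {
  if (is.na(se) || is.na(sp)) return(NA_real_)
  (se + sp) / 2
}

#' @rdname metric_macc
#' @export
metric_fbeta <- function(se, sp, beta = 1) {
  if (is.na(se) || is.na(sp)) return(NA_real_)
  (1 + beta^2) * sp * se / (beta^2 * sp + se)
}

#' Round half-up to a number of decimals (table formatting)
#' @param x Numeric. @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' @export
print.eval_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else
    sprintf("%.2f", round_half_up(v, 2))
  cat(sprintf("Eval report (N = %d): TP=%d FN=%d TN=%d FP=%d\n",
              x$TP + x$FN + x$TN + x$FP, x$TP, x$FN, x$TN, x$FP))
  cat(sprintf("  Acc %s  Se %s  Sp %s  MAcc %s  F%g %s  (percent)\n",
              fmt(x$Acc), fmt(x$Se), fmt(x$Sp), fmt(x$MAcc),
              x$beta, fmt(x$F_beta)))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' JSON plus a one-row CSV in table column order
#' (Acc, Se, Sp, MAcc, F_score).
#'
#' @param report An [eval_report()].
#' @param path Output path without extension; writes `<path>.json` and
#'   `<path>.csv`.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(unclass(report), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  row <- data.frame(
    Acc = round_half_up(report$Acc, 2), Se = round_half_up(report$Se, 2),
    Sp = round_half_up(report$Sp, 2), MAcc = round_half_up(report$MAcc, 2),
    F_score = round_half_up(report$F_beta, 2)
  )
  utils::write.csv(row, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}
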