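# Confusion-matrix metrics: accuracy, predictive values, sensitivity,
# specificity, Cohen's kappa.

#' Confusion counts for two-class predictions
#'
#' @param y_true,y_pred label vectors of equal length, drawn from a 2-class
#'   label set.
#' @param positive_class label treated as positive; defaults to the first
#'   class lexicographically.
#' @return An object of class `confusion_counts` with fields `TP`, `TN`,
#'   `FP`, `FN`, `positive_class`, `negative_class`. The four counts
#'   partition the trials.
#' @examples
#' cm <- confusion(c("L", "L", "R"), c("L", "R", "R"))
#' cm$TP; cm$FN
#' @export
confusion <- function(y_true, y_pred, positive_class = NULL) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1L) {
    tfb_stop("y_true and y_pred must have equal positive length",
             "tfbcsp_contract_error")
  }
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  classes <- sort(unique(c(y_true, y_pred)))
  if (length(classes) > 2L) {
    tfb_stop("labels must come from a 2-class set", "tfbcsp_contract_error")
  }
  positive_class <- positive_class %||% classes[1]
  if (!positive_class %in% classes && length(classes) == 2L) {
    tfb_stop(sprintf("unknown positive class '%s'", positive_class),
             "tfbcsp_contract_error")
  }
  negative_class <- setdiff(classes, positive_class)
  if (length(negative_class) == 0L) negative_class <- NA_character_
  tp <- sum(y_true == positive_class & y_pred == positive_class)
  tn <- sum(y_true != positive_class & y_pred != positive_class)
  fp <- sum(y_true != positive_class & y_pred == positive_class)
  fn <- sum(y_true == positive_class & y_pred != positive_class)
  structure(
    list(TP = tp, TN = tn, FP = fp, FN = fn,
         positive_class = positive_class, negative_class = negative_class[1]),
    class = "confusion_counts"
  )
}

#' Performance report from confusion counts
#'
#' Computes accuracy, positive/negative predictive value, sensitivity (TPR),
#' specificity (TNR), the observed and chance agreement proportions, and
#' Cohen's kappa `(Po - Pe) / (1 - Pe)` with the marginal chance agreement
#' `Pe = [(TP+FP)(TP+FN) + (TN+FN)(TN+FP)] / total^2`. A ratio with zero
#' denominator is reported as `NaN` with a warning, never silently zero.
#'
#' @param counts a `confusion_counts` object.
#' @return An object of class `metrics_report` with fields `accuracy`,
#'   `PPV`, `NPV`, `TPR`, `TNR`, `Po`, `Pe`, `kappa`, `total`.
#' @examples
#' report(confusion(rep(c("L", "R"), c(50, 50)),
#'                  rep(c("L", "R", "L", "R"), c(40, 10, 10, 40))))
#' @export
report <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  total <- tp + tn + fp + fn
  if (total <= 0) tfb_stop("no evaluated trials", "tfbcsp_contract_error")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what))
      return(NaN)
    }
    num / den
  }
  po <- (tp + tn) / total
  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / total^2
  structure(
    list(accuracy = po,
         PPV = ratio(tp, tp + fp, "PPV"),
         NPV = ratio(tn, tn + fn, "NPV"),
         TPR = ratio(tp, tp + fn, "TPR"),
         TNR = ratio(tn, tn + fp, "TNR"),
         Po = po,
         Pe = pe,
         kappa = if (pe == 1) {
           warning("kappa undefined (chance agreement is 1)"); NaN
         } else (po - pe) / (1 - pe),
         total = total),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> n = %d\n  accuracy %.4f | PPV %.4f NPV %.4f | TPR %.4f TNR %.4f | kappa %.4f\n",
    x$total, x$accuracy, x$PPV, x$NPV, x$TPR, x$TNR, x$kappa))
  invisible(x)
}

# Delimited export mirroring a metric-by-subject table layout.
#' Export one or more metric reports as a delimited table
#'
#' @param reports named list of `metrics_report` objects (e.g. one per
#'   subject or per fold).
#' @param path optional file path; when given, the table is written as TSV.
#' @return data.frame with one column per report and one row per metric.
#' @export
metrics_table <- function(reports, path = NULL) {
  fields <- c("accuracy", "PPV", "NPV", "TPR", "TNR", "kappa")
  tab <- data.frame(
    measurement = fields,
    vapply(reports, function(r) unlist(r[fields]), numeric(length(fields))),
    check.names = FALSE
  )
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  tab
}
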