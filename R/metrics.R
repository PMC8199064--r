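#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes.
#'
#' @param y_true,y_pred Equal-length integer label vectors with values in
#'   `classes`.
#' @param classes Class codes (default 1:5).
#' @return A `confusion_matrix` (square integer matrix).
#' @export
confusion <- function(y_true, y_pred, classes = 1:5) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length")
  }
  if (!all(y_true %in% classes) || !all(y_pred %in% classes)) {
    stop("labels outside the class set ", paste(classes, collapse = ","))
  }
  f <- factor(y_true, levels = classes)
  g <- factor(y_pred, levels = classes)
  cm <- unclass(table(f, g))
  dimnames(cm) <- list(true = as.character(classes),
                       predicted = as.character(classes))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Overall accuracy
#'
#' All correct predictions (confusion-matrix main diagonal) divided by all
#' predictions made.
#'
#' @param cm A `confusion_matrix`.
#' @return Scalar in `[0, 1]`.
#' @export
oacc <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(cm)) / total
}

# One-vs-rest TP/TN/FP/FN decomposition for class k.
ovr_counts <- function(cm, k) {
  k <- as.character(k)
  if (!k %in% rownames(cm)) stop("class ", k, " not present in the matrix")
  tp <- cm[k, k]
  fn <- sum(cm[k, ]) - tp
  fp <- sum(cm[, k]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

#' Per-class accuracy, sensitivity, specificity and error
#'
#' One-vs-rest metrics for a single class: `ACC = (TP+TN)/total`,
#' `SEN = TP/(TP+FN)`, `SPE = TN/(TN+FP)`, `Error = (FP+FN)/total`
#' (so `ACC + Error = 1` identically). A metric whose denominator is zero
#' (e.g. sensitivity of an absent class) is undefined and reported as `NA`,
#' never as 0.
#'
#' @param cm A `confusion_matrix`.
#' @param class_k Class code.
#' @return Named list `ACC`, `SEN`, `SPE`, `Error`.
#' @export
class_metrics <- function(cm, class_k) {
  if (sum(cm) == 0) stop("empty confusion matrix")
  ct <- ovr_counts(cm, class_k)
  total <- sum(ct)
  list(ACC = (ct["TP"] + ct["TN"]) / total,
       SEN = if (ct["TP"] + ct["FN"] > 0) ct["TP"] / (ct["TP"] + ct["FN"])
             else NA_real_,
       SPE = if (ct["TN"] + ct["FP"] > 0) ct["TN"] / (ct["TN"] + ct["FP"])
             else NA_real_,
       Error = (ct["FP"] + ct["FN"]) / total) |>
    lapply(unname)
}

#' Sensitivity of the merged blood class
#'
#' Venous and arterial blood are clinically interchangeable during
#' resection, so they are merged into one blood class:
#' `SEN_blood = (TP_arterial + TP_venous) /
#'   ((TP_arterial + FN_arterial) + (TP_venous + FN_venous))`.
#' By default, cross-predictions between venous and arterial count as true
#' positives of the merged class (a vein predicted as artery is still
#' blood); `strict = TRUE` keeps them as errors.
#'
#' @param cm A `confusion_matrix` containing the venous and arterial rows.
#' @param strict Count venous<->arterial confusions as errors.
#' @param venous,arterial Class codes of the two blood classes.
#' @return Scalar in `[0, 1]`, or `NA` if there are no blood samples.
#' @export
blood_sen <- function(cm, strict = FALSE, venous = 3, arterial = 4) {
  v <- as.character(venous); a <- as.character(arterial)
  if (!all(c(v, a) %in% rownames(cm))) {
    stop("venous and arterial rows must be present")
  }
  denom <- sum(cm[v, ]) + sum(cm[a, ])
  if (denom == 0) return(NA_real_)
  tp <- cm[v, v] + cm[a, a]
  if (!strict) tp <- tp + cm[v, a] + cm[a, v]
  unname(tp / denom)
}

#' Overall accuracy per spectral band
#'
#' Normalizes an overall accuracy (in percent) by the number of spectral
#' bands the camera uses, enabling comparison between systems of very
#' different spectral resolution. Reported rounded half-up to 2 decimals.
#'
#' @param oacc_percent Overall accuracy in percent (e.g. 60 for 60%).
#' @param n_bands Positive band count.
#' @return OACC-per-band in percent, 2 decimals.
#' @export
#' @examples
#' oacc_per_band(60, 25)  # 2.4
#' oacc_per_band(80, 128) # 0.63
oacc_per_band <- function(oacc_percent, n_bands) {
  if (!(n_bands > 0)) stop("`n_bands` must be positive")
  round_half_up(oacc_percent / n_bands, 2)
}

#' Full metric report from a confusion matrix
#'
#' @param cm A `confusion_matrix`.
#' @param n_bands Optional band count; if given, OACC-per-band is included.
#' @return A `metric_report`: `OACC`, `per_class` data.frame (ACC, SEN,
#'   SPE, Error per class), `blood_SEN`, optional `OACC_per_band`, and the
#'   confusion matrix itself.
#' @export
metric_report <- function(cm, n_bands = NULL) {
  per <- do.call(rbind, lapply(rownames(cm), function(k) {
    m <- class_metrics(cm, k)
    data.frame(class = k, ACC = m$ACC, SEN = m$SEN, SPE = m$SPE,
               Error = m$Error)
  }))
  if (identical(rownames(cm), as.character(1:5))) {
    per$class <- names(hsi_classes())
  }
  out <- list(OACC = oacc(cm), per_class = per, blood_SEN = blood_sen(cm),
              confusion = cm)
  if (!is.null(n_bands)) {
    out$OACC_per_band <- oacc_per_band(100 * out$OACC, n_bands)
  }
  structure(out, class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  cat("OACC:", format(x$OACC, digits = digits))
  if (!is.null(x$OACC_per_band)) {
    cat("   OACC/band:", x$OACC_per_band, "%")
  }
  cat("   blood SEN:", format(x$blood_SEN, digits = digits), "\n")
  print(format(x$per_class, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Aggregate overall accuracies across images
#'
#' Mean and standard deviation of per-image OACC values, as reported in
#' per-patient result tables. The SD is the population SD by default
#' (divisor n); set `sd_type = "sample"` for the n-1 convention.
#'
#' @param oaccs Numeric vector of per-image OACC values.
#' @param sd_type `"population"` or `"sample"`.
#' @return Named list `mean`, `sd`, `n`.
#' @export
summarize_oacc <- function(oaccs, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  n <- length(oaccs)
  m <- mean(oaccs)
  s <- if (n > 1) {
    v <- sum((oaccs - m)^2) / if (sd_type == "population") n else n - 1
    sqrt(v)
  } else 0
  list(mean = m, sd = s, n = n)
}
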