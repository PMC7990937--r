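#' Classify residual HFO from the post-resection rate
#'
#' A channel (or patient, via the maximal-rate channel) has residual HFOs
#' when its post-resection HFO rate is at least 1 HFO/min (inclusive
#' threshold).
#'
#' @param rate post-resection maximal HFO rate(s), events/min.
#' @param threshold residual threshold in events/min (default 1).
#' @return Character vector, `"residual"` or `"no_residual"`.
#' @export
classifyResidual <- function(rate, threshold = 1) {
  if (any(rate < 0)) stop("rates must be non-negative")
  ifelse(rate >= threshold, "residual", "no_residual")
}

#' Predict seizure outcome from residual HFOs
#'
#' Retrospective outcome "prediction": seizure freedom (ILAE 1) is predicted
#' for patients without residual HFOs (post-resection maximal rate below
#' 1 HFO/min) and seizure recurrence (ILAE 2-6) for patients with residual
#' HFOs. Each patient is labelled against the observed outcome: TP =
#' residual HFO and recurrence, TN = no residual and freedom, FP = residual
#' and freedom, FN = no residual and recurrence.
#'
#' @param records data.frame with columns `patient_id`, `post_max_rate`
#'   (events/min) and `ilae` (integer 1-6); extra columns pass through.
#' @param threshold residual threshold in events/min (default 1).
#' @return A list with `patients` (the records plus `prediction`, `outcome`
#'   and `label` columns) and `counts` (named vector `tp`, `tn`, `fp`, `fn`).
#' @export
predictOutcomes <- function(records, threshold = 1) {
  needed <- c("patient_id", "post_max_rate", "ilae")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop("patient records miss column(s): ", paste(missing, collapse = ", "))
  if (!nrow(records)) stop("need at least one patient record")
  if (!all(records$ilae %in% 1:6)) stop("ilae must be an integer in 1..6")
  residual <- classifyResidual(records$post_max_rate, threshold) == "residual"
  records$prediction <- ifelse(residual, "recurrence", "freedom")
  records$outcome <- ifelse(records$ilae == 1, "freedom", "recurrence")
  records$label <- ifelse(residual & records$outcome == "recurrence", "TP",
                   ifelse(!residual & records$outcome == "freedom", "TN",
                   ifelse(residual, "FP", "FN")))
  counts <- c(tp = sum(records$label == "TP"),
              tn = sum(records$label == "TN"),
              fp = sum(records$label == "FP"),
              fn = sum(records$label == "FN"))
  list(patients = records, counts = counts)
}

#' Prediction metrics from confusion counts
#'
#' Computes PPV = TP/(TP+FP), NPV = TN/(TN+FN), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP) and accuracy = (TP+TN)/(TP+TN+FP+FN), together
#' with the exact binomial confidence interval of the accuracy. Metrics with
#' a zero denominator are reported as `NA` with a warning.
#'
#' @param tp,tn,fp,fn non-negative confusion counts; their sum must be > 0.
#' @param confidence confidence level for the accuracy CI (default 0.95).
#' @return A list of class `predictionMetrics` with the counts, the five
#'   proportions and `acc_ci` (length-2 vector).
#' @export
confusionMetrics <- function(tp, tn, fp, fn, confidence = 0.95) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("all confusion counts are zero")
  safeDiv <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)")
      return(NA_real_)
    }
    num / den
  }
  m <- list(
    tp = tp, tn = tn, fp = fp, fn = fn,
    ppv = safeDiv(tp, tp + fp, "PPV"),
    npv = safeDiv(tn, tn + fn, "NPV"),
    sens = safeDiv(tp, tp + fn, "sensitivity"),
    spec = safeDiv(tn, tn + fp, "specificity"),
    acc = (tp + tn) / n,
    acc_ci = binomialCI(tp + tn, n, confidence))
  class(m) <- "predictionMetrics"
  m
}

#' @export
print.predictionMetrics <- function(x, ...) {
  cat(sprintf("TP=%d TN=%d FP=%d FN=%d\n", x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("PPV=%.3f NPV=%.3f Sens=%.3f Spec=%.3f ACC=%.3f (95%% CI [%.2f, %.2f])\n",
              x$ppv, x$npv, x$sens, x$spec, x$acc, x$acc_ci[1], x$acc_ci[2]))
  invisible(x)
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Two-sided exact interval for a proportion, obtained by inverting the
#' binomial tail probabilities (beta-quantile form). For 8 successes in 8
#' trials at 95% confidence the lower bound is `0.025^(1/8) = 0.63`.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @param confidence confidence level (default 0.95).
#' @return Length-2 numeric vector `c(low, high)`.
#' @examples
#' round(binomialCI(8, 8), 2)  # 0.63 1.00
#' @export
binomialCI <- function(k, n, confidence = 0.95) {
  if (n < 1) stop("n must be >= 1")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  alpha <- 1 - confidence
  low <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  high <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(low, high)
}

#' Read a patient outcome table
#'
#' Ingests a TSV with columns `patient_id`, `ilae`, `followup_months`,
#' `pre_max_rate`, `post_max_rate`. Rates printed as `"<1"` (censored below
#' the residual threshold) are stored as the 0.5 sentinel with the
#' corresponding `*_censored` flag set; the sentinel only ever meets the
#' threshold comparison, for which any value in `[0, 1)` is equivalent.
#'
#' @param path TSV file.
#' @return data.frame with numeric rate columns and logical
#'   `pre_censored` / `post_censored` flags.
#' @export
readPatientTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  needed <- c("patient_id", "ilae", "pre_max_rate", "post_max_rate")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("patient table misses column(s): ", paste(missing, collapse = ", "))
  parseRate <- function(x) {
    censored <- trimws(x) == "<1"
    val <- suppressWarnings(as.numeric(x))
    val[censored] <- 0.5
    if (anyNA(val)) stop("unparseable rate value(s) in patient table")
    list(value = val, censored = censored)
  }
  pre <- parseRate(df$pre_max_rate)
  post <- parseRate(df$post_max_rate)
  out <- data.frame(patient_id = df$patient_id,
                    ilae = as.integer(df$ilae),
                    pre_max_rate = pre$value, pre_censored = pre$censored,
                    post_max_rate = post$value, post_censored = post$censored)
  if ("followup_months" %in% names(df))
    out$followup_months <- as.integer(df$followup_months)
  out
}
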