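#' Confusion counts against reference labels
#'
#' Standard 2x2 counts with positive = ischemic = 1.
#'
#' @param predicted,reference Equal-length binary (0/1) label vectors.
#' @return An object of class `confusion_counts`: named list with `TP`,
#'   `TN`, `FP`, `FN` and `N`.
#' @examples
#' confusion(c(1, 0, 1, 0), c(1, 1, 0, 0))
#' @export
confusion <- function(predicted, reference) {
  if (length(predicted) != length(reference))
    stop("predicted and reference must have equal length")
  predicted <- as.integer(predicted)
  reference <- as.integer(reference)
  if (!all(predicted %in% 0:1) || !all(reference %in% 0:1))
    stop("labels must be binary (0/1)")
  structure(list(TP = sum(predicted == 1 & reference == 1),
                 TN = sum(predicted == 0 & reference == 0),
                 FP = sum(predicted == 1 & reference == 0),
                 FN = sum(predicted == 0 & reference == 1),
                 N = length(reference)),
            class = "confusion_counts")
}

#' Build confusion counts directly
#'
#' @param TP,TN,FP,FN Non-negative integer counts.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN, N = TP + TN + FP + FN),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts (N = %d): TP %d, TN %d, FP %d, FN %d\n",
              x$N, x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy (ACC), two-point ROC AUC, F1 score (F1S), sensitivity
#' (SEN), specificity (SPE) and precision (PRE). Because the classifier
#' emits hard binary labels, the ROC has a single interior operating point
#' and its trapezoidal area reduces to `(SEN + SPE) / 2`. Metrics with a
#' zero denominator are `NA` ("undefined"), never silently 0.
#'
#' @param counts A `confusion_counts` object.
#' @return A named numeric vector of class `metric_set` with entries
#'   `ACC`, `AUC`, `F1S`, `SEN`, `SPE`, `PRE`.
#' @examples
#' compute_metrics(confusion_counts(TP = 15, TN = 25, FP = 1, FN = 5))
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  sen <- safe(counts$TP, counts$TP + counts$FN)
  spe <- safe(counts$TN, counts$TN + counts$FP)
  pre <- safe(counts$TP, counts$TP + counts$FP)
  acc <- safe(counts$TP + counts$TN, counts$N)
  f1 <- if (!is.na(pre) && !is.na(sen) && (pre + sen) > 0)
    2 * pre * sen / (pre + sen) else NA_real_
  auc <- if (!is.na(sen) && !is.na(spe)) (sen + spe) / 2 else NA_real_
  structure(c(ACC = acc, AUC = auc, F1S = f1, SEN = sen, SPE = spe,
              PRE = pre),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  print(round(unclass(x), 4))
  invisible(x)
}

#' Per-run metrics of a prediction ensemble
#'
#' @param ensemble A [run_protocol()] result.
#' @return Data frame with one row per run: the six metrics plus the
#'   confusion counts.
#' @export
ensemble_metrics <- function(ensemble) {
  stopifnot(inherits(ensemble, "run_ensemble"))
  rows <- lapply(seq_len(nrow(ensemble$predictions)), function(r) {
    cc <- confusion(ensemble$predictions[r, ], ensemble$reference_labels)
    m <- compute_metrics(cc)
    data.frame(run = r, t(unclass(m)), TP = cc$TP, TN = cc$TN,
               FP = cc$FP, FN = cc$FN)
  })
  do.call(rbind, rows)
}

#' Median and interquartile range over runs
#'
#' Aggregates per-run metric values to their median and IQR (type-7
#' quartiles, the linear-interpolation default). Order of runs is
#' irrelevant.
#'
#' @param per_run A data frame of per-run metric values (e.g. from
#'   [ensemble_metrics()]); non-numeric columns and a `run` column are
#'   ignored.
#' @return Data frame with `metric`, `median`, `IQR`.
#' @examples
#' aggregate_runs(data.frame(ACC = c(0.8, 0.85, 0.9)))
#' @export
aggregate_runs <- function(per_run) {
  cols <- setdiff(names(per_run)[vapply(per_run, is.numeric, TRUE)], "run")
  stopifnot(length(cols) > 0, nrow(per_run) >= 1)
  data.frame(metric = cols,
             median = vapply(per_run[cols], function(v)
               median(v, na.rm = TRUE), 0),
             IQR = vapply(per_run[cols], function(v)
               stats::IQR(v, na.rm = TRUE, type = 7), 0),
             row.names = NULL)
}

#' Decision-curve net benefit
#'
#' Net benefit of treating on the classifier's positive calls, over a grid
#' of threshold probabilities:
#' `NB(pt) = TP/N - (FP/N) * pt / (1 - pt)`. Negative values are retained
#' (clip only for plotting).
#'
#' @param counts A `confusion_counts` object.
#' @param grid Threshold probabilities in `[0, 1)`; `pt = 1` is excluded.
#' @return An object of class `decision_curve`: data frame with
#'   `threshold` and `net_benefit`.
#' @examples
#' dc <- decision_curve(confusion_counts(15, 25, 1, 5))
#' dc$net_benefit[dc$threshold == 0]    # TP/N
#' @export
decision_curve <- function(counts, grid = seq(0, 0.99, by = 0.01)) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (any(grid < 0 | grid >= 1))
    stop("threshold probabilities must lie in [0, 1)")
  nb <- counts$TP / counts$N -
    (counts$FP / counts$N) * grid / (1 - grid)
  structure(data.frame(threshold = grid, net_benefit = nb),
            class = c("decision_curve", "data.frame"))
}

#' @export
plot.decision_curve <- function(x, clip = TRUE, ...) {
  y <- if (clip) pmax(x$net_benefit, 0) else x$net_benefit
  graphics::plot(x$threshold, y, type = "l",
                 xlab = "threshold probability",
                 ylab = "net benefit", ...)
  invisible(x)
}

#' Cohen's kappa between two binary raters
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)` with
#' marginal-product expected agreement, from the 2x2 agreement table of
#' two per-subject binary indicators.
#'
#' @param indicator_a,indicator_b Equal-length binary (0/1 or logical)
#'   vectors.
#' @return An object of class `agreement_result`: list with `kappa`,
#'   observed agreement `po`, expected agreement `pe`, the agreement
#'   `table` and a `note` (non-empty when kappa is undefined because both
#'   raters are constant, pe = 1).
#' @examples
#' cohen_kappa(c(1, 1, 0, 0), c(1, 1, 0, 0))$kappa  # 1
#' @export
cohen_kappa <- function(indicator_a, indicator_b) {
  a <- as.integer(indicator_a)
  b <- as.integer(indicator_b)
  if (length(a) != length(b)) stop("indicator vectors must have equal length")
  stopifnot(all(a %in% 0:1), all(b %in% 0:1))
  n <- length(a)
  tab <- table(factor(a, 0:1), factor(b, 0:1))
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) {
    return(structure(list(kappa = NA_real_, po = po, pe = pe, table = tab,
                          note = "expected agreement is 1 (both raters constant); kappa undefined"),
                     class = "agreement_result"))
  }
  structure(list(kappa = (po - pe) / (1 - pe), po = po, pe = pe,
                 table = tab, note = ""),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  if (is.na(x$kappa)) cat("Cohen's kappa: undefined (", x$note, ")\n", sep = "")
  else cat(sprintf("Cohen's kappa: %.4f (po %.4f, pe %.4f)\n",
                   x$kappa, x$po, x$pe))
  invisible(x)
}

#' Category-agreement kappas between two raters' assignments
#'
#' For each confusion category (and for "ischemic" = predicted positive),
#' computes Cohen's kappa between the two raters' per-subject membership
#' indicators. This is how majority-vote CNN assignments are compared with
#' the clinical-threshold assignments.
#'
#' @param assign_a,assign_b Character vectors of per-subject categories
#'   (`"TP"`, `"TN"`, `"FP"`, `"FN"`, optionally `"unassigned"`).
#' @return Data frame with `category`, `kappa`, `po`, `pe`, `note`.
#' @export
category_agreement <- function(assign_a, assign_b) {
  stopifnot(length(assign_a) == length(assign_b))
  cats <- c("ischemic", "TP", "TN", "FP", "FN")
  member <- function(assign, cat) {
    if (cat == "ischemic") as.integer(assign %in% c("TP", "FP"))
    else as.integer(assign == cat)
  }
  rows <- lapply(cats, function(cat) {
    k <- cohen_kappa(member(assign_a, cat), member(assign_b, cat))
    data.frame(category = cat, kappa = k$kappa, po = k$po, pe = k$pe,
               note = k$note)
  })
  do.call(rbind, rows)
}
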