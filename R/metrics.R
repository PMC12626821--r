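# Evaluation protocol: pixel confusion matrix, the seven segmentation
# metrics (mean IoU, accuracy, F1, mean recall, precision, Dice,
# specificity), per-image lesion Dice, one-vs-rest ROC/AUC, and aggregation
# of repeated runs.

#' Pixel confusion matrix
#'
#' @param pred,ref integer `[H, W]` masks (labels `0..K-1`) of equal shape.
#' @param k class count.
#' @return `k x k` integer matrix; rows are the reference class, columns the
#'   predicted class, total equals the pixel count.
#' @export
confusion_matrix <- function(pred, ref, k) {
  if (!identical(dim(pred), dim(ref)))
    abort_validation("prediction and reference masks have different shapes")
  pv <- as.integer(pred); rv <- as.integer(ref)
  if (any(pv < 0L | pv >= k) || any(rv < 0L | rv >= k))
    abort_validation(sprintf("mask labels must lie in 0..%d", k - 1L))
  counts <- tabulate(rv * k + pv + 1L, nbins = k * k)
  matrix(counts, k, k, byrow = TRUE,
         dimnames = list(reference = 0:(k - 1L), predicted = 0:(k - 1L)))
}

#' Segmentation metrics from a confusion matrix
#'
#' Per class: IoU = TP/(TP+FP+FN), precision = TP/(TP+FP), recall =
#' TP/(TP+FN), specificity = TN/(TN+FP), F1 = 2PR/(P+R). Macro means skip
#' classes whose denominator is undefined (in particular, classes absent from
#' both reference and prediction contribute no IoU). Accuracy is
#' trace/total.
#'
#' @param cm `K x K` confusion matrix (rows reference, columns predicted).
#' @return a `seg_metrics` object: list with `macro` (tibble of the seven
#'   summary metrics) and `per_class` (tibble of per-class values).
#' @export
segmentation_metrics <- function(cm) {
  if (sum(cm) == 0) abort_validation("confusion matrix is empty")
  k <- nrow(cm)
  tp <- unname(diag(cm))
  fp <- unname(colSums(cm)) - tp
  fn <- unname(rowSums(cm)) - tp
  tn <- sum(cm) - tp - fp - fn
  safe_div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  iou <- safe_div(tp, tp + fp + fn)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  per_class <- tibble::tibble(
    class = 0:(k - 1L), tp = tp, fp = fp, fn = fn, tn = tn,
    iou = iou, precision = precision, recall = recall,
    specificity = specificity, f1 = f1)
  macro <- tibble::tibble(
    miou = mean(iou, na.rm = TRUE),
    acc = sum(tp) / sum(cm),
    f1 = mean(f1, na.rm = TRUE),
    mean_recall = mean(recall, na.rm = TRUE),
    precision = mean(precision, na.rm = TRUE),
    specificity = mean(specificity, na.rm = TRUE))
  structure(list(macro = macro, per_class = per_class, confusion = cm),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat("Segmentation metrics (macro over classes):\n")
  print(as.data.frame(x$macro), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-image Dice coefficient for one class
#'
#' `2 |P intersect R| / (|P| + |R|)` for the chosen class within a single
#' image; defined as 1 when both masks lack the class entirely.
#'
#' @param pred,ref integer `[H, W]` masks of equal shape.
#' @param cls class label (0-based).
#' @return scalar in `[0, 1]`.
#' @export
dice_per_image <- function(pred, ref, cls) {
  if (!identical(dim(pred), dim(ref)))
    abort_validation("prediction and reference masks have different shapes")
  p <- pred == cls; r <- ref == cls
  denom <- sum(p) + sum(r)
  if (denom == 0) return(1)
  2 * sum(p & r) / denom
}

#' One-vs-rest ROC AUC per class
#'
#' For every class the per-pixel probability channel is swept over all
#' thresholds, (FPR, TPR) pairs are accumulated and the area under the curve
#' is computed by trapezoidal integration. Classes without both a positive
#' and a negative pixel get `NA` (undefined, not 0).
#'
#' @param probs `[H, W, K]` probability array, or an `N x K` matrix of
#'   per-pixel scores.
#' @param ref integer mask / vector of reference labels (0-based).
#' @return named numeric vector of per-class AUCs.
#' @export
roc_auc_ovr <- function(probs, ref) {
  if (is.array(probs) && length(dim(probs)) == 3L) {
    d <- dim(probs)
    probs <- matrix(probs, d[1] * d[2], d[3])
  }
  yv <- as.integer(ref)
  if (length(yv) != nrow(probs))
    abort_validation("scores and labels have different lengths")
  k <- ncol(probs)
  vapply(seq_len(k), function(ci) {
    pos <- yv == (ci - 1L)
    auc_sweep(probs[, ci], pos)
  }, numeric(1)) -> out
  names(out) <- 0:(k - 1L)
  out
}

# threshold-sweep trapezoidal AUC for binary labels
auc_sweep <- function(score, pos) {
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; y <- pos[ord]
  # group ties: cumulative counts at each distinct threshold
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[keep]
  fp <- cumsum(!y)[keep]
  tpr <- c(0, tp / np)
  fpr <- c(0, fp / nn)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Aggregate metric reports over repeated runs
#'
#' @param reports list of `seg_metrics` objects (or tibbles/one-row data
#'   frames of metric values), length >= 2.
#' @return tibble with one row per metric: `metric`, `mean`, `sd` (sample
#'   standard deviation, `n - 1` denominator), `n`.
#' @export
aggregate_runs <- function(reports) {
  if (length(reports) < 2L)
    abort_validation("need at least two runs to aggregate")
  rows <- lapply(reports, function(r) {
    if (inherits(r, "seg_metrics")) r$macro else tibble::as_tibble(r)
  })
  tab <- dplyr::bind_rows(rows)
  tidyr::pivot_longer(tab, dplyr::everything(),
                      names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
}

#' Paired t-test between two sets of per-run scores
#'
#' Two-sided paired t-test with `df = n - 1` and exact t-distribution
#' p-values, as used to compare mean-IoU scores across repeated training
#' runs. Zero-variance differences raise a degenerate-input error rather than
#' returning an infinite statistic.
#'
#' @param a,b numeric vectors of equal length `n >= 2`.
#' @return tibble with `t`, `df`, `p_value`, `mean_difference`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) abort_validation("score vectors differ in length")
  if (length(a) < 2L) abort_validation("need at least two paired scores")
  d <- a - b
  if (stats::sd(d) == 0)
    abort_degenerate("paired differences have zero variance; t is undefined")
  ht <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, mean_difference = unname(ht$estimate))
}

#' Serialize a metrics report
#'
#' `write_metrics_report()` writes the macro metrics as a flat
#' `key<TAB>value` text file and the per-class table as CSV alongside it.
#'
#' @param x a `seg_metrics` object.
#' @param path base file path; `<path>.txt` and `<path>_per_class.csv` are
#'   written.
#' @return paths, invisibly.
#' @export
write_metrics_report <- function(x, path) {
  txt <- paste0(path, ".txt")
  csv <- paste0(path, "_per_class.csv")
  flat <- unlist(x$macro[1, ])
  writeLines(paste(names(flat), format(flat, digits = 10), sep = "\t"), txt)
  utils::write.csv(x$per_class, csv, row.names = FALSE)
  invisible(c(txt, csv))
}

# ---- broom-style methods ---------------------------------------------------

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a segmentation metrics object
#'
#' @param x a `seg_metrics` object.
#' @param ... unused.
#' @return tibble of per-class metrics (one row per class).
#' @export
tidy.seg_metrics <- function(x, ...) x$per_class

#' One-row summary of a segmentation metrics object
#'
#' @inheritParams tidy.seg_metrics
#' @return one-row tibble of the macro metrics.
#' @export
glance.seg_metrics <- function(x, ...) x$macro
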