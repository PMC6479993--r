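# Model evaluation: Kennard-Stone calibration/validation splitting,
# confusion matrices, per-class sensitivity / specificity / efficiency,
# accuracy, and cross-model comparison.

#' Kennard-Stone sample selection
#'
#' Deterministic maximin selection of a representative calibration set on
#' Euclidean distances: the first two picks are the most distant pair;
#' each subsequent pick maximises its minimum distance to the already
#' selected samples. Ties break to the lowest row index.
#'
#' @param X Numeric matrix (samples x variables); callers usually pass the
#'   autoscaled matrix the model will be trained on.
#' @param n_cal Number of calibration samples (`2 <= n_cal <= nrow(X)`).
#' @return Object of class `"ks_split"`: `calibration_indices` and
#'   `validation_indices` (sorted, disjoint, exhaustive) and
#'   `selection_order` (the pick order).
#' @examples
#' ks <- kennard_stone(matrix(c(0, 1, 10)), 2)
#' ks$calibration_indices  # the extreme pair {1, 3}
#' @export
kennard_stone <- function(X, n_cal) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_cal < 2 || n_cal > n) stop("`n_cal` must be between 2 and nrow(X)")
  D <- as.matrix(dist(X))
  # maximally distant pair; ties -> lexicographically smallest (i, j)
  mx <- max(D)
  hits <- which(D >= mx - 1e-12 * (mx + 1), arr.ind = TRUE)
  hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  sel <- as.integer(hits[1, ])
  remaining <- setdiff(seq_len(n), sel)
  if (n_cal > 2) {
    mind <- pmin(D[, sel[1]], D[, sel[2]])
    for (k in seq_len(n_cal - 2)) {
      cand <- remaining[which.max(mind[remaining])]  # ties -> lowest index
      sel <- c(sel, cand)
      remaining <- setdiff(remaining, cand)
      mind <- pmin(mind, D[, cand])
    }
  }
  structure(list(calibration_indices = sort(sel),
                 validation_indices = sort(remaining),
                 selection_order = sel),
            class = "ks_split")
}

#' @export
print.ks_split <- function(x, ...) {
  cat(sprintf("<ks_split> calibration %d / validation %d\n",
              length(x$calibration_indices),
              length(x$validation_indices)))
  invisible(x)
}

#' Confusion matrix
#'
#' @param true,predicted Label vectors of equal length.
#' @param classes Ordered class list; defaults to the sorted union of the
#'   labels. Labels outside `classes` are an error.
#' @return Integer matrix, rows = true class, columns = predicted class.
#' @export
confusion_matrix <- function(true, predicted,
                             classes = sort(unique(c(true, predicted)))) {
  if (length(true) != length(predicted)) {
    stop("`true` and `predicted` must have equal length")
  }
  if (!all(c(true, predicted) %in% classes)) {
    stop("label outside the class list")
  }
  cm <- table(factor(true, levels = classes),
              factor(predicted, levels = classes))
  m <- matrix(as.integer(cm), nrow(cm), ncol(cm),
              dimnames = list(true = as.character(classes),
                              predicted = as.character(classes)))
  m
}

#' Per-class classification metrics
#'
#' One-vs-rest counts and rates per class: sensitivity `TP / (TP + FN)`
#' (recognition of the target class), specificity `TN / (TN + FP)`
#' (rejection of all other classes), and efficiency, their product
#' (`efficiency = "geometric"` gives `sqrt(sens * spec)` instead).
#' Overall accuracy is the trace over the total. Metrics of an empty
#' class are reported as `NA`, not 0.
#'
#' @param cm Square confusion matrix (rows = true).
#' @param efficiency `"product"` (default) or `"geometric"`.
#' @return Object of class `"class_metrics"`: `per_class` (data frame
#'   with TP, FP, TN, FN, sensitivity, specificity, efficiency),
#'   `accuracy` (proportion) and `accuracy_pct` (percentage, 2 decimals).
#' @export
class_metrics <- function(cm, efficiency = c("product", "geometric")) {
  efficiency <- match.arg(efficiency)
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("`cm` must be square")
  n <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  eff <- if (efficiency == "product") sens * spec else sqrt(sens * spec)
  per <- data.frame(class = rownames(cm) %||% seq_len(nrow(cm)),
                    TP = as.integer(tp), FP = as.integer(fp),
                    TN = as.integer(tn), FN = as.integer(fn),
                    sensitivity = sens, specificity = spec,
                    efficiency = eff, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(per_class = per,
                 accuracy = sum(tp) / n,
                 accuracy_pct = accuracy_pct(sum(tp), n),
                 efficiency_definition = efficiency),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("<class_metrics> accuracy %.2f%%\n", x$accuracy_pct))
  print(x$per_class, digits = 4)
  invisible(x)
}

#' Compare model reports
#'
#' Ranks model summary rows by validation accuracy, then `Q2cum`, and
#' derives the study-level conclusion flags from the rows present:
#' whether fused models outperform single-technique ones (mean validation
#' accuracy), whether low-level fusion beats mid-level fusion (mean
#' `Q2cum`), and whether the inner part beats the epidermis (mean
#' validation accuracy, two-part models excluded).
#'
#' @param reports Data frame with at least columns `val_acc` and `Q2cum`;
#'   flags additionally use `level` (`"single"`, `"low"`, `"mid"`) and
#'   `part` (`"inner"`, `"epidermis"`, `"both"`) where available.
#' @return The ranked data frame with attribute `"flags"` (named logical
#'   vector, `NA` where a group is absent).
#' @export
compare_models <- function(reports) {
  if (is.null(reports) || NROW(reports) == 0) {
    stop("empty comparison set")
  }
  reports <- as.data.frame(reports)
  if (!all(c("val_acc", "Q2cum") %in% names(reports))) {
    stop("`reports` needs `val_acc` and `Q2cum` columns")
  }
  ranked <- reports[order(-reports$val_acc, -reports$Q2cum), , drop = FALSE]
  rownames(ranked) <- NULL
  grp_mean <- function(x, sel) {
    if (!any(sel, na.rm = TRUE)) NA_real_ else mean(x[sel], na.rm = TRUE)
  }
  flags <- c(fused_ge_single = NA, low_ge_mid = NA,
             inner_ge_epidermis = NA)
  if ("level" %in% names(reports)) {
    fused <- grp_mean(reports$val_acc, reports$level %in% c("low", "mid"))
    single <- grp_mean(reports$val_acc, reports$level == "single")
    flags["fused_ge_single"] <- fused >= single
    lo <- grp_mean(reports$Q2cum, reports$level == "low")
    mi <- grp_mean(reports$Q2cum, reports$level == "mid")
    flags["low_ge_mid"] <- lo >= mi
  }
  if ("part" %in% names(reports)) {
    inn <- grp_mean(reports$val_acc, reports$part == "inner")
    epi <- grp_mean(reports$val_acc, reports$part == "epidermis")
    flags["inner_ge_epidermis"] <- inn >= epi
  }
  attr(ranked, "flags") <- flags
  ranked
}
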