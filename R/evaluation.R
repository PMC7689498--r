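#' ROC curve and trapezoidal AUC for detection values
#'
#' Sweeps a decision threshold over the unique detection values (convention:
#' predict positive when `value >= cutoff`) and integrates the curve by the
#' trapezoidal rule. The resulting AUC equals the Mann-Whitney rank
#' statistic `P(v_pos > v_neg) + 0.5 P(v_pos = v_neg)`.
#'
#' @param values Numeric detection values (one per case).
#' @param labels Logical (`TRUE` = positive) or a vector with levels
#'   `"pos"`/`"neg"` or `"ich"`/`"normal"`.
#' @return An object of class `roc_result`: `points` tibble
#'   (`threshold`, `fpr`, `tpr`, starting at (0,0), ending at (1,1)),
#'   `auc`, and the inputs for operating-point analysis.
#' @examples
#' r <- roc_curve(c(0.9, 0.8, 0.4, 0.7, 0.3), c(TRUE, TRUE, TRUE, FALSE, FALSE))
#' r$auc  # 5/6
#' @export
roc_curve <- function(values, labels) {
  pos <- as_positive(labels)
  stopifnot(length(values) == length(pos))
  if (!any(pos) || all(pos)) {
    abort("ROC analysis needs both classes present.", class = "ich_degenerate_input")
  }
  thr <- c(Inf, sort(unique(values), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(values[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(values[!pos] >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    list(points = tibble(threshold = thr, fpr = fpr, tpr = tpr),
         auc = auc, values = values, positive = pos,
         n_pos = sum(pos), n_neg = sum(!pos)),
    class = "roc_result"
  )
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  l <- tolower(as.character(labels))
  if (all(l %in% c("pos", "neg"))) return(l == "pos")
  if (all(l %in% c("ich", "normal"))) return(l == "ich")
  abort("Labels must be logical, pos/neg or ich/normal.", class = "ich_label_error")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%d pos, %d neg, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' Sensitivity/specificity at an operating point
#'
#' Either the Youden-optimal point (maximising `tpr - fpr`, ties resolved
#' toward higher sensitivity) or the fixed 0.5 cutoff on the detection value
#' — the cutoff at which the score during training equals detection
#' accuracy.
#'
#' @param roc A [roc_curve()] result.
#' @param method `"youden"` or `"fixed"`.
#' @param cutoff Cutoff for `method = "fixed"` (default 0.5); positive
#'   predicted when `value >= cutoff`.
#' @return Named numeric: `sensitivity` and `specificity` in percent, plus
#'   the `cutoff` used.
#' @export
operating_point <- function(roc, method = c("youden", "fixed"), cutoff = 0.5) {
  stopifnot(inherits(roc, "roc_result"))
  method <- match.arg(method)
  if (method == "fixed") {
    sens <- mean(roc$values[roc$positive] >= cutoff) * 100
    spec <- mean(roc$values[!roc$positive] < cutoff) * 100
    return(c(sensitivity = sens, specificity = spec, cutoff = cutoff))
  }
  j <- roc$points$tpr - roc$points$fpr
  best <- which(j == max(j))
  best <- best[which.max(roc$points$tpr[best])]
  c(sensitivity = roc$points$tpr[best] * 100,
    specificity = (1 - roc$points$fpr[best]) * 100,
    cutoff = roc$points$threshold[best])
}

#' Subtype decision from the 3-node output
#'
#' Argmax over the three output nodes, ties broken toward the lowest index:
#' node 1 = EDH/SDH, node 2 = SAH, node 3 = IPH/IVH.
#'
#' @param outputs Length-3 numeric vector, or an n x 3 matrix.
#' @return Integer subtype(s) in 1-3.
#' @export
classify_subtype <- function(outputs) {
  if (is.null(dim(outputs))) {
    stopifnot(length(outputs) == 3)
    outputs <- matrix(outputs, nrow = 1)
  }
  stopifnot(ncol(outputs) == 3)
  drop(max.col(outputs, ties.method = "first"))
}

#' 3-class confusion matrix
#'
#' Rows are true subtypes, columns predicted subtypes.
#'
#' @param true,predicted Integer vectors in 1-3.
#' @return 3 x 3 integer matrix of class `confusion_matrix3`.
#' @export
confusion_matrix3 <- function(true, predicted) {
  stopifnot(length(true) == length(predicted),
            all(true %in% 1:3), all(predicted %in% 1:3))
  m <- table(factor(true, 1:3), factor(predicted, 1:3))
  structure(matrix(as.integer(m), 3, 3,
                   dimnames = list(true = paste0("type", 1:3),
                                   predicted = paste0("type", 1:3))),
            class = c("confusion_matrix3", "matrix"))
}

#' Per-type and overall accuracy from a 3-class confusion matrix
#'
#' Per-type accuracy is the diagonal count over the row (true-type) total;
#' overall accuracy is the trace over the grand total. Percentages are
#' returned unrounded; round to one decimal at report time.
#'
#' @param cm A 3 x 3 confusion matrix (rows = true, cols = predicted).
#' @return A tibble with one row per type (`type`, `n_cases`, `n_correct`,
#'   `accuracy`) and an attached `overall` attribute; also accessible via
#'   the `overall` column of the `"total"` row.
#' @export
classification_metrics <- function(cm) {
  cm <- unclass(cm)
  stopifnot(is.matrix(cm), all(dim(cm) == 3), all(cm >= 0))
  rs <- rowSums(cm)
  per_type <- tibble(
    type = 1:3,
    n_cases = as.integer(unname(rs)),
    n_correct = as.integer(unname(diag(cm))),
    accuracy = unname(ifelse(rs > 0, diag(cm) / rs * 100, NA_real_))
  )
  attr(per_type, "overall") <- sum(diag(cm)) / sum(cm) * 100
  per_type
}

#' @rdname classification_metrics
#' @param metrics Result of `classification_metrics()`.
#' @export
overall_accuracy <- function(metrics) attr(metrics, "overall")

#' Per-subdivision detection report
#'
#' Assembles one row per height subdivision (counts, architecture, AUC,
#' sensitivity, specificity) and computes the prevalence-weighted accuracy
#' for each row via [weighted_accuracy()], then appends an `Average` row of
#' unweighted column means over the subdivisions. Percentages are reported
#' to one decimal.
#'
#' @param results A data frame with columns `subdivision`, `resolution`,
#'   `n_pos`, `n_neg`, `hidden`, `auc`, `sensitivity`, `specificity`.
#' @return A tibble with an added `accuracy` column and a final Average row.
#' @export
subdivision_report <- function(results) {
  stopifnot(nrow(results) >= 1)
  rows <- results |>
    dplyr::mutate(
      accuracy = round_half_up(
        weighted_accuracy(.data$sensitivity, .data$specificity,
                          .data$n_pos, .data$n_neg), 1),
      sensitivity = round_half_up(.data$sensitivity, 1),
      specificity = round_half_up(.data$specificity, 1)
    )
  avg <- tibble(
    subdivision = "Average", resolution = NA_integer_,
    n_pos = NA_integer_, n_neg = NA_integer_, hidden = NA_character_,
    auc = round_half_up(mean(rows$auc), 3),
    sensitivity = round_half_up(mean(rows$sensitivity), 1),
    specificity = round_half_up(mean(rows$specificity), 1),
    accuracy = round_half_up(mean(rows$accuracy), 1)
  )
  dplyr::bind_rows(
    dplyr::mutate(rows,
                  subdivision = as.character(.data$subdivision),
                  resolution = as.integer(.data$resolution),
                  n_pos = as.integer(.data$n_pos),
                  n_neg = as.integer(.data$n_neg),
                  hidden = as.character(.data$hidden)),
    avg
  )
}
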