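#' ROC curve and AUC for one metric as a homogeneity predictor
#'
#' Communities are predicted homogeneous when the metric value is above a
#' threshold; sweeping the threshold over all distinct values traces the
#' ROC curve.  Ties get Mann-Whitney half credit (diagonal ROC segments),
#' so the trapezoidal area equals the tie-corrected Mann-Whitney
#' probability that a random positive outranks a random negative.  An AUC
#' of 0.5 is chance; below 0.5 means the metric predicts when *below* a
#' threshold (negative association) and is reported as-is, never flipped.
#'
#' @param values Numeric metric values, one per community; `NA` dropped
#'   (together with their labels).
#' @param labels Logical homogeneity labels, same length.
#' @return Object of class `"roc_result"`: `points` (data.frame `fpr`,
#'   `tpr`, from (0,0) to (1,1)), `auc`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_curve(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE))$auc  # 0.75
roc_curve <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- as.logical(labels[keep])
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: need at least one positive and one negative label")
  }
  ord <- order(values, decreasing = TRUE)
  v <- values[ord]
  l <- labels[ord]
  # group ties so tied blocks contribute diagonal segments
  grp <- cumsum(!duplicated(v))
  tp <- cumsum(l)
  fp <- cumsum(!l)
  last <- which(!duplicated(grp, fromLast = TRUE))
  pts <- data.frame(fpr = c(0, fp[last] / n_neg),
                    tpr = c(0, tp[last] / n_pos))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  structure(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "false positive rate", ylab = "true positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Per-resolution AUCs of topological metrics
#'
#' Joins a community metric table with homogeneity calls and computes, for
#' each metric and each resolution, the ROC AUC for predicting
#' homogeneity.  Only communities at or above the reporting size with a
#' defined homogeneity call and a finite metric value enter; resolutions
#' where only one class remains get `NA` (skipped later, with coverage
#' reported, by [mean_auc()]).
#'
#' @param metrics_df Long metric table from [sweep_metrics()].
#' @param calls A `"community_calls"` data.frame.
#' @param measure Which measure's homogeneity labels to use (default
#'   `"G"`).
#' @param min_size Community size filter (default 4, the reporting
#'   filter).
#' @return Data.frame: `metric`, `log_lambda`, `auc`, `n_pos`, `n_neg`.
#' @export
metric_aucs <- function(metrics_df, calls, measure = "G", min_size = 4) {
  lab <- calls[calls$measure == measure & calls$size >= min_size &
                 !is.na(calls$homogeneous), , drop = FALSE]
  out <- list()
  for (met in unique(metrics_df$metric)) {
    mdf <- metrics_df[metrics_df$metric == met, , drop = FALSE]
    for (ll in sort(unique(mdf$log_lambda))) {
      mrow <- mdf[mdf$log_lambda == ll, , drop = FALSE]
      lrow <- lab[lab$log_lambda == ll, , drop = FALSE]
      j <- match(mrow$community, lrow$community)
      values <- mrow$value[!is.na(j)]
      labels <- lrow$homogeneous[j[!is.na(j)]]
      rec <- data.frame(metric = met, log_lambda = ll, auc = NA_real_,
                        n_pos = sum(labels %in% TRUE),
                        n_neg = sum(labels %in% FALSE))
      ok <- !is.na(values)
      if (sum(labels[ok] %in% TRUE) > 0 && sum(labels[ok] %in% FALSE) > 0) {
        rec$auc <- roc_curve(values[ok], labels[ok])$auc
      }
      out[[length(out) + 1L]] <- rec
    }
  }
  do.call(rbind, out)
}

#' Mean AUC over a resolution range
#'
#' Unweighted mean of the per-resolution AUCs with
#' `log_lambda` inside `range` (default \[0, 3\]; the noisy low-resolution
#' end, where few communities exist, is excluded by default).  Resolutions
#' with undefined AUC are skipped and counted in the `coverage` attribute
#' (defined / total in range).
#'
#' @param aucs Data.frame from [metric_aucs()] (one metric, or use
#'   [metric_ranking()] for all).
#' @param range Length-2 numeric, inclusive bounds on `log_lambda`.
#' @return Mean AUC (scalar) with attribute `coverage`.
#' @export
mean_auc <- function(aucs, range = c(0, 3)) {
  inr <- aucs$log_lambda >= range[[1]] & aucs$log_lambda <= range[[2]]
  a <- aucs$auc[inr]
  if (!length(a) || all(is.na(a))) {
    stop("no defined AUC in the requested resolution range")
  }
  structure(mean(a, na.rm = TRUE),
            coverage = sum(!is.na(a)) / length(a))
}

#' Rank metrics by mean AUC
#'
#' @param aucs Data.frame from [metric_aucs()] covering several metrics.
#' @param range Resolution range passed to [mean_auc()].
#' @return Data.frame sorted by decreasing `mean_auc`: `metric`,
#'   `mean_auc`, `coverage`.
#' @export
metric_ranking <- function(aucs, range = c(0, 3)) {
  mets <- unique(aucs$metric)
  rows <- lapply(mets, function(m) {
    ma <- tryCatch(mean_auc(aucs[aucs$metric == m, , drop = FALSE], range),
                   error = function(e) structure(NA_real_, coverage = 0))
    data.frame(metric = m, mean_auc = as.numeric(ma),
               coverage = attr(ma, "coverage"))
  })
  out <- do.call(rbind, rows)
  out[order(-out$mean_auc), , drop = FALSE]
}
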