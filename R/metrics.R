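#' Segmentation losses
#'
#' The three training objectives used by the candidate networks, computed
#' on probability/target arrays whose last dimension indexes channels
#' (any leading spatial/batch shape).
#'
#' * `multiclass_cross_entropy()` — per-pixel \eqn{-\sum_c y_c \log p_c}
#'   with one-hot targets, averaged over pixels; pairs with a softmax head.
#' * `binary_cross_entropy()` — per-pixel
#'   \eqn{-[y \log p + (1-y)\log(1-p)]} averaged over pixels; pairs with a
#'   sigmoid head (single channel).
#' * `multilabel_loss()` — the mean of the three per-region binary
#'   cross-entropies (ET, TC, WT channels).
#'
#' Probabilities are clipped to `[eps, 1 - eps]` before the logarithm.
#'
#' @param p numeric array of predicted probabilities in `[0, 1]`.
#' @param y numeric array of targets in `{0, 1}`, same shape as `p`.
#' @param eps clipping constant for the logarithms.
#' @return Scalar loss (non-negative).
#' @export
multiclass_cross_entropy <- function(p, y, eps = 1e-7) {
  stopifnot(identical(dim(p) %||% length(p), dim(y) %||% length(y)))
  d <- dim(p)
  nc <- d[length(d)]
  pm <- matrix(p, ncol = nc)
  ym <- matrix(y, ncol = nc)
  if (!all(ym %in% c(0, 1)) || any(abs(rowSums(ym) - 1) > 1e-9))
    stop_rfs("targets must be one-hot (binary channels summing to 1 per pixel)")
  pm <- pmin(pmax(pm, eps), 1 - eps)
  mean(-rowSums(ym * log(pm)))
}

#' @rdname multiclass_cross_entropy
#' @export
binary_cross_entropy <- function(p, y, eps = 1e-7) {
  stopifnot(length(p) == length(y))
  p <- pmin(pmax(p, eps), 1 - eps)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

#' @rdname multiclass_cross_entropy
#' @export
multilabel_loss <- function(p, y, eps = 1e-7) {
  d <- dim(p)
  nc <- d[length(d)]
  if (nc != 3L) stop_rfs("multilabel_loss expects 3 region channels, got %d", nc)
  stopifnot(identical(dim(p), dim(y)))
  pm <- matrix(p, ncol = 3L)
  ym <- matrix(y, ncol = 3L)
  mean(vapply(1:3, function(k) binary_cross_entropy(pm[, k], ym[, k], eps),
              numeric(1)))
}

as_mask <- function(x) {
  if (is.logical(x)) x else x != 0
}

#' Dice similarity coefficient
#'
#' \eqn{2|T \cap P| / (|T| + |P|)} over positive voxels. When both masks
#' are empty the score is defined as 1 (a correct "no tumor" prediction).
#'
#' @param y_true,y_pred binary arrays on a common grid.
#' @return Fraction in `[0, 1]`.
#' @export
dsc <- function(y_true, y_pred) {
  t <- as_mask(y_true); p <- as_mask(y_pred)
  stopifnot(identical(dim(t), dim(p)))
  nt <- sum(t); np <- sum(p)
  if (nt + np == 0L) return(1)
  2 * sum(t & p) / (nt + np)
}

#' Sensitivity (true-positive rate) of a predicted mask
#'
#' \eqn{|T \cap P| / |T|}; `NA` when the ground truth has no positive
#' voxels (undefined rather than 0 or 1).
#' @inheritParams dsc
#' @return Fraction in `[0, 1]`, or `NA`.
#' @export
sensitivity <- function(y_true, y_pred) {
  t <- as_mask(y_true); p <- as_mask(y_pred)
  stopifnot(identical(dim(t), dim(p)))
  nt <- sum(t)
  if (nt == 0L) return(NA_real_)
  sum(t & p) / nt
}

#' Specificity (true-negative rate) of a predicted mask
#'
#' \eqn{|T^c \cap P^c| / |T^c|}; `NA` when the ground truth covers the
#' whole grid.
#' @inheritParams dsc
#' @return Fraction in `[0, 1]`, or `NA`.
#' @export
specificity <- function(y_true, y_pred) {
  t <- as_mask(y_true); p <- as_mask(y_pred)
  stopifnot(identical(dim(t), dim(p)))
  nn <- sum(!t)
  if (nn == 0L) return(NA_real_)
  sum(!t & !p) / nn
}

#' 95th-percentile Hausdorff distance between two masks
#'
#' Distances are Euclidean between voxel centers scaled by the physical
#' spacing (mm). For every positive voxel of each mask the distance to the
#' nearest positive voxel of the other mask is computed (via an exact
#' distance transform); each direction is summarized by its
#' linearly-interpolated 95th percentile and the two directions are
#' combined by the maximum. A pooled variant (percentile of the two
#' directed distance sets pooled together) is available. `NA` when either
#' mask is empty.
#'
#' @inheritParams dsc
#' @param spacing voxel spacing in mm per axis.
#' @param percentile percentile of the directed distance distributions
#'   (95 for HD95; 100 gives the classical Hausdorff distance).
#' @param method `"max_directed"` (default) or `"pooled"`.
#' @return Distance in mm, or `NA` if either mask is empty.
#' @export
hd95 <- function(y_true, y_pred, spacing = c(1, 1, 1), percentile = 95,
                 method = c("max_directed", "pooled")) {
  method <- match.arg(method)
  t <- as_mask(y_true); p <- as_mask(y_pred)
  stopifnot(identical(dim(t), dim(p)))
  if (sum(t) == 0L || sum(p) == 0L) return(NA_real_)
  d <- dim(t) %||% length(t)
  spacing <- as.numeric(spacing)[seq_along(d)]
  dt_p <- sqrt(.edt_sq(as.logical(p), as.integer(d), spacing))
  dt_t <- sqrt(.edt_sq(as.logical(t), as.integer(d), spacing))
  d_t_to_p <- dt_p[t]   # d(a -> P) for a in T
  d_p_to_t <- dt_t[p]
  q <- percentile / 100
  if (method == "max_directed") {
    max(quantile(d_t_to_p, q, names = FALSE, type = 7),
        quantile(d_p_to_t, q, names = FALSE, type = 7))
  } else {
    quantile(c(d_t_to_p, d_p_to_t), q, names = FALSE, type = 7)
  }
}

#' Evaluate one predicted mask against ground truth
#'
#' @inheritParams hd95
#' @return A `metric_report` list: `dsc`, `hd95` (mm), `sensitivity`,
#'   `specificity`.
#' @export
evaluate_masks <- function(y_true, y_pred, spacing = c(1, 1, 1)) {
  structure(list(dsc = dsc(y_true, y_pred),
                 hd95 = hd95(y_true, y_pred, spacing),
                 sensitivity = sensitivity(y_true, y_pred),
                 specificity = specificity(y_true, y_pred)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("DSC %.4f | HD95 %s mm | sensitivity %s | specificity %s\n",
              x$dsc,
              if (is.na(x$hd95)) "NA" else sprintf("%.3f", x$hd95),
              if (is.na(x$sensitivity)) "NA" else sprintf("%.4f", x$sensitivity),
              if (is.na(x$specificity)) "NA" else sprintf("%.4f", x$specificity)))
  invisible(x)
}

#' Per-patient, per-region metric table
#'
#' @param truths,preds lists of `region_masks` (one per patient).
#' @param ids patient identifiers.
#' @param spacing voxel spacing in mm.
#' @param file optional CSV path to write the table to.
#' @return Data frame with one row per patient x region.
#' @export
metric_table <- function(truths, preds, ids = seq_along(truths),
                         spacing = c(1, 1, 1), file = NULL) {
  rows <- list()
  for (i in seq_along(truths)) {
    for (r in region_names()) {
      m <- evaluate_masks(truths[[i]][[r]], preds[[i]][[r]], spacing)
      rows[[length(rows) + 1L]] <-
        data.frame(patient_id = ids[i], region = r, dsc = m$dsc,
                   hd95 = m$hd95, sensitivity = m$sensitivity,
                   specificity = m$specificity, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}
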