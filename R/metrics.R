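# Evaluation suite: MSE/RMSE/MAE, Pearson R, variance explained by
# cross-validation (VEcv) with its performance bands, Lin's concordance
# correlation coefficient, and detection/effective rates. Multichannel
# series are pooled (flattened) for the global numbers.

flatten_pair <- function(target, predicted) {
  t <- as.vector(as.matrix(target))
  p <- as.vector(as.matrix(predicted))
  if (length(t) != length(p)) stop("target and predicted lengths differ")
  keep <- !is.na(t) & !is.na(p)
  list(t = t[keep], p = p[keep])
}

#' Mean squared, root mean squared and mean absolute error
#'
#' @param target,predicted numeric vectors or matrices of equal shape
#'   (matrices are pooled over all channels).
#' @return List with `mse`, `rmse` (= sqrt(mse)) and `mae`.
#' @export
basic_errors <- function(target, predicted) {
  v <- flatten_pair(target, predicted)
  if (length(v$t) < 1L) stop("need at least one paired observation")
  e <- v$t - v$p
  mse <- mean(e^2)
  list(mse = mse, rmse = sqrt(mse), mae = mean(abs(e)))
}

#' Pearson product-moment correlation
#'
#' @inheritParams basic_errors
#' @return Correlation in [-1, 1].
#' @export
pearson_r <- function(target, predicted) {
  v <- flatten_pair(target, predicted)
  if (stats::var(v$t) == 0 || stats::var(v$p) == 0) {
    stop("correlation undefined: a series has zero variance")
  }
  stats::cor(v$t, v$p)
}

#' Variance explained by cross-validation (VEcv), in percent
#'
#' `VEcv = (1 - sum((t - p)^2) / sum((t - mean(t))^2)) * 100`. At most 100
#' (perfect prediction); 0 for predicting the target mean; negative when
#' worse than the mean.
#'
#' @inheritParams basic_errors
#' @return Percent, <= 100.
#' @export
vecv <- function(target, predicted) {
  v <- flatten_pair(target, predicted)
  ss_tot <- sum((v$t - mean(v$t))^2)
  if (ss_tot == 0) stop("VEcv undefined: target has zero variance")
  (1 - sum((v$t - v$p)^2) / ss_tot) * 100
}

#' Map a VEcv value to its performance category
#'
#' Five bands: very poor (VEcv <= 10), poor (10 < VEcv <= 30), average
#' (30 < VEcv <= 50), good (50 < VEcv <= 80), excellent (VEcv > 80). Upper
#' boundaries are inclusive.
#'
#' @param v finite VEcv percentage (vectorized).
#' @return Character vector of category labels.
#' @export
vecv_category <- function(v) {
  if (any(!is.finite(v))) stop("VEcv values must be finite")
  labels <- c("very poor", "poor", "average", "good", "excellent")
  labels[findInterval(v, c(-Inf, 10, 30, 50, 80), left.open = TRUE)]
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 cov(t, p) / (var(t) + var(p) + (mean(t) - mean(p))^2)` with
#' population (1/n) moments, penalizing both decorrelation and mean or scale
#' shifts; |CCC| <= |Pearson R| always.
#'
#' @inheritParams basic_errors
#' @return Concordance in [-1, 1].
#' @export
lin_ccc <- function(target, predicted) {
  v <- flatten_pair(target, predicted)
  n <- length(v$t)
  if (n < 2L) stop("need at least two paired observations")
  mt <- mean(v$t)
  mp <- mean(v$p)
  vt <- mean((v$t - mt)^2)
  vp <- mean((v$p - mp)^2)
  if (vt == 0 && vp == 0) stop("CCC undefined: both series are constant")
  cv <- mean((v$t - mt) * (v$p - mp))
  2 * cv / (vt + vp + (mt - mp)^2)
}

#' Full accuracy report for one scope
#'
#' @inheritParams basic_errors
#' @return One-row data frame: n, mse, rmse, mae, pearson_r, vecv, ccc.
#' @export
eval_metrics <- function(target, predicted) {
  v <- flatten_pair(target, predicted)
  err <- basic_errors(v$t, v$p)
  r <- tryCatch(pearson_r(v$t, v$p), error = function(e) NA_real_)
  ve <- tryCatch(vecv(v$t, v$p), error = function(e) NA_real_)
  cc <- tryCatch(lin_ccc(v$t, v$p), error = function(e) NA_real_)
  data.frame(n = length(v$t), mse = err$mse, rmse = err$rmse, mae = err$mae,
             pearson_r = r, vecv = ve, ccc = cc)
}

#' Accuracy report by scope
#'
#' Computes the metric suite pooled over everything (`scope = "all"`) and per
#' level of a grouping vector (e.g. dataset, subtype or point), mirroring the
#' per-dataset / per-subtype report layout.
#'
#' @inheritParams basic_errors
#' @param groups grouping vector with one entry per row of `target` (or per
#'   element when vectors).
#' @return Data frame with a `scope` column followed by the metrics.
#' @export
eval_report <- function(target, predicted, groups = NULL) {
  target <- as.matrix(target)
  predicted <- as.matrix(predicted)
  all_row <- cbind(scope = "all", eval_metrics(target, predicted))
  if (is.null(groups)) return(all_row)
  if (length(groups) != nrow(target)) {
    stop("groups must have one entry per row")
  }
  per <- do.call(rbind, lapply(sort(unique(groups)), function(g) {
    idx <- groups == g
    cbind(scope = as.character(g),
          eval_metrics(target[idx, , drop = FALSE],
                       predicted[idx, , drop = FALSE]))
  }))
  rbind(all_row, per)
}

#' Effective detection rate excluding unforecastable complexes
#'
#' Detected complexes divided by the total after removing the ABEXYOZu
#' complexes, which carry no characteristic points to detect.
#'
#' @param n_detected number of fully detected complexes.
#' @param n_total total complexes.
#' @param n_unforecastable number of ABEXYOZu complexes.
#' @return Percentage.
#' @export
effective_rate <- function(n_detected, n_total, n_unforecastable) {
  denom <- n_total - n_unforecastable
  if (denom <= 0) stop("no forecastable complexes")
  100 * n_detected / denom
}

#' Detection rates before and after imputation
#'
#' Combines per-point missingness tables (as from [missingness_summary()],
#' `$per_point`) taken before and after imputation into detected percentages
#' (100 - missing), and computes the per-dataset effective detection rate
#' from complex counts. Warns if imputation made any point's rate worse.
#'
#' @param before,after data frames with columns `dataset_id`, `point`,
#'   `pct_missing`.
#' @param subtype_counts data frame with columns `dataset_id`, `subtype`,
#'   `n`, `n_detected` (complexes fully detected after imputation).
#' @return List with `per_point` (before/after detected percentages) and
#'   `effective` (per-dataset effective rates).
#' @export
detection_rates <- function(before, after, subtype_counts) {
  key_b <- paste(before$dataset_id, before$point)
  key_a <- paste(after$dataset_id, after$point)
  if (!setequal(key_b, key_a)) stop("before/after tables cover different points")
  m <- match(key_b, key_a)
  per_point <- data.frame(dataset_id = before$dataset_id,
                          point = before$point,
                          detected_before = 100 - before$pct_missing,
                          detected_after = 100 - after$pct_missing[m],
                          stringsAsFactors = FALSE)
  if (any(per_point$detected_after < per_point$detected_before - 1e-9)) {
    warning("detection rate decreased for some point; imputation should only add points")
  }
  eff <- do.call(rbind, lapply(unique(subtype_counts$dataset_id), function(d) {
    sc <- subtype_counts[subtype_counts$dataset_id == d, , drop = FALSE]
    n_total <- sum(sc$n)
    n_u <- sum(sc$n[sc$subtype == SUBTYPE_UNFORECASTABLE])
    n_det <- sum(sc$n_detected[sc$subtype != SUBTYPE_UNFORECASTABLE])
    data.frame(dataset_id = d,
               effective_rate = effective_rate(n_det, n_total, n_u),
               plain_rate = 100 * n_det / n_total,
               stringsAsFactors = FALSE)
  }))
  list(per_point = per_point, effective = eff)
}
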