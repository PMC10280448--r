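# Applying the trained network: subtype-aware imputation of missing
# characteristic points along each (subject, subtype) stream, and selection
# of the most suitable X candidate per dataset and subtype.

#' Impute missing characteristic points with the trained network
#'
#' Runs the observation-aware closed loop ([narx_forecast_hybrid()]) along
#' every (dataset, subject, subtype) stream of a normalized interval matrix:
#' at each beat beyond the delay horizon the network predicts all eight
#' channels from the previous beats (observed values where available, its own
#' predictions where not), and each cell flagged missing is replaced by the
#' forecast for that channel. Observed cells are never overwritten.
#' ABEXYOZu streams carry no points and are flagged unforecastable, as are
#' the beats inside the initial delay horizon of each stream.
#'
#' Delay removal does not change the imputed values on a recorded stream --
#' it only shifts the emission index -- so the result is identical for a
#' delay-removed model.
#'
#' @param model fitted `narx_model`; `model$norm$ss_scale` must match the
#'   matrix's scales and `model$norm$col_means` seeds the delay line.
#' @param m `interval_matrix` in state `"ss_normalized"`.
#' @param mask logical matrix over the point columns (beats x 8) marking the
#'   cells to treat as missing; defaults to `is.na` of the point columns.
#' @return Object of class `imputation_result`: list with `completed`
#'   (the interval matrix with forecastable missing cells filled),
#'   `provenance` (character matrix: `"observed"`, `"imputed"`, `"missing"`),
#'   `unforecastable` (logical per row), and `held_out` (per-subtype metric
#'   report of one-step predictions against observed cells).
#' @export
impute_missing_points <- function(model, m, mask = NULL) {
  stopifnot_state(m, "ss_normalized", "impute_missing_points")
  point_cols <- setdiff(ICG_COLUMNS, "RR")
  if (!is.null(model$norm$ss_scale)) {
    if (!isTRUE(all.equal(unname(model$norm$ss_scale[point_cols]),
                          unname(m$ss_scale[point_cols]),
                          tolerance = 1e-8))) {
      stop("normalization scale mismatch between model and matrix")
    }
  }
  vals <- m$values[, point_cols, drop = FALSE]
  if (is.null(mask)) mask <- is.na(vals)
  if (!is.logical(mask) || !identical(dim(mask), dim(vals))) {
    stop("mask must be a logical matrix over the point columns")
  }
  d <- max(model$config$input_delays, model$config$feedback_delays)
  seed_means <- model$norm$col_means %||% colMeans(vals[!mask], na.rm = TRUE)
  completed <- vals
  provenance <- matrix("observed", nrow(vals), ncol(vals),
                       dimnames = dimnames(vals))
  provenance[mask] <- "missing"
  unforecastable <- rep(FALSE, nrow(vals))
  preds <- matrix(NA_real_, nrow(vals), ncol(vals))
  streams <- to_sequences(m)
  for (s in streams) {
    rows <- s$rows
    if (s$subtype == SUBTYPE_UNFORECASTABLE) {
      unforecastable[rows] <- TRUE
      next
    }
    if (length(rows) < d + 1L) {
      unforecastable[rows] <- TRUE
      next
    }
    y_obs <- vals[rows, , drop = FALSE]
    y_obs[mask[rows, , drop = FALSE]] <- NA_real_
    hb <- narx_forecast_hybrid(model, y_obs,
                               seed_values = seed_means[point_cols])
    preds[rows, ] <- hb$pred
    unforecastable[rows[seq_len(d)]] <- TRUE
    fill <- mask[rows, , drop = FALSE] & !is.na(hb$pred)
    completed[rows, ][fill] <- hb$pred[fill]
    provenance[rows, ][fill] <- "imputed"
  }
  out <- m
  out$values[, point_cols] <- completed
  obs_ok <- !mask & !is.na(preds)
  held_out <- if (any(obs_ok)) {
    subtype_of_cell <- matrix(rep(m$row_meta$subtype, ncol(vals)),
                              nrow(vals), ncol(vals))
    eval_report(vals[obs_ok], preds[obs_ok],
                groups = subtype_of_cell[obs_ok])
  } else {
    NULL
  }
  structure(list(completed = out, provenance = provenance,
                 unforecastable = unforecastable, held_out = held_out),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  n_imp <- sum(x$provenance == "imputed")
  n_missing <- sum(x$provenance == "missing")
  cat("<imputation_result> ", n_imp, " cells imputed, ", n_missing,
      " left missing (unforecastable rows: ", sum(x$unforecastable), ")\n",
      sep = "")
  invisible(x)
}

#' Select the most suitable X candidate per dataset and subtype
#'
#' For every (dataset, subtype) scope with both candidates populated,
#' computes the root-mean-square deviation of each candidate's RR ratio from
#' the mean reference ratio of that candidate in the typical (ABEXYOZ0) beats
#' of the same dataset, and chooses the candidate with the smaller deviation.
#' Ties go to X2, the true X of typical complexes. The selection is
#' per-scope because different acquisition systems can favor opposite
#' candidates.
#'
#' @param m completed `interval_matrix` (any normalization state; ratios are
#'   recovered internally) with both `RX1` and `RX2` populated in scope.
#' @param reference subtype whose beats define the reference ratios.
#' @return Data frame of class `x_selection`: one row per (dataset, subtype)
#'   with `sd_x1`, `sd_x2`, `n` and `chosen`.
#' @export
select_x <- function(m, reference = "ABEXYOZ0") {
  if (!inherits(m, "interval_matrix")) stop("not an interval_matrix")
  ratios <- as_rr_ratio(m)
  meta <- m$row_meta
  out <- list()
  for (d in unique(meta$dataset_id)) {
    ref_rows <- meta$dataset_id == d & meta$subtype == reference
    if (!any(ref_rows)) {
      stop("no reference (", reference, ") beats in dataset '", d, "'")
    }
    ref_x1 <- mean(ratios[ref_rows, "RX1"], na.rm = TRUE)
    ref_x2 <- mean(ratios[ref_rows, "RX2"], na.rm = TRUE)
    subtypes <- setdiff(unique(meta$subtype[meta$dataset_id == d]),
                        c(reference, SUBTYPE_UNFORECASTABLE))
    for (st in subtypes) {
      rows <- meta$dataset_id == d & meta$subtype == st
      x1 <- ratios[rows, "RX1"]
      x2 <- ratios[rows, "RX2"]
      ok <- !is.na(x1) & !is.na(x2)
      if (sum(ok) < 2L) {
        stop("scope (", d, ", ", st, ") has fewer than 2 complete rows; ",
             "deviation undefined")
      }
      sd_x1 <- sqrt(mean((x1[ok] - ref_x1)^2))
      sd_x2 <- sqrt(mean((x2[ok] - ref_x2)^2))
      chosen <- if (sd_x1 < sd_x2) "X1" else "X2"
      out[[paste(d, st)]] <- data.frame(dataset_id = d, subtype = st,
                                        n = sum(ok), sd_x1 = sd_x1,
                                        sd_x2 = sd_x2, chosen = chosen,
                                        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("x_selection", class(res))
  res
}
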