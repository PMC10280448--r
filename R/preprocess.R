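# Data-preparation chain: mean imputation of missing cells, RR-ratio
# normalization, cross-dataset sum-of-squares normalization, inversion back
# to seconds, the random 70/15/15 split, and sequence formatting.

#' Replace missing cells by the mean of available cycles
#'
#' Every missing cell of a point column is replaced by the mean of the
#' non-missing values of the same column within the same
#' (dataset, subject, subtype) group; when the group has no observed value
#' for that column, the same-dataset column mean is used instead. Imputation
#' operates on raw intervals, before any normalization.
#'
#' @param m `interval_matrix` in state `"raw"`.
#' @return List with `matrix` (the completed `interval_matrix`) and `mask`
#'   (logical matrix, TRUE where a cell was imputed). Non-missing cells are
#'   returned bit-identical.
#' @export
impute_missing_means <- function(m) {
  stopifnot_state(m, "raw", "impute_missing_means")
  v <- m$values
  mask <- is.na(v)
  point_cols <- setdiff(ICG_COLUMNS, "RR")
  for (col in point_cols) {
    if (!anyNA(v[, col])) next
    for (d in unique(m$row_meta$dataset_id)) {
      in_d <- m$row_meta$dataset_id == d
      if (all(is.na(v[in_d, col]))) {
        stop("column ", col, " is entirely missing in dataset '", d,
             "'; cannot impute")
      }
    }
  }
  grp <- paste(m$row_meta$dataset_id, m$row_meta$subject_id,
               m$row_meta$subtype, sep = "\r")
  ds_of_grp <- tapply(m$row_meta$dataset_id, grp, `[`, 1L)
  for (col in point_cols) {
    x <- v[, col]
    if (!anyNA(x)) next
    grp_mean <- tapply(x, grp, mean, na.rm = TRUE)
    ds_mean <- tapply(x, m$row_meta$dataset_id, mean, na.rm = TRUE)
    fill <- grp_mean[grp]
    empty <- !is.finite(fill)
    fill[empty] <- ds_mean[m$row_meta$dataset_id][empty]
    x[is.na(x)] <- fill[is.na(x)]
    v[, col] <- x
  }
  out <- m
  out$values <- v
  list(matrix = out, mask = mask)
}

#' Normalize point latencies by the RR interval
#'
#' Divides each of the eight point columns row-wise by the RR interval of the
#' same beat, removing between-subject heart-rate differences. The RR column
#' itself is kept unchanged (in seconds) so that the transform can be
#' inverted later.
#'
#' @param m `interval_matrix` in state `"raw"`.
#' @return `interval_matrix` in state `"rr_normalized"`.
#' @export
normalize_rr <- function(m) {
  stopifnot_state(m, "raw", "normalize_rr")
  rr <- m$values[, "RR"]
  bad <- which(rr <= 0)
  if (length(bad) > 0L) stop("non-positive RR at row(s) ",
                             paste(utils::head(bad, 5L), collapse = ", "))
  out <- m
  point_cols <- setdiff(ICG_COLUMNS, "RR")
  out$values[, point_cols] <- m$values[, point_cols] / rr
  out$state <- "rr_normalized"
  out
}

#' Scale each point column to unit sum of squares
#'
#' Divides each point column by its Euclidean norm computed over the pooled
#' rows of all datasets, so that one model fits data from different
#' acquisition systems on a common scale. The per-column scale factors are
#' recorded in `ss_scale` for exact inversion; passing previously recorded
#' `scale` applies training-time scales to new data instead of renormalizing.
#'
#' @param m `interval_matrix` in state `"rr_normalized"` with no missing
#'   cells in the point columns.
#' @param scale optional named numeric of previously recorded scale factors.
#' @return `interval_matrix` in state `"ss_normalized"`.
#' @export
normalize_sum_squares <- function(m, scale = NULL) {
  stopifnot_state(m, "rr_normalized", "normalize_sum_squares")
  point_cols <- setdiff(ICG_COLUMNS, "RR")
  x <- m$values[, point_cols, drop = FALSE]
  if (anyNA(x)) stop("missing cells present; impute before sum-of-squares normalization")
  if (is.null(scale)) {
    scale <- sqrt(colSums(x^2))
    names(scale) <- point_cols
  } else {
    if (!all(point_cols %in% names(scale))) {
      stop("provided scale must name all point columns")
    }
    scale <- scale[point_cols]
  }
  if (any(scale <= 0) || any(!is.finite(scale))) {
    zero <- point_cols[which(scale <= 0 | !is.finite(scale))]
    stop("zero or non-finite norm for column(s): ",
         paste(zero, collapse = ", "))
  }
  out <- m
  out$values[, point_cols] <- sweep(x, 2L, scale, "/")
  out$state <- "ss_normalized"
  out$ss_scale <- scale
  out
}

#' Invert normalization back to intervals in seconds
#'
#' Multiplies each point column by its recorded sum-of-squares scale factor
#' and then row-wise by the RR interval, recovering raw latencies to
#' round-off precision.
#'
#' @param m `interval_matrix` in state `"ss_normalized"` (with `ss_scale`)
#'   or `"rr_normalized"`.
#' @return `interval_matrix` in state `"raw"`, all columns in seconds.
#' @export
denormalize <- function(m) {
  if (!inherits(m, "interval_matrix")) stop("not an interval_matrix")
  point_cols <- setdiff(ICG_COLUMNS, "RR")
  out <- m
  if (m$state == "ss_normalized") {
    if (is.null(m$ss_scale)) stop("ss_scale missing; cannot denormalize")
    out$values[, point_cols] <-
      sweep(out$values[, point_cols, drop = FALSE], 2L,
            m$ss_scale[point_cols], "*")
    out$ss_scale <- NULL
    out$state <- "rr_normalized"
  }
  if (out$state == "rr_normalized") {
    out$values[, point_cols] <-
      out$values[, point_cols, drop = FALSE] * out$values[, "RR"]
    out$state <- "raw"
    return(out)
  }
  stop("denormalize: state '", m$state, "' has nothing to invert")
}

#' Express point columns as RR ratios regardless of state
#'
#' Internal convenience used by X selection: returns the beats x 8 matrix of
#' point latencies as fractions of RR.
#' @noRd
as_rr_ratio <- function(m) {
  point_cols <- setdiff(ICG_COLUMNS, "RR")
  if (m$state == "raw") {
    m$values[, point_cols, drop = FALSE] / m$values[, "RR"]
  } else if (m$state == "rr_normalized") {
    m$values[, point_cols, drop = FALSE]
  } else {
    sweep(m$values[, point_cols, drop = FALSE], 2L, m$ss_scale[point_cols], "*")
  }
}

#' Randomly split rows into training, validation and test sets
#'
#' Rows are permuted uniformly at random under the given seed and assigned
#' 70/15/15 by default: `floor(0.70 n)` to training, `floor(0.15 n)` to
#' validation and the remainder to test. An optional grouping vector assigns
#' whole groups (e.g. subjects) to partitions for leakage-aware evaluation.
#'
#' @param n_rows number of rows (>= 10).
#' @param seed integer seed; identical seeds give identical splits.
#' @param ratios length-3 proportions for train/validation/test.
#' @param groups optional length-`n_rows` grouping vector; whole groups are
#'   assigned to one partition each.
#' @return Object of class `split_indices`: list with integer index vectors
#'   `train`, `val`, `test` and the `seed`.
#' @export
split_data <- function(n_rows, seed, ratios = c(0.70, 0.15, 0.15),
                       groups = NULL) {
  if (n_rows < 10L) stop("n_rows must be >= 10 (split degenerates)")
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-8) {
    stop("ratios must be three proportions summing to 1")
  }
  if (is.null(groups)) {
    perm <- with_seed(seed, sample.int(n_rows))
    n_train <- floor(ratios[1L] * n_rows)
    n_val <- floor(ratios[2L] * n_rows)
    out <- list(train = sort(perm[seq_len(n_train)]),
                val = sort(perm[n_train + seq_len(n_val)]),
                test = sort(perm[(n_train + n_val + 1L):n_rows]),
                seed = seed)
  } else {
    if (length(groups) != n_rows) stop("groups must have length n_rows")
    gs <- unique(groups)
    gperm <- with_seed(seed, sample(gs))
    sizes <- table(groups)[as.character(gperm)]
    cum <- cumsum(as.numeric(sizes)) / n_rows
    part <- ifelse(cum <= ratios[1L], 1L,
                   ifelse(cum <= ratios[1L] + ratios[2L], 2L, 3L))
    assign_of <- stats::setNames(part, as.character(gperm))
    p <- unname(assign_of[as.character(groups)])
    out <- list(train = which(p == 1L), val = which(p == 2L),
                test = which(p == 3L), seed = seed)
  }
  structure(out, class = "split_indices")
}

#' Format the interval matrix as per-stream sequences
#'
#' Emits, for each (dataset, subject, subtype) stream, the time-ordered
#' sequence of 8-dimensional observation vectors consumed by the network.
#' The RR column is excluded from the channels and carried as metadata, and
#' no delay line crosses a stream boundary.
#'
#' @param m `interval_matrix` in state `"ss_normalized"`.
#' @return List of streams; each stream is a list with `y` (T x 8 matrix),
#'   `rr`, `subject_id`, `dataset_id`, `subtype` and `rows` (the original
#'   row indices in `m`).
#' @export
to_sequences <- function(m) {
  stopifnot_state(m, "ss_normalized", "to_sequences")
  point_cols <- setdiff(ICG_COLUMNS, "RR")
  key <- paste(m$row_meta$dataset_id, m$row_meta$subject_id,
               m$row_meta$subtype, sep = "\r")
  lapply(split(seq_len(nrow(m$values)), key), function(rows) {
    rows <- rows[order(m$row_meta$beat_index[rows])]
    list(y = m$values[rows, point_cols, drop = FALSE],
         rr = m$values[rows, "RR"],
         subject_id = m$row_meta$subject_id[rows[1L]],
         dataset_id = m$row_meta$dataset_id[rows[1L]],
         subtype = m$row_meta$subtype[rows[1L]],
         rows = rows)
  })
}
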