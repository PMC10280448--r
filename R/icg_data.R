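# Domain constants and containers for annotated ICG beats and the
# R-peak-anchored interval matrix.

#' Characteristic-point labels of the dZ/dt complex
#'
#' The seven landmarks of one impedance-cardiography beat, with the X point
#' split into its two candidates X1 and X2. The order reflects the expected
#' within-beat time order when all points are present.
#'
#' @format Character vector of length 8.
#' @export
ICG_POINTS <- c("A", "B", "E", "X1", "X2", "Y", "O", "Z")

#' Columns of the interval matrix
#'
#' RR (the beat-to-beat R interval) followed by the R-to-point latency
#' columns, one per characteristic point.
#'
#' @format Character vector of length 9.
#' @export
ICG_COLUMNS <- c("RR", paste0("R", ICG_POINTS))

#' Morphological subtypes of the dZ/dt complex
#'
#' ABEXYOZ0 is the typical complex carrying all characteristic points;
#' ABEXYOZ1-5 are atypical variants with specific points undetectable;
#' ABEXYOZu carries no detectable characteristic points at all.
#'
#' @format Character vector of length 7.
#' @export
ICG_SUBTYPES <- c(paste0("ABEXYOZ", 0:5), "ABEXYOZu")

#' @rdname ICG_SUBTYPES
#' @export
SUBTYPE_UNFORECASTABLE <- "ABEXYOZu"

# Points that appear and disappear together in atypical complexes.
POINT_GROUPS <- list(ABE = c("A", "B", "E"), YOZ = c("Y", "O", "Z"))

ANNOTATION_COLUMNS <- c("subject_id", "dataset_id", "beat_index", "subtype",
                        "r_time", paste0("t_", ICG_POINTS))

point_time_cols <- function() paste0("t_", ICG_POINTS)

#' Validate a table of annotated beats
#'
#' Checks the column contract, subtype labels, finiteness of R-peak times and
#' strict monotonicity of `r_time` within each (dataset, subject), and returns
#' the table ordered by dataset, subject and beat index.
#'
#' @param beats data frame with columns `subject_id`, `dataset_id`,
#'   `beat_index`, `subtype`, `r_time` and `t_A` ... `t_Z` (NA = missing point).
#' @return The validated, reordered data frame.
#' @export
validate_beats <- function(beats) {
  if (!is.data.frame(beats)) stop("`beats` must be a data frame")
  missing_cols <- setdiff(ANNOTATION_COLUMNS, names(beats))
  if (length(missing_cols) > 0L) {
    stop("annotation table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad_sub <- which(!beats$subtype %in% ICG_SUBTYPES)
  if (length(bad_sub) > 0L) {
    stop("unknown subtype label(s) at row(s): ",
         paste(utils::head(bad_sub, 5L), collapse = ", "))
  }
  if (!is.numeric(beats$r_time) || any(!is.finite(beats$r_time))) {
    stop("r_time must be finite numeric")
  }
  for (tc in point_time_cols()) {
    v <- beats[[tc]]
    if (!is.numeric(v)) stop("column ", tc, " must be numeric")
    if (any(is.nan(v) | is.infinite(v), na.rm = TRUE)) {
      stop("column ", tc, " contains non-finite point times")
    }
  }
  beats <- beats[order(beats$dataset_id, beats$subject_id, beats$beat_index), ,
                 drop = FALSE]
  key <- paste(beats$dataset_id, beats$subject_id, sep = "\r")
  for (k in unique(key)) {
    rt <- beats$r_time[key == k]
    if (length(rt) > 1L && any(diff(rt) <= 0)) {
      subj <- beats$subject_id[key == k][1L]
      stop("r_time is not strictly increasing for subject '", subj, "'")
    }
  }
  rownames(beats) <- NULL
  beats
}

#' Read annotated beats from a delimited text file
#'
#' The file is comma-separated with a fixed header (`subject_id`,
#' `dataset_id`, `beat_index`, `subtype`, `r_time`, `t_A` ... `t_Z`); an empty
#' cell or `NA` encodes a missing characteristic point. Times are seconds.
#'
#' @param path path to the annotation file.
#' @return A validated data frame of beats ordered by dataset, subject and
#'   beat index.
#' @seealso [write_annotations()]
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA", "NaN"))
  validate_beats(df)
}

#' Write annotated beats to a delimited text file
#'
#' Inverse of [read_annotations()]: missing points are written as empty cells
#' so that read-then-write round-trips valid tables.
#'
#' @param beats data frame of beats (see [validate_beats()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(beats, path) {
  beats <- validate_beats(beats)
  utils::write.csv(beats[, ANNOTATION_COLUMNS], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Construct an interval-matrix object
#'
#' Low-level constructor; most users obtain interval matrices from
#' [build_interval_matrix()].
#'
#' @param values numeric matrix with columns [ICG_COLUMNS] (NA = missing).
#' @param row_meta data frame with per-row `subject_id`, `dataset_id`,
#'   `subtype`, `beat_index`.
#' @param state normalization state: `"raw"`, `"rr_normalized"` or
#'   `"ss_normalized"`.
#' @param ss_scale named per-column scale factors, required iff
#'   `state == "ss_normalized"`.
#' @return An object of class `interval_matrix`.
#' @export
interval_matrix <- function(values, row_meta,
                            state = c("raw", "rr_normalized", "ss_normalized"),
                            ss_scale = NULL) {
  state <- match.arg(state)
  if (!is.matrix(values) || ncol(values) != length(ICG_COLUMNS)) {
    stop("values must be a matrix with ", length(ICG_COLUMNS), " columns")
  }
  colnames(values) <- ICG_COLUMNS
  if (!is.data.frame(row_meta) || nrow(row_meta) != nrow(values)) {
    stop("row_meta must be a data frame with one row per matrix row")
  }
  if (anyNA(values[, "RR"])) stop("RR column must not contain missing values")
  if (state == "ss_normalized") {
    if (is.null(ss_scale)) stop("ss_scale required when state = ss_normalized")
    if (any(!is.finite(ss_scale)) || any(ss_scale <= 0)) {
      stop("ss_scale factors must be positive and finite")
    }
  } else if (!is.null(ss_scale)) {
    stop("ss_scale only meaningful when state = ss_normalized")
  }
  structure(list(values = values, row_meta = row_meta, state = state,
                 ss_scale = ss_scale),
            class = "interval_matrix")
}

#' @export
print.interval_matrix <- function(x, ...) {
  cat("<interval_matrix> ", nrow(x$values), " beats x ", ncol(x$values),
      " columns, state = ", x$state, "\n", sep = "")
  cat("  datasets: ", paste(unique(x$row_meta$dataset_id), collapse = ", "),
      "; subjects: ", length(unique(paste(x$row_meta$dataset_id,
                                          x$row_meta$subject_id))), "\n",
      sep = "")
  n_missing <- sum(is.na(x$values))
  cat("  missing cells: ", n_missing, " (",
      sprintf("%.1f", 100 * n_missing / length(x$values)), "%)\n", sep = "")
  invisible(x)
}

#' Build the interval time-series matrix from annotated beats
#'
#' For each subject, the forward RR interval of beat i is
#' `r_time(i+1) - r_time(i)`; the last beat of every subject is dropped
#' because it has no forward interval. Each point latency is
#' `t_P(i) - r_time(i)` where the point is present, NA otherwise, so every
#' latency lies inside its own RR window on physiological data.
#'
#' @param beats validated data frame of annotated beats.
#' @return An `interval_matrix` in state `"raw"`.
#' @export
build_interval_matrix <- function(beats) {
  beats <- validate_beats(beats)
  key <- paste(beats$dataset_id, beats$subject_id, sep = "\r")
  vals <- list()
  metas <- list()
  for (k in unique(key)) {
    b <- beats[key == k, , drop = FALSE]
    if (nrow(b) < 2L) {
      warning("subject '", b$subject_id[1L],
              "' has a single beat and was skipped (RR undefined)")
      next
    }
    rr <- diff(b$r_time)
    n <- nrow(b) - 1L
    m <- matrix(NA_real_, n, length(ICG_COLUMNS),
                dimnames = list(NULL, ICG_COLUMNS))
    m[, "RR"] <- rr
    for (p in ICG_POINTS) {
      lat <- b[[paste0("t_", p)]][seq_len(n)] - b$r_time[seq_len(n)]
      bad <- which(!is.na(lat) & lat <= 0)
      if (length(bad) > 0L) {
        stop("non-positive latency for point ", p, " of subject '",
             b$subject_id[1L], "' at beat_index ", b$beat_index[bad[1L]])
      }
      m[, paste0("R", p)] <- lat
    }
    vals[[k]] <- m
    metas[[k]] <- data.frame(subject_id = b$subject_id[seq_len(n)],
                             dataset_id = b$dataset_id[seq_len(n)],
                             subtype = b$subtype[seq_len(n)],
                             beat_index = b$beat_index[seq_len(n)],
                             stringsAsFactors = FALSE)
  }
  if (length(vals) == 0L) stop("no subject had >= 2 beats")
  interval_matrix(do.call(rbind, vals), do.call(rbind, metas), state = "raw")
}

#' Summarize missingness of characteristic points
#'
#' Reports, per dataset, the percentage of beats missing each point, plus the
#' joint behavior of the co-occurring groups ABE and YOZ (points that appear
#' and disappear together in atypical complexes).
#'
#' @param beats validated data frame of annotated beats.
#' @return List with `per_point` (dataset x point percent missing, long
#'   format) and `groups` (per dataset and group: percent of beats where the
#'   whole group is missing, and among beats with any of the group missing,
#'   the percent where all are).
#' @export
missingness_summary <- function(beats) {
  beats <- validate_beats(beats)
  if (nrow(beats) == 0L) stop("empty beat table")
  datasets <- unique(beats$dataset_id)
  per_point <- do.call(rbind, lapply(datasets, function(d) {
    b <- beats[beats$dataset_id == d, , drop = FALSE]
    data.frame(dataset_id = d, point = ICG_POINTS,
               pct_missing = vapply(ICG_POINTS, function(p) {
                 100 * mean(is.na(b[[paste0("t_", p)]]))
               }, numeric(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  groups <- do.call(rbind, lapply(datasets, function(d) {
    b <- beats[beats$dataset_id == d, , drop = FALSE]
    do.call(rbind, lapply(names(POINT_GROUPS), function(g) {
      miss <- sapply(POINT_GROUPS[[g]],
                     function(p) is.na(b[[paste0("t_", p)]]))
      miss <- matrix(miss, nrow = nrow(b))
      all_missing <- rowSums(miss) == ncol(miss)
      any_missing <- rowSums(miss) > 0L
      data.frame(dataset_id = d, group = g,
                 pct_all_missing = 100 * mean(all_missing),
                 co_missing_coherence = if (any(any_missing))
                   100 * sum(all_missing) / sum(any_missing) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  list(per_point = per_point, groups = groups)
}
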