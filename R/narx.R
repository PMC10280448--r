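# The NARX recurrent network: topology, weight initialization, open/closed
# loop forward passes, delay removal, and exact residual Jacobians for
# open-loop (teacher-forced) training.
#
# The update rule with feedback taps {1, 2} and the exogenous line carrying
# the same 8-channel series is
#   y_hat(t) = W_o %*% tanh(W_x [x(t-1); x(t-2)] + W_y [y(t-1); y(t-2)] + b_h) + b_o
# Open loop (series-parallel) reads the true series at the taps; closed loop
# (parallel) reads the network's own previous predictions.

#' Network topology configuration
#'
#' The default matches the study setting: eight input and eight output
#' channels (the RR-ratio latencies of the eight characteristic points), one
#' hidden layer of ten hyperbolic-tangent units, linear output, and delay
#' taps \{1, 2\} on both the exogenous and the feedback line.
#'
#' @param n_channels number of input = output channels.
#' @param n_hidden hidden-layer size (>= 1).
#' @param input_delays positive integer taps on the exogenous line.
#' @param feedback_delays positive integer taps on the feedback line.
#' @return Object of class `narx_config`.
#' @export
narx_config <- function(n_channels = 8L, n_hidden = 10L,
                        input_delays = c(1L, 2L),
                        feedback_delays = c(1L, 2L)) {
  if (n_hidden < 1L) stop("n_hidden must be >= 1")
  if (length(input_delays) == 0L || any(input_delays < 1L) ||
      any(input_delays != as.integer(input_delays))) {
    stop("input_delays must be non-empty positive integers")
  }
  if (length(feedback_delays) == 0L || any(feedback_delays < 1L) ||
      any(feedback_delays != as.integer(feedback_delays))) {
    stop("feedback_delays must be non-empty positive integers")
  }
  structure(list(n_channels = as.integer(n_channels),
                 n_hidden = as.integer(n_hidden),
                 input_delays = sort(as.integer(input_delays)),
                 feedback_delays = sort(as.integer(feedback_delays))),
            class = "narx_config")
}

n_weights <- function(cfg) {
  px <- cfg$n_channels * length(cfg$input_delays)
  py <- cfg$n_channels * length(cfg$feedback_delays)
  cfg$n_hidden * (px + py + 1L) + cfg$n_channels * (cfg$n_hidden + 1L)
}

#' Initialize network weights
#'
#' Nguyen-Widrow-style initialization by default: each hidden unit's incoming
#' weight vector is drawn uniformly, renormalized to the magnitude
#' `0.7 * n_hidden^(1/p)` (p = total tap inputs) so first activations fall in
#' the active region of the hyperbolic tangent, with hidden biases spread
#' evenly across that region. A plain `uniform(-0.5, 0.5)` fallback is
#' available. Deterministic under `seed`.
#'
#' @param cfg a [narx_config()].
#' @param seed integer seed.
#' @param method `"nguyen-widrow"` or `"uniform"`.
#' @return Object of class `narx_model`: list with `config`, `weights`
#'   (`W_x`, `W_y`, `b_h`, `W_o`, `b_o`), `removed_delay = FALSE` and an
#'   empty `norm` slot for normalization metadata.
#' @export
narx_init <- function(cfg, seed = 1L,
                      method = c("nguyen-widrow", "uniform")) {
  method <- match.arg(method)
  px <- cfg$n_channels * length(cfg$input_delays)
  py <- cfg$n_channels * length(cfg$feedback_delays)
  h <- cfg$n_hidden
  K <- cfg$n_channels
  w <- with_seed(seed, {
    if (method == "nguyen-widrow") {
      p <- px + py
      mag <- 0.7 * h^(1 / p)
      Win <- matrix(stats::runif(h * p, -1, 1), h, p)
      Win <- Win * (mag / pmax(sqrt(rowSums(Win^2)), .Machine$double.eps))
      b_h <- if (h == 1L) stats::runif(1L, -mag, mag) else
        mag * seq(-1, 1, length.out = h) * sample(c(-1, 1), h, replace = TRUE)
      list(W_x = Win[, seq_len(px), drop = FALSE],
           W_y = Win[, px + seq_len(py), drop = FALSE],
           b_h = as.numeric(b_h),
           W_o = matrix(stats::runif(K * h, -0.5, 0.5) / sqrt(h), K, h),
           b_o = stats::runif(K, -0.1, 0.1))
    } else {
      list(W_x = matrix(stats::runif(h * px, -0.5, 0.5), h, px),
           W_y = matrix(stats::runif(h * py, -0.5, 0.5), h, py),
           b_h = stats::runif(h, -0.5, 0.5),
           W_o = matrix(stats::runif(K * h, -0.5, 0.5), K, h),
           b_o = stats::runif(K, -0.5, 0.5))
    }
  })
  structure(list(config = cfg, weights = w, removed_delay = FALSE,
                 norm = NULL),
            class = "narx_model")
}

#' @export
print.narx_model <- function(x, ...) {
  cfg <- x$config
  cat("<narx_model> ", cfg$n_channels, " channels, ", cfg$n_hidden,
      " hidden tanh units, taps x{", paste(cfg$input_delays, collapse = ","),
      "} y{", paste(cfg$feedback_delays, collapse = ","), "}",
      if (isTRUE(x$removed_delay)) " [delay removed]" else "", "\n", sep = "")
  cat("  ", n_weights(cfg), " weights; trained: ",
      if (is.null(x$norm)) "no normalization metadata" else "with normalization metadata",
      "\n", sep = "")
  invisible(x)
}

# Pack weights row-major so each hidden unit's incoming weights are
# contiguous: c(rows of W_x, rows of W_y, b_h, rows of W_o, b_o).
pack_weights <- function(w) {
  c(as.vector(t(w$W_x)), as.vector(t(w$W_y)), w$b_h,
    as.vector(t(w$W_o)), w$b_o)
}

unpack_weights <- function(vec, cfg) {
  px <- cfg$n_channels * length(cfg$input_delays)
  py <- cfg$n_channels * length(cfg$feedback_delays)
  h <- cfg$n_hidden
  K <- cfg$n_channels
  i <- 0L
  take <- function(n) {
    out <- vec[i + seq_len(n)]
    i <<- i + n
    out
  }
  list(W_x = matrix(take(h * px), h, px, byrow = TRUE),
       W_y = matrix(take(h * py), h, py, byrow = TRUE),
       b_h = take(h),
       W_o = matrix(take(K * h), K, h, byrow = TRUE),
       b_o = take(K))
}

# Single batched layer evaluation on tap design matrices.
narx_eval <- function(w, Xx, Xy) {
  A <- Xx %*% t(w$W_x) + Xy %*% t(w$W_y)
  H <- tanh(sweep(A, 2L, w$b_h, "+"))
  pred <- H %*% t(w$W_o)
  pred <- sweep(pred, 2L, w$b_o, "+")
  list(H = H, pred = pred)
}

# Build tap design matrices from a series for given delays (0 allowed when a
# removed-delay model reads the current sample). Rows correspond to output
# times `t_out`.
tap_matrix <- function(series, delays, t_out) {
  do.call(cbind, lapply(delays, function(d) {
    series[t_out - d, , drop = FALSE]
  }))
}

effective_delays <- function(model) {
  s <- as.integer(isTRUE(model$removed_delay))
  list(input = model$config$input_delays - s,
       feedback = model$config$feedback_delays - s)
}

#' Open-loop (series-parallel) forward pass
#'
#' Teacher-forced prediction: the feedback taps read the true target series.
#' For a model with taps \{1, 2\}, outputs are defined from the third sample
#' on; a delay-removed model emits each forecast one index earlier.
#'
#' @param model `narx_model`.
#' @param y target series, T x n_channels matrix.
#' @param x exogenous series of the same shape; defaults to `y` (the
#'   application feeds the same eight ratio channels to both lines).
#' @return T x n_channels matrix of predictions, NA in the rows before the
#'   delay horizon.
#' @export
narx_forward_open <- function(model, y, x = y) {
  y <- as.matrix(y)
  x <- as.matrix(x)
  if (!identical(dim(x), dim(y))) stop("x and y must have the same shape")
  del <- effective_delays(model)
  dmax <- max(del$input, del$feedback)
  if (nrow(y) < dmax + 1L) {
    stop("series length must exceed the maximum delay (", dmax, ")")
  }
  t_out <- (dmax + 1L):nrow(y)
  fp <- narx_eval(model$weights,
                  tap_matrix(x, del$input, t_out),
                  tap_matrix(y, del$feedback, t_out))
  out <- matrix(NA_real_, nrow(y), ncol(y), dimnames = dimnames(y))
  out[t_out, ] <- fp$pred
  out
}

#' Closed-loop (parallel) forward pass: free-running multi-step forecast
#'
#' The feedback taps read the network's own previous predictions, seeded by
#' `y_init`; the exogenous taps read `x_seq`. Not available on a
#' delay-removed model (a zero feedback delay would make the update
#' implicit); use [impute_missing_points()] for observation-aware forecasting.
#'
#' @param model `narx_model` with `removed_delay = FALSE`.
#' @param x_seq exogenous series, T x n_channels.
#' @param y_init matrix of exactly `max(feedback_delays)` seed rows (oldest
#'   first), aligned with the first rows of `x_seq`.
#' @return T x n_channels matrix; the first `d` rows (the seed horizon) are NA.
#' @export
narx_forward_closed <- function(model, x_seq, y_init) {
  if (isTRUE(model$removed_delay)) {
    stop("free-running closed loop requires minimum feedback delay >= 1")
  }
  x_seq <- as.matrix(x_seq)
  y_init <- as.matrix(y_init)
  d <- max(model$config$input_delays, model$config$feedback_delays)
  if (nrow(y_init) != d || ncol(y_init) != model$config$n_channels) {
    stop("y_init must supply exactly ", d, " x ", model$config$n_channels,
         " seed values")
  }
  T_len <- nrow(x_seq)
  if (T_len < d + 1L) stop("x_seq shorter than the delay horizon")
  buf <- matrix(NA_real_, T_len, model$config$n_channels)
  buf[seq_len(d), ] <- y_init
  w <- model$weights
  id <- model$config$input_delays
  fd <- model$config$feedback_delays
  for (t in (d + 1L):T_len) {
    xt <- as.vector(t(x_seq[t - id, , drop = FALSE]))
    yt <- as.vector(t(buf[t - fd, , drop = FALSE]))
    h <- tanh(w$W_x %*% xt + w$W_y %*% yt + w$b_h)
    buf[t, ] <- as.vector(w$W_o %*% h + w$b_o)
  }
  out <- buf
  out[seq_len(d), ] <- NA_real_
  out
}

#' Hybrid observation-aware closed-loop forecast
#'
#' Runs the network forward along a partially observed stream: every tap
#' reads the observed value where one exists and the network's own previous
#' prediction where it does not, so free running never discards usable
#' observations. Missing values inside the initial delay horizon are seeded
#' with `seed_values` (typically the training-set channel means).
#'
#' @param model `narx_model`.
#' @param y_obs T x n_channels matrix with NA at unobserved cells.
#' @param seed_values length-n_channels fallback values for missing cells in
#'   the first `d` rows; defaults to the per-channel means of the observed
#'   cells of `y_obs`.
#' @return List with `pred` (network output, NA before the horizon) and
#'   `completed` (`y_obs` with missing cells filled by predictions).
#' @export
narx_forecast_hybrid <- function(model, y_obs, seed_values = NULL) {
  y_obs <- as.matrix(y_obs)
  K <- model$config$n_channels
  if (ncol(y_obs) != K) stop("y_obs must have ", K, " columns")
  id <- model$config$input_delays
  fd <- model$config$feedback_delays
  d <- max(id, fd)
  if (nrow(y_obs) < d + 1L) stop("stream shorter than the delay horizon")
  if (is.null(seed_values)) seed_values <- colMeans(y_obs, na.rm = TRUE)
  if (any(!is.finite(seed_values))) {
    stop("seed_values must be finite for every channel")
  }
  val <- y_obs
  for (t in seq_len(d)) {
    miss <- is.na(val[t, ])
    val[t, miss] <- seed_values[miss]
  }
  pred <- matrix(NA_real_, nrow(y_obs), K, dimnames = dimnames(y_obs))
  w <- model$weights
  for (t in (d + 1L):nrow(y_obs)) {
    xt <- as.vector(t(val[t - id, , drop = FALSE]))
    yt <- as.vector(t(val[t - fd, , drop = FALSE]))
    h <- tanh(w$W_x %*% xt + w$W_y %*% yt + w$b_h)
    p <- as.vector(w$W_o %*% h + w$b_o)
    pred[t, ] <- p
    miss <- is.na(y_obs[t, ])
    val[t, miss] <- p[miss]
  }
  list(pred = pred, completed = val)
}

#' Shift the delay taps one step earlier
#'
#' Converts taps \{1, 2\} into \{0, 1\} on both lines so the fitted network
#' emits each forecast one time step ahead of the original alignment. Weights
#' are preserved bit-exactly; only the output alignment changes, so on a
#' recorded stream the removed-delay network computes the same values one
#' index earlier.
#'
#' @param model fitted `narx_model` with minimum delay >= 1 and delay not
#'   already removed.
#' @return The model with `removed_delay = TRUE`.
#' @export
narx_remove_delay <- function(model) {
  if (isTRUE(model$removed_delay)) {
    stop("delay already removed; minimum delay would drop below 0")
  }
  if (min(model$config$input_delays, model$config$feedback_delays) < 1L) {
    stop("minimum delay is already 0")
  }
  model$removed_delay <- TRUE
  model
}

#' Assemble teacher-forced training samples from sequences
#'
#' Converts streams (or a single series) into the tap design matrices used by
#' open-loop training: for every in-stream time t beyond the delay horizon,
#' one sample with exogenous taps `Xx`, feedback taps `Xy` (both read the
#' true series) and target `Y = y(t)`. Delay lines never cross a stream
#' boundary.
#'
#' @param streams list of streams as returned by [to_sequences()] (or any
#'   list of lists with a `y` matrix), or a single T x n_channels matrix.
#' @param cfg a [narx_config()].
#' @return List with matrices `Xx`, `Xy`, `Y` and vectors `stream`, `t`
#'   mapping each sample to its origin.
#' @export
narx_samples <- function(streams, cfg) {
  if (is.matrix(streams)) streams <- list(list(y = streams))
  d <- max(cfg$input_delays, cfg$feedback_delays)
  keep <- which(vapply(streams, function(s) nrow(s$y) >= d + 1L, logical(1)))
  if (length(keep) == 0L) stop("no stream is longer than the delay horizon")
  parts <- lapply(keep, function(i) {
    y <- streams[[i]]$y
    t_out <- (d + 1L):nrow(y)
    list(Xx = tap_matrix(y, cfg$input_delays, t_out),
         Xy = tap_matrix(y, cfg$feedback_delays, t_out),
         Y = y[t_out, , drop = FALSE],
         stream = rep(i, length(t_out)),
         t = t_out)
  })
  list(Xx = do.call(rbind, lapply(parts, `[[`, "Xx")),
       Xy = do.call(rbind, lapply(parts, `[[`, "Xy")),
       Y = do.call(rbind, lapply(parts, `[[`, "Y")),
       stream = unlist(lapply(parts, `[[`, "stream")),
       t = unlist(lapply(parts, `[[`, "t")))
}

# Residual vector (channel-fastest) on tap design matrices.
narx_residuals <- function(w, Xx, Xy, Y) {
  fp <- narx_eval(w, Xx, Xy)
  list(e = as.vector(t(fp$pred - Y)), pred = fp$pred, H = fp$H)
}

#' Exact Jacobian of the open-loop residuals
#'
#' Computes the matrix of derivatives of every residual component (one row
#' per sample and output channel, channel-fastest) with respect to every
#' weight, under teacher forcing -- each sample is feed-forward, so no
#' backpropagation through time is involved. Closed-loop (free-running)
#' batches are not supported.
#'
#' @param model `narx_model` (or a weight list via `weights`).
#' @param samples list with `Xx`, `Xy`, `Y` as from [narx_samples()].
#' @return List with `J` ((n_samples * n_channels) x n_weights matrix),
#'   `residuals` (matching vector, prediction minus target) and `pred`.
#' @export
narx_jacobian <- function(model, samples) {
  cfg <- model$config
  w <- model$weights
  Xx <- samples$Xx
  Xy <- samples$Xy
  Y <- samples$Y
  n <- nrow(Y)
  K <- cfg$n_channels
  h <- cfg$n_hidden
  px <- ncol(Xx)
  py <- ncol(Xy)
  fp <- narx_eval(w, Xx, Xy)
  D <- 1 - fp$H^2
  Nw <- n_weights(cfg)
  J <- matrix(0, n * K, Nw)
  rep_idx <- rep(seq_len(n), each = K)
  for (j in seq_len(h)) {
    gain <- rep(w$W_o[, j], times = n)          # channel-fastest factor
    Mx <- (D[, j] * Xx)[rep_idx, , drop = FALSE] * gain
    J[, (j - 1L) * px + seq_len(px)] <- Mx
    My <- (D[, j] * Xy)[rep_idx, , drop = FALSE] * gain
    J[, h * px + (j - 1L) * py + seq_len(py)] <- My
    J[, h * (px + py) + j] <- D[rep_idx, j] * gain
  }
  o3 <- h * (px + py) + h
  for (k in seq_len(K)) {
    rows <- seq(k, n * K, by = K)
    J[rows, o3 + (k - 1L) * h + seq_len(h)] <- fp$H
    J[rows, o3 + K * h + k] <- 1
  }
  list(J = J, residuals = as.vector(t(fp$pred - Y)), pred = fp$pred)
}

# Sum-of-squares loss (SSE/2) and its exact gradient, computed by direct
# backpropagation (no Jacobian materialized). Used by scaled conjugate
# gradient.
narx_loss_grad <- function(wvec, cfg, Xx, Xy, Y) {
  w <- unpack_weights(wvec, cfg)
  fp <- narx_eval(w, Xx, Xy)
  E <- fp$pred - Y
  G <- (E %*% w$W_o) * (1 - fp$H^2)
  grad <- pack_weights(list(W_x = t(G) %*% Xx,
                            W_y = t(G) %*% Xy,
                            b_h = colSums(G),
                            W_o = t(E) %*% fp$H,
                            b_o = colSums(E)))
  list(loss = 0.5 * sum(E^2), grad = grad)
}

#' Persist a fitted model as JSON
#'
#' Stores topology, weights (nested arrays), delay-removal state and
#' normalization metadata under a versioned schema.
#'
#' @param model `narx_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
narx_save <- function(model, path) {
  obj <- list(schema = "icgnarx/narx-model/1",
              config = unclass(model$config),
              weights = lapply(model$weights, function(x) {
                if (is.matrix(x)) unname(apply(x, 1L, identity,
                                               simplify = FALSE)) else unname(x)
              }),
              removed_delay = isTRUE(model$removed_delay),
              norm = lapply(model$norm, as.list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a model saved by [narx_save()]
#'
#' @param path JSON file path.
#' @return `narx_model`.
#' @export
narx_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "icgnarx/narx-model/1")) {
    stop("unrecognized model schema: ", obj$schema)
  }
  cfg <- narx_config(obj$config$n_channels, obj$config$n_hidden,
                     obj$config$input_delays, obj$config$feedback_delays)
  as_mat <- function(x) if (is.matrix(x)) x else do.call(rbind, x)
  weights <- list(W_x = as_mat(obj$weights$W_x),
                  W_y = as_mat(obj$weights$W_y),
                  b_h = as.numeric(obj$weights$b_h),
                  W_o = as_mat(obj$weights$W_o),
                  b_o = as.numeric(obj$weights$b_o))
  norm <- obj$norm
  if (!is.null(norm$ss_scale)) norm$ss_scale <- unlist(norm$ss_scale)
  if (!is.null(norm$col_means)) norm$col_means <- unlist(norm$col_means)
  structure(list(config = cfg, weights = weights,
                 removed_delay = isTRUE(obj$removed_delay), norm = norm),
            class = "narx_model")
}
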