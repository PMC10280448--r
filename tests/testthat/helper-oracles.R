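# Independent brute-force oracles and fixture builders shared by the tests.
# The oracles are written as explicit elementwise loops so they share no code
# path with the package implementations.

oracle_mse <- function(t, p) {
  s <- 0
  for (i in seq_along(t)) s <- s + (t[i] - p[i])^2
  s / length(t)
}

oracle_mae <- function(t, p) {
  s <- 0
  for (i in seq_along(t)) s <- s + abs(t[i] - p[i])
  s / length(t)
}

oracle_pearson <- function(t, p) {
  mt <- sum(t) / length(t)
  mp <- sum(p) / length(p)
  num <- 0
  dt <- 0
  dp <- 0
  for (i in seq_along(t)) {
    num <- num + (t[i] - mt) * (p[i] - mp)
    dt <- dt + (t[i] - mt)^2
    dp <- dp + (p[i] - mp)^2
  }
  num / sqrt(dt * dp)
}

oracle_vecv <- function(t, p) {
  mt <- sum(t) / length(t)
  sse <- 0
  sst <- 0
  for (i in seq_along(t)) {
    sse <- sse + (t[i] - p[i])^2
    sst <- sst + (t[i] - mt)^2
  }
  (1 - sse / sst) * 100
}

oracle_ccc <- function(t, p) {
  n <- length(t)
  mt <- sum(t) / n
  mp <- sum(p) / n
  vt <- 0
  vp <- 0
  cv <- 0
  for (i in seq_len(n)) {
    vt <- vt + (t[i] - mt)^2
    vp <- vp + (p[i] - mp)^2
    cv <- cv + (t[i] - mt) * (p[i] - mp)
  }
  vt <- vt / n
  vp <- vp / n
  cv <- cv / n
  2 * cv / (vt + vp + (mt - mp)^2)
}

# Minimal well-formed annotation table: one subject, evenly spaced R peaks,
# all point latencies fixed fractions of the RR interval.
make_beats <- function(n_beats = 5, subject = "s1", dataset = "V",
                       rr = 0.8, subtype = "ABEXYOZ0") {
  r_time <- (seq_len(n_beats) - 1) * rr
  b <- data.frame(subject_id = subject, dataset_id = dataset,
                  beat_index = seq_len(n_beats) - 1L, subtype = subtype,
                  r_time = r_time, stringsAsFactors = FALSE)
  fr <- c(A = 0.05, B = 0.10, E = 0.18, X1 = 0.30, X2 = 0.38,
          Y = 0.50, O = 0.62, Z = 0.75)
  for (p in names(fr)) b[[paste0("t_", p)]] <- r_time + fr[[p]] * rr
  b
}

# Scalar two-tap toy network (1 channel, 1 hidden unit) with hand-set weights.
toy_model <- function(a1 = 0.3, a2 = -0.2, b1 = 0.5, b2 = 0.1,
                      bh = 0.05, c_out = 1.2, d_out = -0.1) {
  cfg <- narx_config(n_channels = 1L, n_hidden = 1L)
  model <- narx_init(cfg, seed = 1)
  model$weights <- list(W_x = matrix(c(a1, a2), 1, 2),
                        W_y = matrix(c(b1, b2), 1, 2),
                        b_h = bh,
                        W_o = matrix(c_out, 1, 1),
                        b_o = d_out)
  model
}

# A fitted-looking multichannel model whose norm slot matches a matrix's
# scales, for exercising imputation mechanics without training.
model_for_matrix <- function(m_ss, seed = 1) {
  model <- narx_init(narx_config(), seed = seed)
  pts <- setdiff(ICG_COLUMNS, "RR")
  model$norm <- list(ss_scale = m_ss$ss_scale,
                     col_means = colMeans(m_ss$values[, pts]))
  model
}
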