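# A small normalized cohort matrix plus an (untrained) model whose norm slot
# matches, for exercising imputation mechanics.
small_setup <- function(seed = 1, beats = 40, mask = NULL) {
  cfg <- cohort_config(datasets = list(list(dataset_id = "V",
                                            n_subjects = 2L,
                                            rr_mean = 0.8, rr_sd = 0.04)),
                       beats_per_subject = beats, seed = seed)
  gen <- generate_cohort(cfg)
  m <- suppressWarnings(build_interval_matrix(gen$beats))
  m_ss <- normalize_sum_squares(normalize_rr(m))
  list(m_ss = m_ss, model = model_for_matrix(m_ss, seed = seed))
}

test_that("imputation fills exactly the masked cells and nothing else", {
  s <- small_setup()
  pts <- setdiff(ICG_COLUMNS, "RR")
  mask <- matrix(FALSE, nrow(s$m_ss$values), 8,
                 dimnames = list(NULL, pts))
  mask[10, "RX2"] <- TRUE  # beyond the delay horizon of the single stream
  res <- impute_missing_points(s$model, s$m_ss, mask = mask)
  expect_equal(sum(res$provenance == "imputed"), 1L)
  expect_equal(unname(res$provenance[10, "RX2"]), "imputed")
  # observed cells are bit-identical
  keep <- !mask
  expect_identical(res$completed$values[, pts][keep], s$m_ss$values[, pts][keep])
  expect_false(is.na(res$completed$values[10, "RX2"]))
})

test_that("a fully observed stream passes through unchanged", {
  s <- small_setup()
  res <- impute_missing_points(s$model, s$m_ss)
  expect_true(all(res$provenance %in% c("observed")))
  expect_identical(res$completed$values, s$m_ss$values)
  # held-out one-step metrics are reported per subtype plus pooled
  expect_true("all" %in% res$held_out$scope)
})

test_that("unforecastable rows are flagged and left missing", {
  cfg <- cohort_config(datasets = list(list(dataset_id = "V",
                                            n_subjects = 2L,
                                            rr_mean = 0.8, rr_sd = 0.04)),
                       beats_per_subject = 60,
                       subtype_probs = c(ABEXYOZ0 = 0.6, ABEXYOZ1 = 0.3,
                                         ABEXYOZ2 = 0, ABEXYOZ3 = 0,
                                         ABEXYOZ4 = 0, ABEXYOZ5 = 0,
                                         ABEXYOZu = 0.1),
                       seed = 5)
  gen <- generate_cohort(cfg)
  m <- suppressWarnings(build_interval_matrix(gen$beats))
  imp0 <- impute_missing_means(m)
  m_ss <- normalize_sum_squares(normalize_rr(imp0$matrix))
  model <- model_for_matrix(m_ss)
  pts <- setdiff(ICG_COLUMNS, "RR")
  res <- impute_missing_points(model, m_ss, mask = imp0$mask[, pts])
  u_rows <- m_ss$row_meta$subtype == "ABEXYOZu"
  expect_true(all(res$unforecastable[u_rows]))
  expect_true(all(res$provenance[u_rows, ] == "missing"))
  # forecastable rows end up with no missing cells
  fc <- !res$unforecastable
  expect_true(all(res$provenance[fc, ] != "missing"))
})

test_that("normalization scale mismatch is rejected", {
  s <- small_setup()
  model <- s$model
  model$norm$ss_scale <- model$norm$ss_scale * 2
  expect_error(impute_missing_points(model, s$m_ss), "scale mismatch")
})

test_that("held-out imputation error shrinks with the generator noise", {
  rmse_at <- function(noise) {
    cfg <- cohort_config(datasets = list(list(dataset_id = "V",
                                              n_subjects = 4L,
                                              rr_mean = 0.8, rr_sd = 0.04)),
                        beats_per_subject = 80,
                        noise_sd = noise,
                        subtype_probs = c(ABEXYOZ0 = 0.5, ABEXYOZ1 = 0.5,
                                          ABEXYOZ2 = 0, ABEXYOZ3 = 0,
                                          ABEXYOZ4 = 0, ABEXYOZ5 = 0,
                                          ABEXYOZu = 0),
                        seed = 17)
    res <- run_pipeline(list(seed = 17, cohort = cfg,
                             train = list(max_epochs = 40)))
    truth <- res$truth$values[, setdiff(ICG_COLUMNS, "RR")]
    comp <- res$completed_raw$values[, setdiff(ICG_COLUMNS, "RR")]
    cells <- res$imputation$provenance == "imputed"
    basic_errors(truth[cells], comp[cells])$rmse
  }
  errs <- vapply(c(0.002, 0.02, 0.08), rmse_at, numeric(1))
  expect_true(all(diff(errs) > 0))
})

test_that("X selection takes the argmin with ties going to X2", {
  beats <- rbind(make_beats(12, subject = "s1", subtype = "ABEXYOZ0"),
                 make_beats(12, subject = "s2", subtype = "ABEXYOZ2"))
  m <- suppressWarnings(build_interval_matrix(beats))
  # displace X1 in the atypical scope; X2 stays on its reference
  rows <- m$row_meta$subtype == "ABEXYOZ2"
  m$values[rows, "RX1"] <- m$values[rows, "RX1"] + 0.04 * m$values[rows, "RR"]
  sel <- select_x(m)
  expect_equal(sel$chosen, "X2")
  expect_lt(sel$sd_x2, sel$sd_x1)

  # symmetric displacement flips the winner
  m2 <- suppressWarnings(build_interval_matrix(beats))
  m2$values[rows, "RX2"] <- m2$values[rows, "RX2"] + 0.04 * m2$values[rows, "RR"]
  expect_equal(select_x(m2)$chosen, "X1")

  # exact tie goes to X2, the true X of typical complexes; power-of-two
  # constants make both deviations exactly zero
  m3 <- suppressWarnings(build_interval_matrix(beats))
  m3$values[, "RR"] <- 1
  m3$values[, "RX1"] <- 0.25
  m3$values[, "RX2"] <- 0.5
  expect_equal(select_x(m3)$chosen, "X2")
})

test_that("denormalization reproduces worked arithmetic", {
  beats <- make_beats(3, rr = 0.8)
  m <- suppressWarnings(build_interval_matrix(beats))
  m$values[, "RA"] <- 0.05
  rrn <- normalize_rr(m)
  expect_equal(unname(rrn$values[1, "RA"]), 0.0625)
  back <- denormalize(rrn)
  expect_equal(unname(back$values[1, "RA"]), 0.05)
  expect_error(denormalize(back), "nothing to invert")
})
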