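# Shared AR(1) task: y(t) = 0.9 y(t-1) + noise(sd = 0.01), n = 500.
ar1_task <- function(seed = 21, n = 500, sd = 0.01) {
  with_seed <- icgnarx:::with_seed
  y <- with_seed(seed, {
    out <- numeric(n)
    out[1] <- rnorm(1, sd = sd / sqrt(1 - 0.81))
    for (t in 2:n) out[t] <- 0.9 * out[t - 1] + rnorm(1, sd = sd)
    out
  })
  cfg <- narx_config(n_channels = 1, n_hidden = 5)
  smp <- narx_samples(matrix(y, ncol = 1), cfg)
  list(cfg = cfg, smp = smp, split = split_data(nrow(smp$Y), seed = seed))
}

test_that("Levenberg-Marquardt fits the AR(1) task to the noise floor", {
  task <- ar1_task()
  rep <- narx_train(narx_init(task$cfg, seed = 21), task$smp, task$split,
                    train_options("lm", max_epochs = 60, seed = 21))
  expect_lte(sqrt(utils::tail(rep$trace$train_mse, 1)), 0.02)
  # accepted-step monotonicity: training loss never increases
  expect_true(all(diff(rep$trace$train_mse) <= 1e-12))
})

test_that("early stopping restores the weights of the best validation epoch", {
  # small noisy sample with a large network overfits quickly
  set.seed(7)
  y <- matrix(rnorm(30, sd = 0.5), ncol = 1)
  cfg <- narx_config(n_channels = 1, n_hidden = 10)
  smp <- narx_samples(y, cfg)
  split <- split_data(nrow(smp$Y), seed = 7)
  rep <- narx_train(narx_init(cfg, seed = 7), smp, split,
                    train_options("lm", max_epochs = 400, max_fail = 6,
                                  seed = 7))
  if (rep$stop_reason == "val_fail") {
    expect_equal(rep$best_epoch, which.min(rep$trace$val_mse))
    returned_val <- icgnarx:::mse_of(
      icgnarx:::pack_weights(rep$model$weights), cfg,
      icgnarx:::sub_samples(smp, split$val))
    expect_equal(returned_val, min(rep$trace$val_mse), tolerance = 1e-12)
    # patience rule: exactly max_fail non-improving epochs after the best
    expect_equal(nrow(rep$trace), rep$best_epoch + 6L)
  } else {
    succeed("training did not overfit under this seed; patience not exercised")
  }
})

test_that("scaled conjugate gradient reaches the AR(1) noise floor", {
  task <- ar1_task()
  rep <- narx_train(narx_init(task$cfg, seed = 21), task$smp, task$split,
                    train_options("scg", max_epochs = 300, max_fail = 25,
                                  seed = 21))
  best <- sqrt(min(rep$trace$train_mse))
  expect_lte(best, 0.03)
})

test_that("the SCG core minimizes a quadratic and stops on a zero gradient", {
  # f(w) = 0.5 w' A w - b' w with A symmetric positive definite
  set.seed(5)
  n <- 12
  M <- matrix(rnorm(n * n), n)
  A <- crossprod(M) + diag(n)
  b <- rnorm(n)
  fn <- function(w) list(loss = 0.5 * sum(w * (A %*% w)) - sum(b * w),
                         grad = as.vector(A %*% w - b))
  res <- icgnarx:::scg_core(rep(0, n), fn, max_iter = 3L * n,
                            grad_tol = 1e-6)
  w_star <- solve(A, b)
  expect_lt(max(abs(res$w - w_star)), 1e-4)
  # starting at the minimizer: immediate stop with zero iterations
  res0 <- icgnarx:::scg_core(w_star, fn, max_iter = 10, grad_tol = 1e-6)
  expect_equal(res0$iters, 0L)
  expect_equal(res0$reason, "grad_zero")
})

test_that("Bayesian regularization fits the task and shrinks the weights", {
  task <- ar1_task()
  rep_br <- narx_train(narx_init(task$cfg, seed = 21), task$smp, task$split,
                       train_options("br", max_epochs = 60, seed = 21))
  expect_lte(sqrt(utils::tail(rep_br$trace$train_mse, 1)), 0.03)

  # weight norm at most that of unregularized LM, on the same noisy task,
  # as a statistical property over several seeds
  norms <- vapply(1:5, function(s) {
    t2 <- ar1_task(seed = 100 + s, n = 120, sd = 0.05)
    lm <- narx_train(narx_init(t2$cfg, seed = s), t2$smp, t2$split,
                     train_options("lm", max_epochs = 40, seed = s))
    br <- narx_train(narx_init(t2$cfg, seed = s), t2$smp, t2$split,
                     train_options("br", max_epochs = 40, seed = s))
    c(lm = sum(icgnarx:::pack_weights(lm$model$weights)^2),
      br = sum(icgnarx:::pack_weights(br$model$weights)^2))
  }, numeric(2))
  expect_lt(mean(norms["br", ]), mean(norms["lm", ]))
})

test_that("a pure-noise target drives the regularizer toward zero weights", {
  set.seed(9)
  y <- matrix(rnorm(120), ncol = 1)
  cfg <- narx_config(n_channels = 1, n_hidden = 4)
  smp <- narx_samples(y, cfg)
  split <- split_data(nrow(smp$Y), seed = 9)
  init <- narx_init(cfg, seed = 9)
  rep <- narx_train(init, smp, split,
                    train_options("br", max_epochs = 60, seed = 9))
  w0 <- sum(icgnarx:::pack_weights(init$weights)^2)
  w1 <- sum(icgnarx:::pack_weights(rep$model$weights)^2)
  expect_lt(w1, 0.5 * w0)
  # the evidence update keeps raising the decay strength on pure noise
  alpha_trace <- rep$trace$alpha
  expect_true(is.finite(utils::tail(alpha_trace, 1)))
  expect_gt(utils::tail(alpha_trace, 1), alpha_trace[1])
})

test_that("Bayesian regularization with alpha fixed at zero is plain LM", {
  task <- ar1_task(seed = 33, n = 150)
  lm <- narx_train(narx_init(task$cfg, seed = 33), task$smp, task$split,
                   train_options("lm", max_epochs = 25, seed = 33))
  br <- narx_train(narx_init(task$cfg, seed = 33), task$smp, task$split,
                   train_options("br", max_epochs = 25, seed = 33,
                                 alpha_fixed = 0, use_validation = TRUE))
  expect_equal(br$trace$train_mse, lm$trace$train_mse, tolerance = 1e-12)
  expect_equal(icgnarx:::pack_weights(br$model$weights),
               icgnarx:::pack_weights(lm$model$weights), tolerance = 1e-12)
})

test_that("algorithm comparison ranks by VEcv then RMSE and is reproducible", {
  task <- ar1_task(seed = 44, n = 200)
  opts <- list(train_options("lm", max_epochs = 25, seed = 44),
               train_options("scg", max_epochs = 60, seed = 44),
               train_options("br", max_epochs = 25, seed = 44))
  tab1 <- compare_algorithms(task$cfg, task$smp, task$split, opts)
  tab2 <- compare_algorithms(task$cfg, task$smp, task$split, opts)
  expect_identical(tab1, tab2)
  expect_equal(sort(tab1$rank), 1:3)
  expect_true(all(diff(tab1$vecv) <= 1e-12))

  # single algorithm trivially ranks first
  solo <- compare_algorithms(task$cfg, task$smp, task$split, opts[1])
  expect_equal(solo$rank, 1L)

  # identical entries tie; declaration order breaks the tie
  twin <- compare_algorithms(task$cfg, task$smp, task$split,
                             list(opts[[1]], opts[[1]]))
  expect_equal(twin$rank, 1:2)
})
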