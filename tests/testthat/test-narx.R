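test_that("initialization is seeded, shaped and bounded", {
  cfg <- narx_config()
  m1 <- narx_init(cfg, seed = 4)
  m2 <- narx_init(cfg, seed = 4)
  expect_identical(m1$weights, m2$weights)
  expect_false(identical(m1$weights, narx_init(cfg, seed = 5)$weights))
  expect_equal(dim(m1$weights$W_x), c(10L, 16L))
  expect_equal(dim(m1$weights$W_y), c(10L, 16L))
  expect_equal(dim(m1$weights$W_o), c(8L, 10L))
  expect_length(m1$weights$b_h, 10L)

  # hidden activations are bounded by the hyperbolic tangent
  y <- matrix(rnorm(80, sd = 10), 10, 8)
  smp <- narx_samples(y, cfg)
  H <- icgnarx:::narx_eval(m1$weights, smp$Xx, smp$Xy)$H
  expect_true(all(abs(H) <= 1))
})

test_that("a zero network outputs its output bias everywhere", {
  model <- toy_model(0, 0, 0, 0, 0, 0, d_out = 0.7)
  y <- matrix(seq(0.1, 1, length.out = 10), ncol = 1)
  open <- narx_forward_open(model, y)
  expect_true(all(is.na(open[1:2, ])))
  expect_equal(unname(open[3:10, 1]), rep(0.7, 8))
  closed <- narx_forward_closed(model, y, y_init = y[1:2, , drop = FALSE])
  expect_equal(unname(closed[3:10, 1]), rep(0.7, 8))
})

test_that("open-loop output matches the hand-computed two-tap recursion", {
  a1 <- 0.3; a2 <- -0.2; b1 <- 0.5; b2 <- 0.1
  bh <- 0.05; c_out <- 1.2; d_out <- -0.1
  model <- toy_model(a1, a2, b1, b2, bh, c_out, d_out)
  y <- matrix(c(0.2, -0.4, 0.1, 0.6, -0.3), ncol = 1)
  pred <- narx_forward_open(model, y)
  # hand evaluation of y_hat(t) = c*tanh((a1+b1) y(t-1) + (a2+b2) y(t-2) + bh) + d
  for (t in 3:5) {
    expected <- c_out * tanh(a1 * y[t - 1] + a2 * y[t - 2] +
                             b1 * y[t - 1] + b2 * y[t - 2] + bh) + d_out
    expect_equal(pred[t, 1], expected, tolerance = 1e-14)
  }
  expect_true(all(is.na(pred[1:2, ])))
  expect_error(narx_forward_open(model, y[1:2, , drop = FALSE]), "delay")
})

test_that("constant series give constant predictions beyond the horizon", {
  model <- toy_model()
  y <- matrix(rep(0.4, 12), ncol = 1)
  pred <- narx_forward_open(model, y)
  expect_equal(length(unique(round(pred[3:12, 1], 12))), 1L)
})

test_that("closed loop equals open loop when fed the true history", {
  model <- toy_model()
  set.seed(1)
  y <- matrix(rnorm(15, sd = 0.3), ncol = 1)
  open <- narx_forward_open(model, y)
  closed <- narx_forward_closed(model, y, y_init = y[1:2, , drop = FALSE])
  # first closed-loop step still reads true history: identical to open loop
  expect_equal(closed[3, 1], open[3, 1], tolerance = 1e-14)
  # the hybrid loop with a fully observed stream reproduces open loop exactly
  hb <- narx_forecast_hybrid(model, y)
  expect_equal(hb$pred[3:15, , drop = FALSE], open[3:15, , drop = FALSE],
               tolerance = 1e-14)
  expect_error(narx_forward_closed(model, y, y_init = y[1:3, , drop = FALSE]),
               "seed values")
})

test_that("closed loop tracks the analytic AR(2) recursion on a linear net", {
  # one hidden unit operating in the near-linear region of tanh implements
  # y(t) = phi1 y(t-1) + phi2 y(t-2) up to O(eps^2)
  phi1 <- 0.5; phi2 <- -0.3; eps <- 1e-4
  model <- toy_model(a1 = 0, a2 = 0, b1 = eps * phi1, b2 = eps * phi2,
                     bh = 0, c_out = 1 / eps, d_out = 0)
  y0 <- c(0.8, -0.5)
  n <- 40
  analytic <- numeric(n)
  analytic[1:2] <- y0
  for (t in 3:n) {
    analytic[t] <- phi1 * analytic[t - 1] + phi2 * analytic[t - 2]
  }
  x <- matrix(0, n, 1)  # exogenous taps are zero-weighted
  closed <- narx_forward_closed(model, x, y_init = matrix(y0, 2, 1))
  expect_lt(max(abs(closed[3:n, 1] - analytic[3:n])), 1e-3)
})

test_that("delay removal shifts outputs by one sample and keeps weights", {
  model <- toy_model()
  set.seed(2)
  y <- matrix(rnorm(20, sd = 0.3), ncol = 1)
  removed <- narx_remove_delay(model)
  expect_identical(removed$weights, model$weights)
  orig <- narx_forward_open(model, y)
  adv <- narx_forward_open(removed, y)
  # removed-delay output at t equals original output at t + 1
  expect_equal(adv[2:19, 1], orig[3:20, 1], tolerance = 1e-14)
  expect_error(narx_remove_delay(removed), "already removed")
  expect_error(narx_forward_closed(removed, y, y[1:2, , drop = FALSE]),
               "feedback delay")
})

test_that("analytic Jacobian matches central finite differences", {
  set.seed(11)
  for (case in list(c(ch = 1, h = 2, n = 8), c(ch = 3, h = 4, n = 10),
                    c(ch = 2, h = 1, n = 12))) {
    cfg <- narx_config(n_channels = case[["ch"]], n_hidden = case[["h"]])
    model <- narx_init(cfg, seed = case[["n"]], method = "uniform")
    y <- matrix(rnorm(case[["n"]] * case[["ch"]]), case[["n"]], case[["ch"]])
    smp <- narx_samples(y, cfg)
    jac <- narx_jacobian(model, smp)
    w0 <- icgnarx:::pack_weights(model$weights)
    h_eps <- 1e-6
    num <- vapply(seq_along(w0), function(i) {
      wp <- w0; wp[i] <- wp[i] + h_eps
      wm <- w0; wm[i] <- wm[i] - h_eps
      ep <- icgnarx:::narx_residuals(icgnarx:::unpack_weights(wp, cfg),
                                     smp$Xx, smp$Xy, smp$Y)$e
      em <- icgnarx:::narx_residuals(icgnarx:::unpack_weights(wm, cfg),
                                     smp$Xx, smp$Xy, smp$Y)$e
      (ep - em) / (2 * h_eps)
    }, numeric(nrow(jac$J)))
    rel_err <- max(abs(num - jac$J)) / max(abs(jac$J))
    expect_lt(rel_err, 1e-5)
  }
})

test_that("gradient end cases follow the chain rule", {
  cfg <- narx_config(n_channels = 2, n_hidden = 3)
  model <- narx_init(cfg, seed = 3)
  set.seed(3)
  y <- matrix(rnorm(20), 10, 2)
  smp <- narx_samples(y, cfg)
  jac <- narx_jacobian(model, smp)
  # output-weight columns of the Jacobian are the hidden activations
  H <- icgnarx:::narx_eval(model$weights, smp$Xx, smp$Xy)$H
  o3 <- 3 * (4 + 4) + 3  # offset of the W_o block in the packing
  rows_k1 <- seq(1, nrow(jac$J), by = 2)
  expect_equal(jac$J[rows_k1, o3 + 1:3], H, tolerance = 1e-14,
               ignore_attr = TRUE)
  # zero residuals give a zero gradient of the sum-of-squares loss
  smp0 <- smp
  smp0$Y <- jac$pred
  g <- icgnarx:::narx_loss_grad(icgnarx:::pack_weights(model$weights), cfg,
                                smp0$Xx, smp0$Xy, smp0$Y)
  expect_equal(max(abs(g$grad)), 0)
  # and the backprop gradient equals J' e in general
  g1 <- icgnarx:::narx_loss_grad(icgnarx:::pack_weights(model$weights), cfg,
                                 smp$Xx, smp$Xy, smp$Y)
  expect_equal(g1$grad, as.vector(crossprod(jac$J, jac$residuals)),
               tolerance = 1e-12)
})

test_that("models persist through JSON round trip", {
  model <- narx_init(narx_config(), seed = 8)
  model$norm <- list(ss_scale = stats::setNames(runif(8, 0.5, 2),
                                                paste0("R", ICG_POINTS)),
                     col_means = stats::setNames(runif(8),
                                                 paste0("R", ICG_POINTS)))
  path <- withr::local_tempfile(fileext = ".json")
  narx_save(model, path)
  back <- narx_load(path)
  expect_equal(back$weights, model$weights, tolerance = 1e-12)
  expect_equal(back$norm$ss_scale, model$norm$ss_scale, tolerance = 1e-12)
  expect_equal(back$config, model$config)
})
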