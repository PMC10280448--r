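# Open-loop training of the NARX network by Levenberg-Marquardt, scaled
# conjugate gradient (Moller) or Bayesian regularization (MacKay evidence
# updates on the LM engine), with validation-based early stopping.

#' Training options
#'
#' Defaults follow the customary full-batch settings of this architecture
#' family: up to 1000 epochs, validation patience of 6 epochs, damping
#' schedule mu0 = 1e-3 multiplied by 10 on a rejected step and by 0.1 on an
#' accepted one. Bayesian regularization disables validation stopping by
#' default (the evidence term replaces it); pass `use_validation = TRUE` to
#' re-enable.
#'
#' @param algorithm `"lm"` (Levenberg-Marquardt), `"scg"` (scaled conjugate
#'   gradient) or `"br"` (Bayesian regularization).
#' @param max_epochs maximum number of epochs (>= 1).
#' @param max_fail consecutive validation-loss increases tolerated before
#'   stopping.
#' @param mu0,mu_inc,mu_dec LM damping: initial value, rejection multiplier
#'   (> 1) and acceptance multiplier (in (0, 1)).
#' @param goal stop when training MSE drops to this value.
#' @param seed integer seed controlling weight initialization and any
#'   training randomness.
#' @param use_validation logical; default TRUE except for `"br"`.
#' @param alpha0,beta0 initial regularization and noise precision for `"br"`.
#' @param alpha_fixed if non-NULL, `"br"` keeps alpha fixed at this value
#'   (0 reduces BR to the plain LM trajectory).
#' @return Object of class `train_options`.
#' @export
train_options <- function(algorithm = c("lm", "scg", "br"),
                          max_epochs = 1000L, max_fail = 6L,
                          mu0 = 1e-3, mu_inc = 10, mu_dec = 0.1,
                          goal = 0, seed = 1L, use_validation = NULL,
                          alpha0 = 0, beta0 = 1, alpha_fixed = NULL) {
  algorithm <- match.arg(algorithm)
  if (max_epochs < 1L) stop("max_epochs must be >= 1")
  if (mu0 <= 0) stop("mu0 must be positive")
  if (!(mu_dec > 0 && mu_dec < 1 && mu_inc > 1)) {
    stop("need 0 < mu_dec < 1 < mu_inc")
  }
  if (is.null(use_validation)) use_validation <- algorithm != "br"
  structure(list(algorithm = algorithm, max_epochs = as.integer(max_epochs),
                 max_fail = as.integer(max_fail), mu0 = mu0, mu_inc = mu_inc,
                 mu_dec = mu_dec, goal = goal, seed = as.integer(seed),
                 use_validation = isTRUE(use_validation),
                 alpha0 = alpha0, beta0 = beta0, alpha_fixed = alpha_fixed),
            class = "train_options")
}

sub_samples <- function(s, idx) {
  list(Xx = s$Xx[idx, , drop = FALSE], Xy = s$Xy[idx, , drop = FALSE],
       Y = s$Y[idx, , drop = FALSE])
}

mse_of <- function(wvec, cfg, s) {
  if (nrow(s$Y) == 0L) return(NA_real_)
  w <- unpack_weights(wvec, cfg)
  fp <- narx_eval(w, s$Xx, s$Xy)
  mean((fp$pred - s$Y)^2)
}

new_train_report <- function(model, wvec, trace, stop_reason, best_epoch,
                             opts) {
  model$weights <- unpack_weights(wvec, model$config)
  structure(list(model = model,
                 trace = do.call(rbind, trace),
                 stop_reason = stop_reason,
                 best_epoch = best_epoch,
                 algorithm = opts$algorithm,
                 seed = opts$seed),
            class = "narx_train_report")
}

#' @export
print.narx_train_report <- function(x, ...) {
  n <- nrow(x$trace)
  cat("<narx_train_report> ", x$algorithm, ", ", n, " epochs, stopped: ",
      x$stop_reason, ", best epoch ", x$best_epoch, "\n", sep = "")
  if (n > 0L) {
    last <- x$trace[n, ]
    cat(sprintf("  final train MSE %.3g; val MSE %.3g\n",
                last$train_mse, last$val_mse))
  }
  invisible(x)
}

# Shared Levenberg-Marquardt engine. With bayes = FALSE it minimizes the sum
# of squared residuals; with bayes = TRUE it minimizes
# F = beta * SSE/2 + alpha * |w|^2 / 2 and re-estimates (alpha, beta) each
# epoch from the effective number of parameters
# gamma = N_w - alpha * tr((beta J'J + alpha I)^-1).
lm_engine <- function(model, samples, split, opts, bayes) {
  cfg <- model$config
  wvec <- pack_weights(model$weights)
  Nw <- length(wvec)
  tr <- sub_samples(samples, split$train)
  va <- sub_samples(samples, split$val)
  te <- sub_samples(samples, split$test)
  n_obs <- nrow(tr$Y) * ncol(tr$Y)
  mu <- opts$mu0
  alpha <- if (bayes) (opts$alpha_fixed %||% opts$alpha0) else 0
  beta <- if (bayes) opts$beta0 else 1
  use_val <- opts$use_validation && nrow(va$Y) > 0L
  best <- list(val = Inf, epoch = 0L, wvec = wvec)
  fails <- 0L
  trace <- list()
  stop_reason <- "max_epochs"
  tmp_model <- model
  for (epoch in seq_len(opts$max_epochs)) {
    tmp_model$weights <- unpack_weights(wvec, cfg)
    jac <- narx_jacobian(tmp_model, tr)
    e <- jac$residuals
    sse <- sum(e^2)
    obj <- beta * sse / 2 + alpha * sum(wvec^2) / 2
    g <- beta * as.vector(crossprod(jac$J, e)) + alpha * wvec
    A <- beta * crossprod(jac$J)
    accepted <- FALSE
    repeat {
      step <- tryCatch(solve(A + diag(alpha + mu, Nw), g),
                       error = function(err) NULL)
      if (!is.null(step)) {
        cand <- wvec - as.vector(step)
        w_cand <- unpack_weights(cand, cfg)
        fp <- narx_eval(w_cand, tr$Xx, tr$Xy)
        csse <- sum((fp$pred - tr$Y)^2)
        cobj <- beta * csse / 2 + alpha * sum(cand^2) / 2
        if (is.finite(cobj) && cobj < obj) {
          wvec <- cand
          sse <- csse
          mu <- max(mu * opts$mu_dec, 1e-20)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * opts$mu_inc
      if (mu > 1e10) break
    }
    if (!accepted) {
      stop_reason <- "mu_overflow"
      break
    }
    if (bayes && is.null(opts$alpha_fixed)) {
      Hinv <- tryCatch(solve(A + diag(alpha + 1e-12, Nw)),
                       error = function(err) NULL)
      if (!is.null(Hinv)) {
        gamma <- Nw - alpha * sum(diag(Hinv))
        if (gamma < 0 || gamma > Nw) {
          warning("effective parameter count clamped to [0, N_w]")
          gamma <- min(max(gamma, 0), Nw)
        }
        ew <- sum(wvec^2) / 2
        alpha <- gamma / max(2 * ew, 1e-12)
        beta <- max(n_obs - gamma, 1e-12) / max(sse, 1e-12)
      }
    }
    train_mse <- sse / n_obs
    val_mse <- mse_of(wvec, cfg, va)
    test_mse <- mse_of(wvec, cfg, te)
    trace[[epoch]] <- data.frame(epoch = epoch, train_mse = train_mse,
                                 val_mse = val_mse, test_mse = test_mse,
                                 mu = mu, alpha = alpha, beta = beta)
    if (use_val) {
      if (val_mse < best$val) {
        best <- list(val = val_mse, epoch = epoch, wvec = wvec)
        fails <- 0L
      } else {
        fails <- fails + 1L
        if (fails >= opts$max_fail) {
          stop_reason <- "val_fail"
          break
        }
      }
    } else {
      best <- list(val = val_mse, epoch = epoch, wvec = wvec)
    }
    if (train_mse <= opts$goal) {
      stop_reason <- "goal"
      break
    }
  }
  final <- if (use_val && best$epoch > 0L) best$wvec else wvec
  best_epoch <- if (use_val && best$epoch > 0L) best$epoch else length(trace)
  new_train_report(model, final, trace, stop_reason, best_epoch, opts)
}

# Moller's scaled conjugate gradient on a generic loss/gradient function.
# `fn(w)` returns list(loss, grad); `on_success(k, w, loss)` is called after
# every accepted update and may return TRUE to stop.
scg_core <- function(w, fn, max_iter = 1000L, grad_tol = 1e-10,
                     sigma0 = 5e-5, on_success = NULL) {
  fg <- fn(w)
  f <- fg$loss
  g <- fg$grad
  if (!is.finite(f)) stop("non-finite loss at the starting point")
  r <- -g
  p <- r
  if (sqrt(sum(r^2)) <= grad_tol) {
    return(list(w = w, loss = f, iters = 0L, reason = "grad_zero"))
  }
  lambda <- 5e-7
  lambda_bar <- 0
  success <- TRUE
  Nw <- length(w)
  delta <- 0
  reason <- "max_iter"
  k <- 0L
  successes <- 0L
  while (k < max_iter) {
    k <- k + 1L
    p2 <- sum(p^2)
    if (p2 == 0) {
      reason <- "grad_zero"
      break
    }
    if (success) {
      sigma <- sigma0 / sqrt(p2)
      s <- (fn(w + sigma * p)$grad - g) / sigma
      delta <- sum(p * s)
    }
    delta_k <- delta + (lambda - lambda_bar) * p2
    if (delta_k <= 0) {
      lambda_bar <- 2 * (lambda - delta_k / p2)
      delta_k <- -delta_k + lambda * p2
      lambda <- lambda_bar
    }
    mu_ <- sum(p * r)
    alpha <- mu_ / delta_k
    cand <- w + alpha * p
    fg_new <- fn(cand)
    if (!is.finite(fg_new$loss)) stop("non-finite loss during line search")
    Delta <- 2 * delta_k * (f - fg_new$loss) / mu_^2
    if (Delta >= 0) {
      w <- cand
      f <- fg_new$loss
      g_new <- fg_new$grad
      r_new <- -g_new
      lambda_bar <- 0
      success <- TRUE
      successes <- successes + 1L
      if (successes %% Nw == 0L) {
        p <- r_new
      } else {
        beta_ <- (sum(r_new^2) - sum(r_new * r)) / mu_
        p <- r_new + beta_ * p
      }
      r <- r_new
      g <- g_new
      if (Delta >= 0.75) lambda <- lambda / 4
      if (!is.null(on_success) && isTRUE(on_success(successes, w, f))) {
        reason <- "callback"
        break
      }
      if (sqrt(sum(r^2)) <= grad_tol) {
        reason <- "grad_zero"
        break
      }
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (Delta < 0.25) lambda <- lambda + delta_k * (1 - Delta) / p2
    if (lambda > 1e15) {
      reason <- "lambda_overflow"
      break
    }
  }
  list(w = w, loss = f, iters = successes, reason = reason)
}

scg_trainer <- function(model, samples, split, opts) {
  cfg <- model$config
  tr <- sub_samples(samples, split$train)
  va <- sub_samples(samples, split$val)
  te <- sub_samples(samples, split$test)
  n_obs <- nrow(tr$Y) * ncol(tr$Y)
  use_val <- opts$use_validation && nrow(va$Y) > 0L
  state <- new.env(parent = emptyenv())
  state$trace <- list()
  state$best <- list(val = Inf, epoch = 0L, wvec = NULL)
  state$fails <- 0L
  state$stop_reason <- NULL
  on_success <- function(epoch, w, loss) {
    if (epoch > opts$max_epochs) {
      state$stop_reason <- "max_epochs"
      return(TRUE)
    }
    train_mse <- 2 * loss / n_obs
    val_mse <- mse_of(w, cfg, va)
    test_mse <- mse_of(w, cfg, te)
    state$trace[[epoch]] <- data.frame(epoch = epoch, train_mse = train_mse,
                                       val_mse = val_mse, test_mse = test_mse,
                                       mu = NA_real_, alpha = NA_real_,
                                       beta = NA_real_)
    if (use_val) {
      if (val_mse < state$best$val) {
        state$best <- list(val = val_mse, epoch = epoch, wvec = w)
        state$fails <- 0L
      } else {
        state$fails <- state$fails + 1L
        if (state$fails >= opts$max_fail) {
          state$stop_reason <- "val_fail"
          return(TRUE)
        }
      }
    } else {
      state$best <- list(val = val_mse, epoch = epoch, wvec = w)
    }
    if (train_mse <= opts$goal) {
      state$stop_reason <- "goal"
      return(TRUE)
    }
    FALSE
  }
  res <- scg_core(pack_weights(model$weights),
                  function(w) narx_loss_grad(w, cfg, tr$Xx, tr$Xy, tr$Y),
                  max_iter = 50L * opts$max_epochs,
                  on_success = on_success)
  stop_reason <- state$stop_reason %||%
    (if (res$reason == "grad_zero") "goal" else "max_epochs")
  final <- if (use_val && state$best$epoch > 0L) state$best$wvec else res$w
  best_epoch <- if (use_val && state$best$epoch > 0L) state$best$epoch
                else length(state$trace)
  new_train_report(model, final, state$trace, stop_reason, best_epoch, opts)
}

#' Train a NARX model open-loop
#'
#' Full-batch teacher-forced training of the network on pre-built tap
#' samples, under one of three algorithms: Levenberg-Marquardt (damped
#' Gauss-Newton on the exact residual Jacobian), Moller's scaled conjugate
#' gradient (gradient-only, low memory), or Bayesian regularization
#' (Levenberg-Marquardt on the regularized objective with MacKay evidence
#' re-estimation of the weight-decay and noise precisions each epoch).
#' Training stops at `max_epochs`, at the loss `goal`, when the validation
#' loss fails to improve `max_fail` epochs in a row (weights are restored
#' from the best validation epoch), or when the LM damping overflows.
#'
#' @param model initialized `narx_model`.
#' @param samples tap samples from [narx_samples()].
#' @param split `split_indices` over the sample rows.
#' @param opts a [train_options()].
#' @return `narx_train_report` with the fitted `model`, the per-epoch loss
#'   `trace`, `stop_reason` and `best_epoch`.
#' @export
narx_train <- function(model, samples, split, opts = train_options()) {
  switch(opts$algorithm,
         lm = lm_engine(model, samples, split, opts, bayes = FALSE),
         scg = scg_trainer(model, samples, split, opts),
         br = lm_engine(model, samples, split, opts, bayes = TRUE))
}

#' Train and rank several algorithms on identical splits
#'
#' Trains one model per option set from identically seeded initial weights,
#' evaluates each on the common test partition, and ranks primarily by higher
#' VEcv, breaking ties by lower RMSE and then by declaration order. A failed
#' training is ranked last with a failure note.
#'
#' @param cfg a [narx_config()].
#' @param samples tap samples from [narx_samples()].
#' @param split common `split_indices`.
#' @param opts_list list of [train_options()] (>= 1).
#' @return Data frame with one row per algorithm: test-set VEcv, MSE, RMSE,
#'   MAE, Pearson R, rank, and a note column.
#' @export
compare_algorithms <- function(cfg, samples, split, opts_list) {
  if (length(opts_list) < 1L) stop("need at least one option set")
  te <- sub_samples(samples, split$test)
  rows <- lapply(seq_along(opts_list), function(i) {
    opts <- opts_list[[i]]
    res <- tryCatch({
      model <- narx_init(cfg, seed = opts$seed)
      rep <- narx_train(model, samples, split, opts)
      fp <- narx_eval(rep$model$weights, te$Xx, te$Xy)
      err <- basic_errors(te$Y, fp$pred)
      data.frame(algorithm = opts$algorithm,
                 vecv = vecv(te$Y, fp$pred),
                 mse = err$mse, rmse = err$rmse, mae = err$mae,
                 r = pearson_r(te$Y, fp$pred),
                 note = "", stringsAsFactors = FALSE)
    }, error = function(err) {
      data.frame(algorithm = opts$algorithm, vecv = -Inf, mse = Inf,
                 rmse = Inf, mae = Inf, r = NA_real_,
                 note = paste("training failed:", conditionMessage(err)),
                 stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$vecv, out$rmse, seq_len(nrow(out)))
  out$rank <- NA_integer_
  out$rank[ord] <- seq_len(nrow(out))
  out[ord, c("rank", "algorithm", "vecv", "mse", "rmse", "mae", "r", "note")]
}
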