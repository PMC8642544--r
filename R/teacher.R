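#' Initialise a non-spiking tanh rate network
#'
#' The teacher dynamical system
#' \deqn{\tau_j \dot x_j = -x_j + (F c)_j + (\Omega \tanh(x))_j + b_j,
#'       \quad y = D x}
#' with per-unit time constants initialised linearly spaced over
#' `tau_range` (default 10--100 ms).  Input weights are drawn
#' `N(0, 1/sqrt(d1))`, recurrent weights `N(0, g/sqrt(N))` with gain
#' `g = 1.2` (slightly supercritical, giving the rich initial dynamics a
#' temporal-memory task needs),
#' biases at zero, and the fixed readout `D` has entries `N(0, 1/sqrt(N))`
#' so that unit-scale states map to unit-scale outputs.  No noise is
#' applied during training or inference.
#'
#' @param n_units number of rate units.
#' @param n_in input dimensionality `d1`.
#' @param n_out output dimensionality `d2`.
#' @param dt simulation step (s).
#' @param tau_range range (s) over which unit time constants are linearly
#'   spaced.
#' @param gain initial recurrent gain.
#' @return an object of class `rate_network` with fields `tau`, `F`,
#'   `Omega`, `b`, `D`, `dt` and sizes.
#' @export
rate_network <- function(n_units = 64, n_in = 1, n_out = 1, dt = 0.001,
                         tau_range = c(0.01, 0.1), gain = 1.2) {
  stopifnot(n_units >= 1, n_in >= 1, n_out >= 1, dt > 0,
            length(tau_range) == 2, all(tau_range > 0))
  structure(list(
    n_units = as.integer(n_units), n_in = as.integer(n_in),
    n_out = as.integer(n_out), dt = dt,
    tau = seq(tau_range[1], tau_range[2], length.out = n_units),
    F = matrix(stats::rnorm(n_units * n_in, sd = 1 / sqrt(n_in)), n_units, n_in),
    Omega = matrix(stats::rnorm(n_units^2, sd = gain / sqrt(n_units)), n_units, n_units),
    b = numeric(n_units),
    D = matrix(stats::rnorm(n_out * n_units, sd = 1 / sqrt(n_units)), n_out, n_units)
  ), class = "rate_network")
}

#' @export
print.rate_network <- function(x, ...) {
  cat(sprintf("<rate_network> %d units, %d -> %d, dt = %g s, tau in [%g, %g] s\n",
              x$n_units, x$n_in, x$n_out, x$dt, min(x$tau), max(x$tau)))
  invisible(x)
}

#' One forward-Euler step of the rate network
#'
#' @param x state vector (length `n_units`).
#' @param c_in input vector (length `n_in`).
#' @param params a `rate_network`.
#' @return updated state vector.
#' @export
rnn_step <- function(x, c_in, params) {
  if (any(!is.finite(x))) stop("non-finite rate-network state")
  drive <- -x + drop(params$F %*% c_in) + drop(params$Omega %*% tanh(x)) + params$b
  x + params$dt / params$tau * drive
}

#' Simulate the rate network over an input time series
#'
#' Runs the same Euler discretisation as the training path and returns the
#' full state trajectory `x_hat` along with the instantaneous linear
#' readout `y_hat = D x_hat`.
#'
#' @param params a `rate_network`.
#' @param c_in input `time_series` (`n_in` channels) sampled at the network
#'   `dt`.
#' @param x0 initial state (default zero).
#' @param bound divergence bound on `max |x|`; exceeding it is an error
#'   naming the step.
#' @return list of class `teacher_trajectory` with `x_hat`, `y_hat`
#'   (`time_series`) and the `input`.
#' @export
simulate_rnn <- function(params, c_in, x0 = NULL, bound = 1e6) {
  stopifnot(inherits(c_in, "time_series"))
  if (abs(c_in$dt - params$dt) > 1e-12) {
    stop("input dt does not match the network simulation dt")
  }
  if (nrow(c_in$values) != params$n_in) stop("input channel count mismatch")
  if (is.null(x0)) x0 <- numeric(params$n_units)
  out <- cpp_simulate_rnn(params$tau, params$F, params$Omega, params$b,
                          params$D, c_in$values, x0, params$dt, bound)
  structure(list(x_hat = time_series(out$X, dt = params$dt),
                 y_hat = time_series(out$Y, dt = params$dt),
                 input = c_in),
            class = "teacher_trajectory")
}

# Pack a list of samples into input/target cubes (d x B x T arrays).
samples_to_cubes <- function(samples) {
  B <- length(samples)
  d1 <- nrow(samples[[1]]$input$values)
  d2 <- nrow(samples[[1]]$target$values)
  T <- ncol(samples[[1]]$input$values)
  C <- array(0, c(d1, B, T))
  Y <- array(0, c(d2, B, T))
  for (i in seq_len(B)) {
    C[, i, ] <- samples[[i]]$input$values
    Y[, i, ] <- samples[[i]]$target$values
  }
  list(C = C, Y = Y)
}

adam_new <- function(par) list(m = lapply(par, function(p) p * 0),
                               v = lapply(par, function(p) p * 0), t = 0)

adam_update <- function(opt, par, grad, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  opt$t <- opt$t + 1
  for (nm in names(par)) {
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * grad[[nm]]
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(opt = opt, par = par)
}

#' Train the rate network by backpropagation through time
#'
#' Minimises the mean squared error of the readout against the target
#' signal over the Euler-discretised dynamics, using Adam.  Trainable
#' parameters are the time constants `tau`, input weights `F`, recurrent
#' weights `Omega` and biases `b`; the readout `D` is fixed.  Time
#' constants are clipped at 1 ms after each update.
#'
#' @param task_sampler function `f(n)` returning a list of `n` samples,
#'   each a list with `input` and `target` `time_series` (see e.g.
#'   [xor_task_sampler()]).
#' @param params initial `rate_network`.
#' @param epochs number of training epochs; 0 returns `params` unchanged.
#' @param samples_per_epoch samples drawn per epoch.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param verbose print per-epoch smoothed loss.
#' @return list with the trained `params` and a data frame `loss_trace`
#'   (per-batch loss and its running exponential smoothing).
#' @export
train_rnn <- function(task_sampler, params, epochs = 20,
                      samples_per_epoch = 500, batch_size = 10, lr = 5e-3,
                      verbose = FALSE) {
  stopifnot(epochs >= 0)
  trace <- data.frame(epoch = integer(), batch = integer(),
                      loss = numeric(), smoothed = numeric())
  if (epochs == 0) return(list(params = params, loss_trace = trace))
  trainable <- c("tau", "F", "Omega", "b")
  opt <- adam_new(params[trainable])
  smoothed <- NA_real_
  for (ep in seq_len(epochs)) {
    samples <- task_sampler(samples_per_epoch)
    idx <- split(seq_len(samples_per_epoch),
                 ceiling(seq_len(samples_per_epoch) / batch_size))
    for (bi in seq_along(idx)) {
      cubes <- samples_to_cubes(samples[idx[[bi]]])
      g <- cpp_rnn_loss_grad(params$tau, params$F, params$Omega, params$b,
                             params$D, cubes$C, cubes$Y, params$dt)
      if (!is.finite(g$loss)) {
        stop(sprintf("non-finite training loss at epoch %d", ep))
      }
      upd <- adam_update(opt, params[trainable],
                         list(tau = g$dtau, F = g$dF, Omega = g$dOmega, b = g$db),
                         lr = lr)
      opt <- upd$opt
      params[trainable] <- upd$par
      params$tau <- pmax(as.numeric(params$tau), 0.001)
      params$b <- as.numeric(params$b)
      smoothed <- if (is.na(smoothed)) g$loss else 0.95 * smoothed + 0.05 * g$loss
      trace <- rbind(trace, data.frame(epoch = ep, batch = bi,
                                       loss = g$loss, smoothed = smoothed))
    }
    if (verbose) {
      message(sprintf("epoch %2d  smoothed MSE %.5f", ep, smoothed))
    }
  }
  list(params = params, loss_trace = trace)
}
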