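#' Construct a spiking ADS network from a trained teacher
#'
#' Builds the "arbitrary dynamical system" spiking network: a population of
#' `n_neurons` LIF neurons with a random encoder `F` (see
#' [sample_encoder()]), analytically initialised fast balanced feedback
#' `Omega_f` (see [init_fast_weights()]), slow learned recurrent weights
#' `Omega_s` initialised to zero (the untrained network is then a pure
#' balanced autoencoder), and the teacher's input/readout weights `F_hat`
#' and `D_hat` copied verbatim so that the spiking network implements the
#' same task mapping `c -> y` once trained.
#'
#' @param teacher a trained `rate_network`.
#' @param n_neurons number of spiking neurons `N` (overcomplete,
#'   `N >= n_units` of the teacher).
#' @param lif a `lif_params` for the population; defaults to the standard
#'   constants at the teacher's `dt`.
#' @param mu regulariser passed to [init_fast_weights()].
#' @return an object of class `ads_network`.
#' @export
ads_network <- function(teacher, n_neurons = 320, lif = NULL, mu = NULL) {
  stopifnot(inherits(teacher, "rate_network"))
  if (is.null(lif)) lif <- lif_params(n_neurons, dt = teacher$dt)
  if (lif$n != n_neurons) stop("`lif$n` must equal `n_neurons`")
  if (abs(lif$dt - teacher$dt) > 1e-12) stop("teacher and LIF dt differ")
  F <- sample_encoder(teacher$n_units, n_neurons)
  s <- fast_weight_scale(F, lif, mu)
  structure(list(
    n = as.integer(n_neurons), n_hat = teacher$n_units,
    lif = lif, F = F,
    Omega_f = attr(s, "Omega_f"),
    Omega_s = matrix(0, n_neurons, n_neurons),
    F_hat = teacher$F, D_hat = teacher$D,
    current_scale = as.numeric(s)
  ), class = "ads_network")
}

#' @export
print.ads_network <- function(x, ...) {
  cat(sprintf("<ads_network> N = %d LIF neurons mimicking a %d-unit teacher, |Omega_s| = %.3g, current scale %.3g\n",
              x$n, x$n_hat, norm(x$Omega_s, "F"), x$current_scale))
  invisible(x)
}

expand_lif <- function(lif) {
  n <- lif$n
  list(tau_mem = rep_len(lif$tau_mem, n), v_thresh = rep_len(lif$v_thresh, n),
       v_rest = rep_len(lif$v_rest, n), v_reset = lif$v_reset,
       tau_fast = rep_len(lif$tau_fast, n), tau_slow = rep_len(lif$tau_slow, n))
}

#' Simulate the spiking ADS network
#'
#' Runs the clocked forward-Euler simulation.  Per step: the fast/slow
#' synaptic currents and the filtered trace `r` are advanced with the
#' previous step's spikes; the state decodes as `x_tilde = F r`; when a
#' teacher trajectory is supplied with `k > 0` the error `e = x_hat -
#' x_tilde` is fed back as a membrane current `k t(F) e`, clamping the
#' network to the target dynamics; the membrane equation integrates the
#' input drive `t(F) (F_hat c)` plus all recurrent currents; spikes reset
#' the membrane.  The output is `y_tilde = D_hat x_tilde`.
#'
#' The input drive is expressed in threshold-gap voltage units through the
#' network's `current_scale` (see [fast_weight_scale()]), matching the
#' rescaled fast feedback `Omega_f`; the decoder `x_tilde = F r` stays in
#' teacher-state units, and `k` and `eta` act on the raw teacher-space
#' error projection `t(F) e` so that their values are independent of the
#' hardware voltage scale.
#'
#' @param net an `ads_network`.
#' @param c_in input `time_series` at the network `dt`.
#' @param x_hat teacher state trajectory (`time_series`, `n_hat` channels)
#'   or `NULL`; required when `k > 0` or `learn = TRUE`.
#' @param k error-feedback rate (0 at inference).
#' @param noise_sigma thermal-noise level; each step adds
#'   `N(0, noise_sigma * (v_thresh - v_reset))` to each membrane potential.
#' @param eta learning rate for the online slow-weight update (ignored
#'   unless `learn = TRUE`).
#' @param learn if `TRUE`, apply `Omega_s <- Omega_s + eta (t(F) e) t(r)`
#'   every step and return the updated weights.
#' @param silence optional [silence_spec()]: clamps a random subset of
#'   membranes to `v_reset` inside a step window (sudden neuron failure).
#' @param return_raster keep the full spike raster (set `FALSE` in large
#'   sweeps to save memory).
#' @return list with `x_tilde`, `y_tilde` (`time_series`), `raster`
#'   (`spike_raster` or `NULL`), `mse` (mean squared reconstruction error
#'   against `x_hat`, `NA` when no teacher trajectory is given), and
#'   `Omega_s` (updated when learning).
#' @export
simulate_ads <- function(net, c_in, x_hat = NULL, k = 0, noise_sigma = 0,
                         eta = 0, learn = FALSE, silence = NULL,
                         return_raster = TRUE) {
  stopifnot(inherits(net, "ads_network"), inherits(c_in, "time_series"))
  lif <- net$lif
  if (abs(c_in$dt - lif$dt) > 1e-12) stop("input dt does not match network dt")
  if ((k > 0 || learn) && is.null(x_hat)) {
    stop("a teacher trajectory `x_hat` is required when k > 0 or learning")
  }
  T <- n_steps(c_in)
  p <- expand_lif(lif)
  Xhat <- if (is.null(x_hat)) matrix(0, 0, 0) else x_hat$values
  if (!is.null(x_hat) && ncol(Xhat) != T) stop("x_hat length mismatch")
  noise <- if (noise_sigma > 0) {
    matrix(stats::rnorm(lif$n * T), lif$n, T) *
      (noise_sigma * (p$v_thresh - p$v_reset))
  } else matrix(0, 0, 0)
  mask <- integer(0); on <- 0L; off <- 0L
  if (!is.null(silence)) {
    n_sil <- round(silence$fraction * lif$n)
    mask <- integer(lif$n)
    if (n_sil > 0) mask[sample.int(lif$n, n_sil)] <- 1L
    on <- as.integer(silence$onset) - 1L   # to 0-based
    off <- as.integer(silence$offset)
  }
  out <- cpp_simulate_ads(
    net$current_scale * t(net$F) %*% net$F_hat, net$Omega_f, net$Omega_s,
    net$F, net$D_hat,
    p$tau_mem, p$v_thresh, p$v_rest, p$v_reset, p$tau_fast, p$tau_slow,
    lif$dt, c_in$values, Xhat, k, eta, noise, mask, on, off,
    isTRUE(learn), isTRUE(return_raster))
  list(x_tilde = time_series(out$Xtilde, dt = lif$dt),
       y_tilde = time_series(out$Y, dt = lif$dt),
       raster = if (return_raster) spike_raster(out$raster, lif$dt) else NULL,
       mse = out$mse,
       Omega_s = out$Omega_s)
}

#' Local error-feedback update of the slow recurrent weights
#'
#' `delta Omega_s[i, j] = eta * (t(F) e)[i] * r[j]`: postsynaptic projected
#' error times presynaptic filtered trace, applied every simulation step
#' during training.  [simulate_ads()] passes `e = x_hat - x_tilde`, so the
#' learned slow current comes to reproduce the clamping error current as
#' the feedback rate is withdrawn.
#'
#' @param Omega_s current slow weights (`n` x `n`).
#' @param r filtered spike trace (length `n`).
#' @param e error vector in teacher-state space (length `n_hat`).
#' @param F encoder matrix (`n_hat` x `n`).
#' @param eta learning rate.
#' @return updated `Omega_s`.
#' @export
ads_weight_update <- function(Omega_s, r, e, F, eta) {
  Omega_s + eta * tcrossprod(drop(crossprod(F, e)), r)
}

#' Error-feedback schedule
#'
#' An ordered list of `(k, n_samples)` stages with a single learning rate.
#' Holding `k` fixed for a block of samples lets the network adapt to that
#' scale of error feedback; `k` must approach zero before the end of
#' training or the network learns to lean on the feedback and generalises
#' poorly once it is removed.
#'
#' @param k vector of non-negative feedback rates, one per stage.
#' @param n_samples samples per stage (recycled).
#' @param eta learning rate.
#' @return a `feedback_schedule` with a `stages` data frame and `eta`.
#' @export
feedback_schedule <- function(k, n_samples, eta) {
  if (any(k < 0)) stop("`k` values must be non-negative")
  stopifnot(eta >= 0)
  structure(list(stages = data.frame(k = k,
                                     n_samples = rep_len(n_samples, length(k))),
                 eta = eta),
            class = "feedback_schedule")
}

#' Named schedule presets
#'
#' `"xor"`: fixed `k = 75`, `eta = 1e-5`, 1000 samples.  `"speech"`:
#' `k` stepping 200 down to 25 in 8 evenly spaced stages, `eta = 1e-4`,
#' 5000 samples total (5 epochs of 1000).
#'
#' @param name preset name.
#' @param n_samples optionally override the total sample count (split
#'   evenly over stages).
#' @export
schedule_preset <- function(name = c("xor", "speech"), n_samples = NULL) {
  name <- match.arg(name)
  if (name == "xor") {
    total <- if (is.null(n_samples)) 1000 else n_samples
    feedback_schedule(k = 75, n_samples = total, eta = 1e-5)
  } else {
    total <- if (is.null(n_samples)) 5000 else n_samples
    feedback_schedule(k = seq(200, 25, length.out = 8),
                      n_samples = ceiling(total / 8), eta = 1e-4)
  }
}

#' Train the ADS network to mimic the teacher
#'
#' For each sample drawn from the task: simulate the teacher to obtain the
#' target state trajectory `x_hat`, then simulate the spiking network at
#' the current stage's error-feedback rate while applying the local
#' slow-weight update online.  Records the per-sample reconstruction MSE
#' `mean((x_tilde - x_hat)^2)` and the `k` trace.
#'
#' @param teacher a trained `rate_network` (must share `F_hat`/`D_hat`
#'   and state dimensionality with `net`).
#' @param net an `ads_network` from [ads_network()].
#' @param task_sampler function `f(n)` returning task samples.
#' @param schedule a [feedback_schedule()] or preset name.
#' @param omega_bound divergence guard: training aborts (with the sample
#'   index) if the Frobenius norm of `Omega_s` exceeds this.
#' @param verbose print stage progress.
#' @return list with the trained `net` and a `record` data frame
#'   (`sample`, `stage`, `k`, `mse`).
#' @export
train_ads <- function(teacher, net, task_sampler, schedule = "xor",
                      omega_bound = 1e6, verbose = FALSE) {
  if (is.character(schedule)) schedule <- schedule_preset(schedule)
  stopifnot(inherits(schedule, "feedback_schedule"),
            inherits(teacher, "rate_network"), inherits(net, "ads_network"))
  if (net$n_hat != teacher$n_units ||
      !identical(dim(net$F_hat), dim(teacher$F)) ||
      !identical(dim(net$D_hat), dim(teacher$D))) {
    stop("teacher and ADS network input/output weights are inconsistent")
  }
  rec <- list()
  s_idx <- 0L
  for (st in seq_len(nrow(schedule$stages))) {
    k <- schedule$stages$k[st]
    n_st <- schedule$stages$n_samples[st]
    if (n_st <= 0) next
    samples <- task_sampler(n_st)
    for (i in seq_len(n_st)) {
      s_idx <- s_idx + 1L
      traj <- simulate_rnn(teacher, samples[[i]]$input)
      sim <- simulate_ads(net, samples[[i]]$input, x_hat = traj$x_hat,
                          k = k, eta = schedule$eta, learn = TRUE,
                          return_raster = FALSE)
      net$Omega_s <- sim$Omega_s
      if (!all(is.finite(net$Omega_s)) || norm(net$Omega_s, "F") > omega_bound) {
        stop(sprintf("slow weights diverged at training sample %d", s_idx))
      }
      rec[[s_idx]] <- data.frame(sample = s_idx, stage = st, k = k,
                                 mse = sim$mse)
    }
    if (verbose) {
      message(sprintf("stage %d (k = %g): median reconstruction MSE %.4g",
                      st, k, median(vapply(rec[(s_idx - n_st + 1):s_idx],
                                           function(d) d$mse, 0))))
    }
  }
  list(net = net,
       record = if (length(rec)) do.call(rbind, rec)
                else data.frame(sample = integer(), stage = integer(),
                                k = numeric(), mse = numeric()))
}

#' Evaluate a network on fresh task samples
#'
#' Inference always runs at `k = 0`: the spiking network replaces the
#' teacher entirely and no error feedback is available.  Accuracy uses the
#' task's readout rule; the output MSE is measured against the teacher's
#' own readout `y_hat` (the distillation target).
#'
#' @param net an `ads_network`, or a `rate_network` (evaluated through the
#'   same readout, e.g. for the teacher's own accuracy).
#' @param task_sampler function `f(n)` returning labelled samples.
#' @param n_samples number of evaluation samples.
#' @param readout function `f(y_ts)` returning a class label; default
#'   [classify_xor()].
#' @param teacher optional `rate_network` used as the MSE reference for a
#'   spiking `net`.
#' @param noise_sigma,silence perturbations forwarded to [simulate_ads()].
#' @return list with `accuracy`, `mse` (mean over samples; `NA` without a
#'   reference), and a per-sample data frame `trials`.
#' @export
evaluate_ads <- function(net, task_sampler, n_samples = 200,
                         readout = classify_xor, teacher = NULL,
                         noise_sigma = 0, silence = NULL) {
  samples <- task_sampler(n_samples)
  correct <- logical(n_samples)
  mse <- rep(NA_real_, n_samples)
  for (i in seq_len(n_samples)) {
    s <- samples[[i]]
    if (inherits(net, "rate_network")) {
      y <- simulate_rnn(net, s$input)$y_hat
    } else {
      sim <- simulate_ads(net, s$input, k = 0, noise_sigma = noise_sigma,
                          silence = silence, return_raster = FALSE)
      y <- sim$y_tilde
      if (!is.null(teacher)) {
        ref <- simulate_rnn(teacher, s$input)$y_hat
        mse[i] <- mean((y$values - ref$values)^2)
      }
    }
    correct[i] <- identical(readout(y), s$label)
  }
  list(accuracy = mean(correct), mse = mean(mse),
       trials = data.frame(sample = seq_len(n_samples), correct = correct,
                           mse = mse))
}
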