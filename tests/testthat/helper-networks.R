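# Small fixture builders shared across test files.  Everything is built in
# code under fixed seeds; no stored fixtures.

tiny_teacher <- function(n_units = 3, n_in = 1, n_out = 1, seed = 42) {
  set.seed(seed)
  rate_network(n_units, n_in, n_out)
}

tiny_ads <- function(n_neurons = 8, teacher = tiny_teacher(), seed = 43) {
  set.seed(seed)
  ads_network(teacher, n_neurons = n_neurons)
}

# A "teacher" whose role is only to provide shapes for autoencoding tests:
# the ADS network is asked to represent an externally supplied target
# trajectory (x_hat), with zero input.
shape_teacher <- function(n_units, n_in = 1, n_out = 1, seed = 7) {
  set.seed(seed)
  rate_network(n_units, n_in, n_out)
}

# Slow two-dimensional sinusoidal target used by the stiff-clamp tracking
# test (simulated at a fine dt so the feedback kick per step stays below
# the spike quantum).
sinusoid_target <- function(T = 800, dt = 1e-3, freq = c(1.5, 2.5),
                            amp = 1) {
  tt <- seq_len(T) * dt
  time_series(rbind(amp * sin(2 * pi * freq[1] * tt),
                    amp * cos(2 * pi * freq[2] * tt)), dt = dt)
}

# 16-channel multisine target: the balanced-coding regime of the XOR-scale
# system (concentrated encoder column norms), used by the k- and
# N-monotonicity tests.
multisine_target <- function(T = 800, dt = 1e-3, n_channels = 16,
                             amp = 1.5, seed = 8) {
  tt <- seq_len(T) * dt
  set.seed(seed)
  freqs <- runif(n_channels, 0.5, 2.5)
  ph <- runif(n_channels, 0, 2 * pi)
  time_series(amp * sin(outer(2 * pi * freqs, tt) + ph), dt = dt)
}

zero_input <- function(T = 800, dt = 1e-3, d = 1) {
  time_series(matrix(0, d, T), dt = dt)
}

# Pure-R reference simulation of the ADS network, built from the exported
# step primitives, mirroring the compiled loop's update order exactly.
reference_ads_sim <- function(net, c_in, x_hat = NULL, k = 0) {
  lif <- net$lif
  T <- n_steps(c_in)
  st <- lif_state(lif)
  s <- net$current_scale
  W_in <- s * t(net$F) %*% net$F_hat
  o_prev <- numeric(lif$n)
  Xt <- matrix(0, net$n_hat, T)
  spikes <- matrix(0L, lif$n, T)
  r <- numeric(lif$n)
  for (t in seq_len(T)) {
    st$I_fast <- synapse_step(st$I_fast, -net$Omega_f, o_prev, lif$tau_fast, lif$dt)
    st$I_slow <- synapse_step(st$I_slow, net$Omega_s, o_prev, lif$tau_slow, lif$dt)
    r <- r * (1 - lif$dt / lif$tau_slow) + o_prev
    xt <- drop(net$F %*% r)
    e <- if (is.null(x_hat)) numeric(net$n_hat) else x_hat$values[, t] - xt
    inputs <- drop(W_in %*% c_in$values[, t]) + k * drop(crossprod(net$F, e))
    stp <- lif_step(st, lif, inputs)
    st <- stp$state
    o_prev <- stp$spikes
    Xt[, t] <- xt
    spikes[, t] <- o_prev
  }
  list(x_tilde = Xt, spikes = spikes)
}
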