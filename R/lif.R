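#' Leaky integrate-and-fire parameters
#'
#' Parameter set for a population of LIF neurons with two exponential
#' synapse channels ("fast", ~1 ms, carrying the balancing feedback, and
#' "slow", ~70 ms, carrying the learned recurrence).  Defaults are the
#' values used throughout: membrane time constant 50 ms, reset 0, rest 0.5,
#' threshold 1, fast/slow synaptic constants 1 ms / 70 ms, Euler step 1 ms.
#'
#' `tau_mem`, `v_thresh`, `v_rest`, `tau_fast` and `tau_slow` may be either
#' scalars or length-`n` vectors; per-neuron values arise when simulating
#' device mismatch.
#'
#' @param n number of neurons.
#' @param tau_mem membrane time constant (s).
#' @param v_thresh spiking threshold.
#' @param v_reset reset potential (scalar).
#' @param v_rest resting potential.
#' @param tau_fast fast synaptic time constant (s).
#' @param tau_slow slow synaptic time constant (s); also the filter constant
#'   of the decoded trace `r`.
#' @param dt simulation step (s); must not exceed `min(tau_fast, tau_mem)`.
#' @return an object of class `lif_params`.
#' @export
lif_params <- function(n, tau_mem = 0.05, v_thresh = 1, v_reset = 0,
                       v_rest = 0.5, tau_fast = 0.001, tau_slow = 0.07,
                       dt = 0.001) {
  stopifnot(n >= 1)
  chk_len <- function(x, nm) {
    if (!length(x) %in% c(1L, n)) stop(sprintf("`%s` must have length 1 or n", nm))
    if (any(!is.finite(x))) stop(sprintf("`%s` must be finite", nm))
    x
  }
  tau_mem <- chk_len(tau_mem, "tau_mem"); tau_fast <- chk_len(tau_fast, "tau_fast")
  tau_slow <- chk_len(tau_slow, "tau_slow"); v_thresh <- chk_len(v_thresh, "v_thresh")
  v_rest <- chk_len(v_rest, "v_rest")
  if (any(c(tau_mem, tau_fast, tau_slow) <= 0)) stop("time constants must be positive")
  if (length(v_reset) != 1) stop("`v_reset` must be a scalar")
  if (any(v_reset > v_rest) || any(v_rest >= v_thresh)) {
    stop("require v_reset <= v_rest < v_thresh")
  }
  if (dt <= 0 || dt > min(tau_fast) || dt > min(tau_mem)) {
    stop("require 0 < dt <= min(tau_fast, tau_mem)")
  }
  structure(list(n = as.integer(n), tau_mem = tau_mem, v_thresh = v_thresh,
                 v_reset = v_reset, v_rest = v_rest, tau_fast = tau_fast,
                 tau_slow = tau_slow, dt = dt),
            class = "lif_params")
}

#' Membrane leak rate
#'
#' The leak-rate form of the membrane equation uses `lambda = 1/tau_mem`;
#' exposed read-only for convenience.
#' @param params a `lif_params`.
#' @export
leak_rate <- function(params) 1 / params$tau_mem

#' Initial LIF state
#'
#' Membrane potentials start at rest; all currents and the filtered spike
#' trace start at zero.
#' @param params a `lif_params`.
#' @return a `lif_state` list with fields `V`, `I_fast`, `I_slow`, `I_inp`,
#'   `I_err`, `r`.
#' @export
lif_state <- function(params) {
  n <- params$n
  structure(list(V = rep_len(params$v_rest, n), I_fast = numeric(n),
                 I_slow = numeric(n), I_inp = numeric(n), I_err = numeric(n),
                 r = numeric(n)),
            class = "lif_state")
}

#' One forward-Euler step of the LIF membrane equation
#'
#' Updates `V <- V + dt/tau_mem * (v_rest - V + I_inp + I_fast + I_slow +
#' I_err)` plus, when `noise_sigma > 0`, an additive membrane perturbation
#' drawn i.i.d. `N(0, noise_sigma * (v_thresh - v_reset))` per neuron per
#' step (the thermal-noise model; the scaling to the reset--threshold gap
#' keeps noise levels comparable across parameterisations).  Neurons whose
#' updated potential exceeds threshold emit a spike and are reset to
#' `v_reset` regardless of overshoot.  There is no refractory period: at
#' most one spike per neuron per step, and exactly the neurons with
#' `V > v_thresh` spike.
#'
#' The input and error currents are taken from the `inputs` argument;
#' synaptic currents are taken from the state (update them beforehand with
#' [synapse_step()]).  The filtered trace `r` is advanced with this step's
#' spikes.
#'
#' @param state a `lif_state`.
#' @param params a `lif_params`.
#' @param inputs per-neuron external current (input drive plus any error
#'   current), length `n` (recycled if scalar).
#' @param noise_sigma thermal-noise level (dimensionless fraction of the
#'   reset--threshold gap); 0 disables noise.
#' @return list with elements `state` (updated) and `spikes` (0/1 vector).
#' @export
lif_step <- function(state, params, inputs = 0, noise_sigma = 0) {
  n <- params$n
  inputs <- rep_len(inputs, n)
  I_tot <- inputs + state$I_fast + state$I_slow
  V <- state$V + params$dt / params$tau_mem * (params$v_rest - state$V + I_tot)
  if (noise_sigma > 0) {
    V <- V + stats::rnorm(n, 0, noise_sigma * (params$v_thresh - params$v_reset))
  }
  if (any(!is.finite(V))) {
    stop(sprintf("non-finite membrane potential in neuron %d",
                 which(!is.finite(V))[1]))
  }
  spikes <- as.integer(V > params$v_thresh)
  V[spikes == 1L] <- params$v_reset
  state$V <- V
  state$I_inp <- inputs
  state$r <- state$r * (1 - params$dt / params$tau_slow) + spikes
  list(state = state, spikes = spikes)
}

#' One forward-Euler step of an exponential synapse
#'
#' `I <- I + dt/tau_syn * (-I + (W o) * tau_syn / dt)`, which simplifies to
#' `I * (1 - dt/tau_syn) + W o`: an isolated presynaptic spike through unit
#' weight raises the current by exactly 1, and the discrete integral
#' `sum(I) * dt` of that PSP equals `tau_syn` (so the integral is 1 in
#' units of the synaptic time constant).  The update is linear in both `W`
#' and the spike vector.
#'
#' @param I postsynaptic current vector (length `n_post`).
#' @param W weight matrix, `n_post` x `n_pre`.
#' @param spikes binary presynaptic spike vector (length `n_pre`).
#' @param tau_syn synaptic time constant (s), scalar or per-postsynaptic
#'   vector.
#' @param dt simulation step (s).
#' @return updated current vector.
#' @export
synapse_step <- function(I, W, spikes, tau_syn, dt) {
  if (!is.matrix(W)) W <- matrix(W, nrow = length(I))
  if (ncol(W) != length(spikes) || nrow(W) != length(I)) {
    stop(sprintf("shape mismatch: W is %dx%d, I has length %d, spikes %d",
                 nrow(W), ncol(W), length(I), length(spikes)))
  }
  if (any(tau_syn <= 0)) stop("`tau_syn` must be positive")
  I * (1 - dt / tau_syn) + drop(W %*% spikes)
}

#' Exponentially filtered spike trains
#'
#' Convolves each neuron's spike train with the same exponential kernel as
#' [synapse_step()] with unit weight: `r_t = r_{t-1} (1 - dt/tau) + o_t`.
#' This trace is what the decoder reads out (`x_tilde = F r`) and what the
#' learning rule uses as the presynaptic factor.
#'
#' @param raster a `spike_raster`.
#' @param tau filter time constant (s).
#' @return a `time_series` with one channel per neuron.
#' @export
filter_spikes <- function(raster, tau) {
  if (any(tau <= 0)) stop("`tau` must be positive")
  o <- raster$spikes
  a <- 1 - raster$dt / tau
  r <- matrix(0, nrow(o), ncol(o))
  prev <- numeric(nrow(o))
  for (t in seq_len(ncol(o))) {
    prev <- prev * a + o[, t]
    r[, t] <- prev
  }
  time_series(r, dt = raster$dt)
}
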