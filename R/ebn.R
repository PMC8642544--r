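#' Sample a random encoding matrix
#'
#' Column `i` is the encoding vector of spiking neuron `i` in teacher-state
#' space: the decoder reads `x_tilde = F r` and the error current projects
#' through `t(F)`.  Entries are i.i.d. standard normal divided by the
#' teacher dimensionality `n_hat` (so entry s.d. is `1/n_hat` and column
#' norms concentrate around `1/sqrt(n_hat)`).  An overcomplete code
#' (`n >= n_hat`) is recommended.
#'
#' @param n_hat teacher state dimensionality.
#' @param n number of spiking neurons.
#' @return an `n_hat` x `n` matrix.
#' @export
sample_encoder <- function(n_hat, n) {
  stopifnot(n_hat >= 1, n >= 1)
  matrix(stats::rnorm(n_hat * n) / n_hat, n_hat, n)
}

#' Analytic fast balanced feedback weights
#'
#' `Omega_f = t(F) F + mu I`, rescaled by a single scalar so that the mean
#' diagonal element equals `v_thresh - v_reset`.  The fast synapses carry
#' `-Omega_f o`, so a neuron's own spike pulls its membrane from threshold
#' back across the reset gap (on average), implementing the fast balanced
#' self-reset of the efficient balanced network coding scheme.  The result
#' is symmetric and positive semidefinite up to the identity regulariser,
#' with a strictly positive diagonal.
#'
#' @param F encoder matrix from [sample_encoder()].
#' @param params a `lif_params` (supplies the threshold and reset).
#' @param mu identity regulariser; default `2e-4 * (v_thresh - v_reset)`,
#'   a small stabiliser against near-duplicate encoding columns.
#' @return an `n` x `n` matrix of fast feedback weights.
#' @export
init_fast_weights <- function(F, params, mu = NULL) {
  attr(fast_weight_scale(F, params, mu), "Omega_f")
}

#' Threshold rescaling factor of the balanced feedback
#'
#' The scalar `s = (v_thresh - v_reset) / mean(diag(t(F) F + mu I))` that
#' rescales `t(F) F + mu I` into `Omega_f`.  The same factor converts all
#' input-side currents (input drive, error feedback, learned slow
#' recurrence) into threshold-gap voltage units, so that the network is
#' the reference balanced network expressed at the hardware's threshold
#' and reset potentials while the decoder `x_tilde = F r` stays in
#' teacher-state units.
#'
#' @inheritParams init_fast_weights
#' @return the scalar `s`, with the rescaled matrix attached as attribute
#'   `Omega_f`.
#' @export
fast_weight_scale <- function(F, params, mu = NULL) {
  if (all(F == 0)) stop("encoder matrix is identically zero")
  gap <- mean(params$v_thresh) - params$v_reset
  if (is.null(mu)) mu <- 2e-4 * gap
  if (mu < 0) stop("`mu` must be non-negative")
  W <- crossprod(F) + mu * diag(ncol(F))
  s <- gap / mean(diag(W))
  structure(s, Omega_f = W * s)
}
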