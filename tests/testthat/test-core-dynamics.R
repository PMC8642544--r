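test_that("resting state with zero input is a fixed point of the leak equation", {
  p <- lif_params(4)
  st <- lif_state(p)
  out <- lif_step(st, p, inputs = 0)
  expect_identical(out$state$V, st$V)
  expect_identical(out$spikes, rep(0L, 4))
})

test_that("threshold crossing emits one spike and resets the membrane", {
  p <- lif_params(1)
  st <- lif_state(p)
  st$V <- 0.99 * p$v_thresh
  # current large enough that one Euler step crosses threshold
  out <- lif_step(st, p, inputs = 5)
  expect_identical(out$spikes, 1L)
  expect_identical(out$state$V, p$v_reset)
  # and from reset, with no input, no further spike
  out2 <- lif_step(out$state, p, inputs = 0)
  expect_identical(out2$spikes, 0L)
})

test_that("subthreshold trajectory follows the closed-form exponential relaxation", {
  p <- lif_params(1, dt = 1e-3)
  I <- 0.3                      # steady state v_rest + I = 0.8 < threshold
  st <- lif_state(p)
  n <- 200
  V <- numeric(n)
  for (t in seq_len(n)) {
    out <- lif_step(st, p, inputs = I)
    st <- out$state
    V[t] <- st$V
  }
  tt <- seq_len(n) * p$dt
  V_exact <- p$v_rest + I - I * exp(-tt / p$tau_mem)
  expect_identical(sum(abs(V > p$v_thresh)), 0L)
  expect_lt(max(abs(V - V_exact)), 5 * p$dt / p$tau_mem)
})

test_that("halving dt changes a noise-free trajectory by O(dt)", {
  sim_v <- function(dt, t_end = 0.1, I = 0.3) {
    p <- lif_params(1, dt = dt)
    st <- lif_state(p)
    for (t in seq_len(round(t_end / dt))) st <- lif_step(st, p, I)$state
    st$V
  }
  v_exact <- 0.5 + 0.3 - 0.3 * exp(-0.1 / 0.05)
  err1 <- abs(sim_v(1e-3) - v_exact)
  err2 <- abs(sim_v(5e-4) - v_exact)
  expect_lt(err2, err1)
  expect_lt(err1, 0.02)
})

test_that("exactly the neurons above threshold spike (no refractory state)", {
  set.seed(5)
  p <- lif_params(50)
  st <- lif_state(p)
  st$V <- runif(50, 0, 1.2)
  # with zero net current the leak pulls V toward rest before thresholding
  expected <- as.integer(st$V + p$dt / p$tau_mem * (p$v_rest - st$V) > p$v_thresh)
  out <- lif_step(st, p, inputs = 0)
  expect_identical(out$spikes, expected)
})

test_that("thermal noise perturbs the membrane at the configured scale", {
  set.seed(11)
  p <- lif_params(2000)
  st <- lif_state(p)
  out <- lif_step(st, p, inputs = 0, noise_sigma = 0.05)
  dev <- out$state$V - p$v_rest
  expect_gt(sd(dev), 0.04)
  expect_lt(sd(dev), 0.06)
  # and zero noise is exactly deterministic
  out0 <- lif_step(st, p, inputs = 0, noise_sigma = 0)
  expect_identical(out0$state$V, st$V)
})

test_that("non-finite state fails naming the offending neuron", {
  p <- lif_params(3)
  st <- lif_state(p)
  st$V[2] <- NaN
  expect_error(lif_step(st, p, 0), "neuron 2")
})

test_that("synaptic current decays exponentially and spikes inject unit PSPs", {
  # no spikes, zero current stays zero
  expect_identical(synapse_step(numeric(2), diag(2), c(0, 0), 0.01, 1e-3),
                   c(0, 0))
  # exponential decay with time constant tau_syn, checked at t = tau_syn
  tau <- 0.01; dt <- 1e-3
  I <- 1
  for (t in seq_len(round(tau / dt))) I <- synapse_step(I, matrix(1), 0, tau, dt)
  expect_equal(I, exp(-1), tolerance = 0.06)
  # single spike through unit weight with dt = tau: jump of exactly 1
  expect_identical(synapse_step(0, matrix(1), 1, 1e-3, 1e-3), 1)
})

test_that("the discrete PSP integral of one unit-weight spike is tau_syn", {
  tau <- 0.005; dt <- 1e-3
  I <- synapse_step(0, matrix(1), 1, tau, dt)
  total <- I * dt
  for (t in 1:200) {
    I <- synapse_step(I, matrix(1), 0, tau, dt)
    total <- total + I * dt
  }
  expect_equal(total / tau, 1, tolerance = 1e-6)
})

test_that("synapse_step is linear in the weights and in the spike vector", {
  set.seed(3)
  W <- matrix(rnorm(12), 3, 4)
  o1 <- c(1, 0, 1, 0); o2 <- c(0, 1, 0, 1)
  I0 <- rnorm(3)
  base <- synapse_step(I0 * 0, W, o1, 0.01, 1e-3)
  expect_equal(synapse_step(I0 * 0, 2 * W, o1, 0.01, 1e-3), 2 * base)
  expect_equal(synapse_step(I0 * 0, W, o1 + o2, 0.01, 1e-3),
               base + synapse_step(I0 * 0, W, o2, 0.01, 1e-3))
})

test_that("synapse_step rejects shape mismatches", {
  expect_error(synapse_step(numeric(3), matrix(1, 3, 2), c(1, 0, 0), 0.01, 1e-3),
               "shape mismatch")
})

test_that("filter_spikes matches the unit-weight synapse response and is shift-invariant", {
  empty <- spike_raster(matrix(0L, 2, 50), 1e-3)
  expect_true(all(filter_spikes(empty, 0.07)$values == 0))

  one <- matrix(0L, 1, 50); one[1, 10] <- 1L
  tr <- filter_spikes(spike_raster(one, 1e-3), 0.005)$values[1, ]
  I <- 0; ref <- numeric(50)
  for (t in 1:50) {
    I <- synapse_step(I, matrix(1), as.numeric(one[1, t]), 0.005, 1e-3)
    ref[t] <- I
  }
  expect_equal(tr, ref)

  shifted <- matrix(0L, 1, 50); shifted[1, 25] <- 1L
  tr2 <- filter_spikes(spike_raster(shifted, 1e-3), 0.005)$values[1, ]
  expect_equal(tr2[25:50], tr[10:35])
})

test_that("lif_params enforces its invariants", {
  expect_error(lif_params(2, v_rest = 1.5), "v_reset <= v_rest < v_thresh")
  expect_error(lif_params(2, dt = 0.01, tau_fast = 0.001), "dt")
  expect_error(lif_params(2, tau_mem = -1), "positive|length")
  expect_equal(leak_rate(lif_params(1)), 1 / 0.05)
})
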