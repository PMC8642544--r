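test_that("a silent unstimulated network stays silent and decodes zero", {
  net <- tiny_ads()
  sim <- simulate_ads(net, zero_input(200), k = 0)
  expect_identical(sum(sim$raster$spikes), 0L)
  expect_true(all(sim$x_tilde$values == 0))
  expect_true(all(sim$y_tilde$values == 0))
})

test_that("with k = 0 the output is independent of any supplied teacher trajectory", {
  net <- tiny_ads()
  set.seed(9)
  cin <- time_series(matrix(rnorm(300, sd = 0.2), 1), 1e-3)
  fake <- time_series(matrix(rnorm(3 * 300), 3), 1e-3)
  a <- simulate_ads(net, cin, k = 0)
  b <- simulate_ads(net, cin, x_hat = fake, k = 0)
  expect_identical(a$x_tilde$values, b$x_tilde$values)
  expect_identical(a$raster$spikes, b$raster$spikes)
})

test_that("error feedback requires a teacher trajectory", {
  net <- tiny_ads()
  expect_error(simulate_ads(net, zero_input(50), k = 10), "x_hat")
})

test_that("the weight update is the stated outer product", {
  # N = 2, n_hat = 1, F = [1, -1], e = 0.5, r = (1, 0), eta = 1
  F1 <- matrix(c(1, -1), 1, 2)
  out <- ads_weight_update(matrix(0, 2, 2), r = c(1, 0), e = 0.5, F = F1,
                           eta = 1)
  expect_equal(out, matrix(c(0.5, -0.5, 0, 0), 2, 2))
  # zero error or zero trace gives no update
  base <- matrix(rnorm(4), 2, 2)
  expect_equal(ads_weight_update(base, c(1, 1), 0, F1, 1), base)
  expect_equal(ads_weight_update(base, c(0, 0), 0.5, F1, 1), base)
})

test_that("the compiled simulator matches the R step primitives bit for bit", {
  teach <- tiny_teacher(3)
  net <- tiny_ads(8, teach)
  set.seed(12)
  cin <- time_series(matrix(rnorm(150, sd = 0.5), 1), 1e-3)
  traj <- simulate_rnn(teach, cin)
  for (k in c(0, 50)) {
    cppo <- simulate_ads(net, cin, x_hat = traj$x_hat, k = k)
    refo <- reference_ads_sim(net, cin, x_hat = traj$x_hat, k = k)
    expect_identical(cppo$raster$spikes, refo$spikes)
    expect_equal(cppo$x_tilde$values, refo$x_tilde, tolerance = 1e-12)
  }
})

test_that("simulation and training are bit-exactly reproducible under a fixed seed", {
  teach <- tiny_teacher(3)
  sampler <- xor_task_sampler()
  run <- function() {
    set.seed(77)
    net <- ads_network(teach, n_neurons = 16)
    train_ads(teach, net, sampler,
              feedback_schedule(20, 3, eta = 1e-5))$net$Omega_s
  }
  expect_identical(run(), run())
})

test_that("an empty schedule or zero learning rate leaves the network unchanged", {
  teach <- tiny_teacher(3)
  net <- tiny_ads(8, teach)
  sampler <- xor_task_sampler()
  out <- train_ads(teach, net, sampler, feedback_schedule(75, 0, eta = 1e-5))
  expect_identical(out$net$Omega_s, net$Omega_s)
  expect_identical(nrow(out$record), 0L)

  set.seed(13)
  out2 <- train_ads(teach, net, sampler, feedback_schedule(75, 2, eta = 0))
  expect_identical(out2$net$Omega_s, net$Omega_s)
  expect_identical(nrow(out2$record), 2L)
})

test_that("clamped tracking of a slow target is accurate for large k", {
  # N = 160 balanced population tracking a 2-d sinusoid with Omega_s = 0.
  # The clamp is stiff (feedback gain x spike quantum), so the simulation
  # step must keep the per-step feedback kick below the quantum: dt = 1e-5.
  dtf <- 1e-5
  target <- sinusoid_target(T = 20000, dt = dtf, freq = c(10, 16), amp = 3)
  teach <- shape_teacher(2)
  teach$dt <- dtf
  set.seed(100 + 160)
  net <- ads_network(teach, n_neurons = 160,
                     lif = lif_params(160, dt = dtf))
  sim <- simulate_ads(net, zero_input(20000, dt = dtf), x_hat = target,
                      k = 100, return_raster = FALSE)
  rel <- sqrt(sum((sim$x_tilde$values - target$values)^2) /
                sum(target$values^2))
  expect_lt(rel, 0.3)
})

test_that("time-averaged tracking error does not increase with the feedback rate", {
  target <- multisine_target(T = 800)
  teach <- shape_teacher(16)
  set.seed(100 + 80)
  net <- ads_network(teach, n_neurons = 80)
  errs <- vapply(c(0, 25, 75, 200), function(k) {
    sim <- simulate_ads(net, zero_input(800), x_hat = target, k = k,
                        return_raster = FALSE)
    mean(sqrt(colSums((sim$x_tilde$values - target$values)^2)))
  }, 0)
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("feedback schedules validate their stages and presets are as configured", {
  expect_error(feedback_schedule(c(75, -1), 10, 1e-5), "non-negative")
  xor <- schedule_preset("xor")
  expect_equal(xor$stages$k, 75)
  expect_equal(xor$eta, 1e-5)
  sp <- schedule_preset("speech")
  expect_equal(sp$stages$k, seq(200, 25, length.out = 8))
  expect_equal(sp$eta, 1e-4)
  expect_true(tail(sp$stages$k, 1) <= head(sp$stages$k, 1) / 8)
})

test_that("the evaluation readout scores targets perfectly and silent networks at zero", {
  # the target signal itself classifies to its own label for both classes
  set.seed(18)
  samples <- xor_task_sampler()(30)
  expect_true(all(vapply(samples, function(s) classify_xor(s$target), 0) ==
                    vapply(samples, function(s) s$label, 0)))
  expect_true(any(vapply(samples, function(s) s$label, 0) == 1) &&
                any(vapply(samples, function(s) s$label, 0) == -1))

  # a degenerate all-silent network abstains everywhere: zero accuracy
  teach <- tiny_teacher(4)
  set.seed(16)
  net <- ads_network(teach, n_neurons = 8)
  net$F_hat <- net$F_hat * 0     # no input drive at all
  set.seed(17)
  ev <- evaluate_ads(net, xor_task_sampler(), n_samples = 10)
  expect_equal(ev$accuracy, 0)
})
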