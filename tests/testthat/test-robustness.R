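test_that("zero mismatch is the identity and zeros stay exactly zero", {
  net <- tiny_ads()
  net$Omega_s[1, 2] <- 0.5
  set.seed(1)
  out <- apply_mismatch(net, delta = 0)
  expect_equal(out$F, net$F)
  expect_equal(out$Omega_s, net$Omega_s)
  expect_equal(rep_len(out$lif$v_thresh, net$n), rep_len(net$lif$v_thresh, net$n))

  set.seed(2)
  out2 <- apply_mismatch(net, delta = 0.2)
  expect_true(all(out2$Omega_s[net$Omega_s == 0] == 0))
  # purity: the input object is untouched
  expect_identical(sum(net$lif$v_thresh != 1), 0L)
})

test_that("mismatch draws recover the configured relative spread", {
  net <- tiny_ads()
  w <- 0.5
  net$Omega_s <- matrix(w, 100, 100)   # 1e4 identical weights
  set.seed(3)
  out <- apply_mismatch(net, delta = 0.2, targets = "weights")
  ratio <- sd(out$Omega_s) / w
  se <- 0.2 / sqrt(2 * 1e4)
  expect_lt(abs(ratio - 0.2), 3 * se)
  expect_equal(mean(out$Omega_s), w, tolerance = 3 * 0.2 * w / sqrt(1e4) / w)
})

test_that("mismatch reproduces the linear mean-variance law across magnitudes", {
  delta <- 0.1
  mags <- c(0.2, 0.5, 1, 2, 5)
  set.seed(4)
  sds <- vapply(mags, function(m) sd(rnorm(2e4, m, delta * m)), 0)
  fit <- lm(sds ~ 0 + mags)
  expect_equal(unname(coef(fit)), delta, tolerance = 0.05 * delta)
  # and through the network path: thresholds scale the same way
  net <- tiny_ads(200)
  set.seed(5)
  out <- apply_mismatch(net, delta = 0.1, targets = "thresholds")
  expect_lt(abs(sd(out$lif$v_thresh) / mean(net$lif$v_thresh) - 0.1), 0.015)
})

test_that("the quantiser reproduces hand-computed codebooks", {
  # grid-exact input is returned exactly
  expect_equal(quantize_weights(matrix(0:3, 1), bits = 2), matrix(0:3, 1))
  # rho = 2/7; 0.3/rho = 1.05 -> 1; +-1/rho = +-3.5 -> +-4 (half away from zero)
  got <- quantize_weights(matrix(c(-1, 0.3, 1), 1), bits = 3)
  expect_equal(got, matrix(c(-8 / 7, 2 / 7, 8 / 7), 1))
})

test_that("the quantiser is idempotent with a bounded codebook", {
  set.seed(6)
  for (bits in c(2, 4, 6)) {
    W <- matrix(rnorm(400), 20, 20)
    Q <- quantize_weights(W, bits)
    expect_lte(length(unique(as.vector(Q))), 2^bits)
    expect_equal(quantize_weights(Q, bits), Q, tolerance = 1e-12)
  }
  expect_warning(out <- quantize_weights(matrix(1, 2, 2), 3), "constant")
  expect_equal(out, matrix(1, 2, 2))
  expect_error(quantize_weights(matrix(rnorm(4), 2), bits = 0), "bits")
})

test_that("silencing clamps the chosen subset and a zero fraction is exact identity", {
  teach <- tiny_teacher(3)
  net <- tiny_ads(20, teach)
  set.seed(7)
  cin <- time_series(matrix(rnorm(400, sd = 0.6), 1), 1e-3)

  base <- simulate_ads(net, cin, k = 0)
  set.seed(8)
  same <- simulate_ads(net, cin, k = 0,
                       silence = silence_spec(0, onset = 100, offset = 300))
  expect_identical(same$raster$spikes, base$raster$spikes)

  set.seed(8)
  sil <- simulate_ads(net, cin, k = 0,
                      silence = silence_spec(0.4, onset = 100, offset = 300))
  set.seed(8)
  mask <- integer(20); mask[sample.int(20, 8)] <- 1L  # same draw as inside
  expect_identical(sum(sil$raster$spikes[mask == 1L, 100:299]), 0L)

  expect_error(silence_spec(1.2, 1, 2), "fraction")
  expect_error(silence_spec(0.4, 10, 5), "offset")
})

test_that("the robustness harness is shaped and paired as documented", {
  teach <- tiny_teacher(3)
  net <- tiny_ads(16, teach)
  sampler <- xor_task_sampler()
  res <- run_robustness_suite(net, teach, sampler, "mismatch",
                              levels = c(0, 0.1), n_network_draws = 2,
                              n_trials = 3, seed = 5)
  expect_identical(nrow(res), 2L * 2L * 3L)
  expect_true(all(res$mse >= 0))
  expect_true(all(res$accuracy %in% c(0, 1)))
  # trials are paired: the same trial seeds appear at every level
  expect_identical(unique(table(res$trial_seed)), as.integer(4))

  # delta = 0 rows reproduce the unperturbed baseline bit-exactly
  base <- run_robustness_suite(net, teach, sampler, "mismatch",
                               levels = 0, n_network_draws = 1, n_trials = 3,
                               seed = 5)
  lvl0 <- res[res$level == 0 & res$network_seed == res$network_seed[1], ]
  expect_equal(sort(base$mse), sort(lvl0$mse[seq_len(3)]), tolerance = 1e-15)

  expect_error(run_robustness_suite(net, teach, sampler, "mismatch",
                                    levels = numeric(0)), "non-empty")
})

test_that("rank-sum p-values agree with full enumeration for small samples", {
  # oracle: enumerate all C(n1+n2, n1) group assignments of the pooled
  # ranks and tabulate the exact U distribution
  exact_u_p <- function(a, b) {
    pooled <- c(a, b)
    n1 <- length(a)
    combos <- combn(length(pooled), n1)
    r <- rank(pooled)
    us <- apply(combos, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  }
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  expect_equal(exact_u_p(a, b), 0.1)
  expect_equal(compare_distributions(a, b)$p_rank_sum, 0.1)

  set.seed(9)
  for (i in 1:5) {
    a <- runif(sample(3:8, 1))
    b <- runif(sample(3:8, 1)) + runif(1, -0.3, 0.3)
    expect_equal(compare_distributions(a, b)$p_rank_sum, exact_u_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("identical and degenerate samples are handled", {
  out <- compare_distributions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(out$p_rank_sum, 1)
  expect_warning(deg <- compare_distributions(rep(1, 5), rep(1, 4)), "tied")
  expect_equal(deg$p_rank_sum, 1)
  expect_error(compare_distributions(1:2, 1:5), "size >= 3")
})

test_that("the variance test detects a tenfold scale difference", {
  set.seed(10)
  a <- rnorm(50, sd = 1)
  b <- rnorm(50, sd = 10)
  expect_lt(compare_distributions(a, b)$p_levene, 0.05)
  # similar scales are not flagged
  set.seed(11)
  c1 <- rnorm(50); c2 <- rnorm(50)
  expect_gt(compare_distributions(c1, c2)$p_levene, 0.05)
})
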