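#' Simulated device mismatch
#'
#' Frozen parameter noise as measured on mixed-signal neuromorphic
#' hardware: every targeted scalar parameter `theta` is replaced by a draw
#' from `N(theta, delta * |theta|)` (standard deviation proportional to the
#' magnitude -- the linear mean--variance relationship observed on analog
#' LIF circuits; the absolute value keeps the scale positive for negative
#' weights).  Parameters exactly zero stay exactly zero.  Perturbed time
#' constants are clipped at 0.1 ms and thresholds at 1% of the
#' reset--threshold gap above reset.  Pure: the input network is not
#' modified.
#'
#' Targets: `"weights"` perturbs every weight matrix (`F`, `Omega_f`,
#' `Omega_s`, and the copied teacher `F_hat`, `D_hat`); `"thresholds"`
#' perturbs `v_thresh` per neuron; `"biases"` perturbs the resting
#' potential `v_rest` per neuron (the bias term of the membrane equation);
#' `"tau_mem"` and `"tau_syn"` perturb the membrane and both synaptic time
#' constants per neuron.
#'
#' @param net an `ads_network`.
#' @param delta mismatch level (fraction, e.g. 0.2 for 20%); the study
#'   levels are 0.05, 0.10, 0.20.
#' @param targets subset of
#'   `c("weights", "thresholds", "biases", "tau_mem", "tau_syn")`.
#' @return a perturbed copy of `net`.
#' @export
apply_mismatch <- function(net, delta,
                           targets = c("weights", "thresholds", "biases",
                                       "tau_mem", "tau_syn")) {
  stopifnot(inherits(net, "ads_network"), delta >= 0)
  targets <- match.arg(targets, several.ok = TRUE)
  mm <- function(theta) {
    out <- stats::rnorm(length(theta), theta, delta * abs(theta))
    dim(out) <- dim(theta)
    out
  }
  n <- net$n
  lif <- net$lif
  gap <- mean(lif$v_thresh) - lif$v_reset
  if ("weights" %in% targets) {
    for (nm in c("F", "Omega_f", "Omega_s", "F_hat", "D_hat")) {
      net[[nm]] <- mm(net[[nm]])
    }
  }
  if ("thresholds" %in% targets) {
    lif$v_thresh <- pmax(mm(rep_len(lif$v_thresh, n)),
                         lif$v_reset + 0.01 * gap)
  }
  if ("biases" %in% targets) {
    lif$v_rest <- mm(rep_len(lif$v_rest, n))
  }
  if ("tau_mem" %in% targets) {
    lif$tau_mem <- pmax(mm(rep_len(lif$tau_mem, n)), 1e-4)
  }
  if ("tau_syn" %in% targets) {
    lif$tau_fast <- pmax(mm(rep_len(lif$tau_fast, n)), 1e-4)
    lif$tau_slow <- pmax(mm(rep_len(lif$tau_slow, n)), 1e-4)
  }
  net$lif <- lif
  net
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Post-training weight quantisation
#'
#' Quantises a weight matrix to `bits` bits with the per-matrix rule
#' `rho = (max(W) - min(W)) / (2^bits - 1)`, `W_q = rho * round(W / rho)`
#' (rounding half away from zero).  Idempotent, and the codebook has at
#' most `2^bits` levels (for generic inputs).  A constant matrix has no
#' quantisation range and is returned unchanged with a warning.
#'
#' @param W numeric weight matrix.
#' @param bits bit depth (>= 1); the study sweeps 2--6 bits.
#' @return the quantised matrix.
#' @export
quantize_weights <- function(W, bits) {
  stopifnot(bits >= 1)
  rng <- range(W)
  if (rng[1] == rng[2]) {
    warning("constant weight matrix: no quantisation range, returned unchanged")
    return(W)
  }
  rho <- (rng[2] - rng[1]) / (2^bits - 1)
  rho * round_half_away(W / rho)
}

#' Quantise every weight matrix of an ADS network
#'
#' Applies [quantize_weights()] separately to each weight matrix
#' (per-matrix range), leaving neuron parameters untouched.
#'
#' @param net an `ads_network`.
#' @param bits bit depth.
#' @return a quantised copy of `net`.
#' @export
quantize_network <- function(net, bits) {
  for (nm in c("F", "Omega_f", "Omega_s", "F_hat", "D_hat")) {
    net[[nm]] <- quantize_weights(net[[nm]], bits)
  }
  net
}

#' Sudden neuron failure
#'
#' Describes a mid-trial silencing event: a random fraction of the
#' population has its membrane clamped to `v_reset` (emitting no spikes)
#' between two step indices.  The subset is drawn inside [simulate_ads()]
#' from the current RNG stream; `fraction = 0` reproduces the unperturbed
#' trajectory bit-exactly.
#'
#' @param fraction fraction of neurons silenced (0 < fraction < 1; the
#'   study uses 0.4).
#' @param onset,offset first and one-past-last silenced step (1-based).
#' @export
silence_spec <- function(fraction = 0.4, onset, offset) {
  if (fraction < 0 || fraction >= 1) stop("`fraction` must be in [0, 1)")
  if (offset <= onset) stop("`offset` must exceed `onset`")
  structure(list(fraction = fraction, onset = onset, offset = offset),
            class = "silence_spec")
}

#' Robustness evaluation harness
#'
#' Sweeps a perturbation grid over a trained network and records, for each
#' (level, network draw, trial), the MSE of the spiking output against the
#' teacher's output and the trial correctness.  Trials are paired across
#' levels: trial `t` uses the same seed (hence the same task sample and
#' noise draws) at every level, so level effects are not confounded with
#' sampling noise.
#'
#' Perturbations: `"mismatch"` redraws parameters per network draw
#' (`levels` are `delta` values; the study grid is 0.05/0.10/0.20),
#' `"quantise"` quantises weights (`levels` are bit depths 2--6, one
#' deterministic network per level), `"thermal"` injects membrane noise
#' per trial (`levels` are sigma values 0.01/0.05/0.10), `"ablation"`
#' silences a fraction of neurons mid-trial (`levels` are fractions, one
#' mask per network draw).
#'
#' @param net trained `ads_network`.
#' @param teacher the teacher `rate_network` (MSE reference).
#' @param task_sampler function `f(n)` returning labelled samples.
#' @param perturbation one of `"mismatch"`, `"quantise"`, `"thermal"`,
#'   `"ablation"`.
#' @param levels perturbation levels (non-empty).
#' @param n_network_draws random perturbed-network draws per level (for
#'   the stochastic perturbations).
#' @param n_trials evaluation trials (samples) per draw.
#' @param readout task readout rule.
#' @param seed master seed; every draw and trial derives from it.
#' @param silence_window `c(onset, offset)` steps for `"ablation"`.
#' @return a `data.frame` with columns `architecture`, `perturbation`,
#'   `level`, `network_seed`, `trial_seed`, `mse`, `accuracy` (one row per
#'   trial).
#' @export
run_robustness_suite <- function(net, teacher, task_sampler,
                                 perturbation = c("mismatch", "quantise",
                                                  "thermal", "ablation"),
                                 levels, n_network_draws = 10, n_trials = 10,
                                 readout = classify_xor, seed = 1,
                                 silence_window = NULL) {
  perturbation <- match.arg(perturbation)
  if (length(levels) == 0) stop("perturbation grid must be non-empty")
  if (perturbation %in% c("quantise", "thermal")) n_network_draws <- 1L
  rows <- vector("list", 0)
  for (lv in levels) {
    for (d in seq_len(n_network_draws)) {
      net_seed <- derive_seed(seed, sprintf("net-%s-%g-%d", perturbation, lv, d))
      pnet <- net
      sil <- NULL
      noise_sigma <- 0
      set.seed(net_seed)
      if (perturbation == "mismatch" && lv > 0) {
        pnet <- apply_mismatch(net, lv)
      } else if (perturbation == "quantise") {
        pnet <- quantize_network(net, lv)
      } else if (perturbation == "thermal") {
        noise_sigma <- lv
      } else if (perturbation == "ablation" && lv > 0) {
        if (is.null(silence_window)) stop("`silence_window` required for ablation")
        sil <- silence_spec(lv, silence_window[1], silence_window[2])
      }
      for (tr in seq_len(n_trials)) {
        trial_seed <- derive_seed(seed, sprintf("trial-%d", tr))
        set.seed(trial_seed)
        s <- task_sampler(1)[[1]]
        ref <- simulate_rnn(teacher, s$input)
        set.seed(derive_seed(trial_seed, sprintf("sim-%d", net_seed)))
        sim <- simulate_ads(pnet, s$input, k = 0, noise_sigma = noise_sigma,
                            silence = sil, return_raster = FALSE)
        rows[[length(rows) + 1]] <- data.frame(
          architecture = "ads", perturbation = perturbation, level = lv,
          network_seed = net_seed, trial_seed = trial_seed,
          mse = mean((sim$y_tilde$values - ref$y_hat$values)^2),
          accuracy = as.numeric(identical(readout(sim$y_tilde), s$label)))
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarise a robustness result table
#'
#' Medians and interquartile ranges of MSE and accuracy per perturbation
#' level.
#'
#' @param result data frame from [run_robustness_suite()].
#' @export
summarise_robustness <- function(result) {
  agg <- aggregate(cbind(mse, accuracy) ~ perturbation + level, result,
                   function(v) c(median = median(v),
                                 iqr = unname(diff(quantile(v, c(0.25, 0.75))))))
  data.frame(perturbation = agg$perturbation, level = agg$level,
             mse_median = agg$mse[, "median"], mse_iqr = agg$mse[, "iqr"],
             accuracy_median = agg$accuracy[, "median"],
             accuracy_iqr = agg$accuracy[, "iqr"])
}

#' Compare two MSE distributions
#'
#' Double-sided Mann--Whitney U test on location (exact for small
#' tie-free samples, as computed by [stats::wilcox.test()]) and a Levene
#' test on spread (mean-centred absolute deviations compared by one-way
#' ANOVA, via `car::leveneTest`).
#'
#' @param a,b numeric samples (each of size >= 3).
#' @return list with `p_rank_sum`, `p_levene`, and the `U` statistic.
#' @export
compare_distributions <- function(a, b) {
  if (length(a) < 3 || length(b) < 3) stop("each sample must have size >= 3")
  if (length(unique(c(a, b))) == 1) {
    warning("degenerate input: all observations tied")
    return(list(p_rank_sum = 1, p_levene = NA_real_, U = length(a) * length(b) / 2))
  }
  u <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  grp <- factor(rep(c("a", "b"), c(length(a), length(b))))
  lev <- car::leveneTest(c(a, b), grp, center = mean)
  list(p_rank_sum = u$p.value, p_levene = lev[["Pr(>F)"]][1],
       U = unname(u$statistic))
}
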