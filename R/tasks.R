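#' Temporal XOR task specification
#'
#' One-second single-channel signals at `dt = 1` ms.  The first two thirds
#' carry two Gaussian-smoothed activity bumps of magnitude +-1 and widths
#' drawn uniformly from 66--157 ms, placed at random without overlap (20 ms
#' margin); the last third carries a single smoothed target bump whose sign
#' is +1 when the input signs differ and -1 when they agree.
#'
#' @param duration total signal duration (s).
#' @param dt sample step (s).
#' @param input_frac fraction of the signal holding the input bumps.
#' @param width_range bump-width range (s), drawn uniformly.
#' @param smooth_sd Gaussian smoothing width (s).
#' @param margin minimum gap between the two input bumps (s).
#' @param target_width width of the target bump (s), centred in the target
#'   window.
#' @return an `xor_spec` list.
#' @export
xor_spec <- function(duration = 1, dt = 0.001, input_frac = 2 / 3,
                     width_range = c(0.066, 0.157), smooth_sd = 0.010,
                     margin = 0.020, target_width = 0.120) {
  spec <- list(duration = duration, dt = dt, input_frac = input_frac,
               width_range = width_range, smooth_sd = smooth_sd,
               margin = margin, target_width = target_width)
  win <- floor(duration * input_frac / dt)
  if (2 * ceiling(width_range[2] / dt) + ceiling(margin / dt) > win) {
    stop("two maximal bumps do not fit disjointly in the input window")
  }
  structure(spec, class = "xor_spec")
}

gauss_smooth <- function(x, sd_steps) {
  if (sd_steps <= 0) return(x)
  half <- ceiling(4 * sd_steps)
  kern <- stats::dnorm(-half:half, sd = sd_steps)
  kern <- kern / sum(kern)
  n <- length(x)
  padded <- c(numeric(half), x, numeric(half))
  out <- stats::convolve(padded, rev(kern), type = "filter")
  out[seq_len(n)]
}

#' Generate one temporal XOR sample
#'
#' @param spec an [xor_spec()].
#' @return a list (class `labeled_sample`) with `input` and `target`
#'   `time_series`, `label` (+1/-1), and the drawn `signs`.
#' @examples
#' set.seed(1)
#' s <- generate_xor_sample()
#' s$label
#' @export
generate_xor_sample <- function(spec = xor_spec()) {
  T <- round(spec$duration / spec$dt)
  win <- floor(T * spec$input_frac)
  w <- round(stats::runif(2, spec$width_range[1], spec$width_range[2]) / spec$dt)
  signs <- sample(c(-1, 1), 2, replace = TRUE)
  m <- round(spec$margin / spec$dt)
  # place two disjoint bumps: split the free slack over three gaps
  slack <- win - sum(w) - m
  cuts <- sort(round(stats::runif(2, 0, slack)))
  s1 <- cuts[1] + 1
  s2 <- cuts[1] + w[1] + m + (cuts[2] - cuts[1]) + 1
  input <- numeric(T)
  input[s1:(s1 + w[1] - 1)] <- signs[1]
  input[s2:(s2 + w[2] - 1)] <- signs[2]
  label <- if (signs[1] != signs[2]) 1 else -1
  target <- numeric(T)
  tw <- round(spec$target_width / spec$dt)
  t_start <- win + floor((T - win - tw) / 2) + 1
  target[t_start:(t_start + tw - 1)] <- label
  sd_steps <- spec$smooth_sd / spec$dt
  structure(list(input = time_series(gauss_smooth(input, sd_steps), spec$dt),
                 target = time_series(gauss_smooth(target, sd_steps), spec$dt),
                 label = label, signs = signs),
            class = "labeled_sample")
}

#' Task sampler for the temporal XOR task
#'
#' @param spec an [xor_spec()].
#' @return a function `f(n)` returning a list of `n` samples, suitable for
#'   [train_rnn()], [train_ads()] and [evaluate_ads()].
#' @export
xor_task_sampler <- function(spec = xor_spec()) {
  force(spec)
  function(n) lapply(seq_len(n), function(i) generate_xor_sample(spec))
}

#' Threshold readout for the XOR task
#'
#' Classifies by the first +-0.5 threshold crossing of the single output
#' channel inside the target window (the last `1 - input_frac` of the
#' signal): +1 if the output exceeds +0.5 before ever crossing -0.5, -1
#' symmetrically, and 0 (an abstention, counted incorrect) if neither
#' threshold is crossed.
#'
#' @param y single-channel output `time_series`.
#' @param threshold readout threshold.
#' @param input_frac fraction of the signal excluded as the input window.
#' @return +1, -1 or 0.
#' @export
classify_xor <- function(y, threshold = 0.5, input_frac = 2 / 3) {
  v <- y$values[1, ]
  win <- (floor(length(v) * input_frac) + 1):length(v)
  v <- v[win]
  up <- which(v > threshold)[1]
  dn <- which(v < -threshold)[1]
  if (is.na(up) && is.na(dn)) return(0)
  if (is.na(dn) || (!is.na(up) && up < dn)) 1 else -1
}

#' Butterworth filterbank specification
#'
#' 16 band-pass channels of 2nd-order Butterworth filters with centre
#' frequencies evenly spaced 0.4--2.8 kHz (channel `c` centred at
#' `400 + 160 c` Hz, `c = 0..15`), full-wave rectification with `abs`, and
#' a 2nd-order Butterworth low-pass at 0.3 kHz estimating the
#' instantaneous power per band.  Filters are applied causally
#' (single-pass), as a real-time front-end would.
#'
#' @param n_channels number of bands.
#' @param f_lo,f_hi first and last centre frequency (Hz).
#' @param order band-pass (and low-pass) filter order.
#' @param lp_cutoff envelope low-pass cutoff (Hz).
#' @param fs waveform sample rate (Hz); must exceed twice the top band
#'   edge.
#' @param dt_out output sample step (s) after downsampling.
#' @export
filterbank_spec <- function(n_channels = 16, f_lo = 400, f_hi = 2800,
                            order = 2, lp_cutoff = 300, fs = 16000,
                            dt_out = 0.001) {
  centres <- seq(f_lo, f_hi, length.out = n_channels)
  bw <- diff(centres[1:2])
  if (any(diff(centres) <= 0)) stop("centre frequencies must increase")
  if (max(centres) + bw / 2 >= fs / 2) stop("top band edge is above Nyquist")
  structure(list(n_channels = n_channels, centres = centres, bandwidth = bw,
                 order = order, lp_cutoff = lp_cutoff, fs = fs,
                 dt_out = dt_out),
            class = "filterbank_spec")
}

#' Filterbank features of a waveform
#'
#' Band-pass each channel, rectify with `abs`, low-pass, and downsample to
#' the network step.  Deterministic, and linear up to the rectifier.
#'
#' @param waveform numeric vector sampled at `spec$fs`.
#' @param spec a [filterbank_spec()].
#' @return a `time_series` with `n_channels` channels at `dt_out`.
#' @export
filterbank_features <- function(waveform, spec = filterbank_spec()) {
  dec <- round(spec$fs * spec$dt_out)
  if (length(waveform) < 4 * dec) {
    stop("waveform too short for filter warm-up")
  }
  nyq <- spec$fs / 2
  lp <- signal::butter(spec$order, spec$lp_cutoff / nyq, type = "low")
  rows <- lapply(spec$centres, function(fc) {
    band <- c(fc - spec$bandwidth / 2, fc + spec$bandwidth / 2) / nyq
    bp <- signal::butter(spec$order, band, type = "pass")
    env <- signal::filter(lp, abs(signal::filter(bp, waveform)))
    as.numeric(env)[seq(dec, length(waveform), by = dec)]
  })
  time_series(do.call(rbind, rows), dt = spec$dt_out)
}

coloured_noise <- function(n, fs, cutoff = 4000) {
  lp <- signal::butter(2, cutoff / (fs / 2), type = "low")
  as.numeric(signal::filter(lp, stats::rnorm(n)))
}

#' Mix a signal with noise at a given SNR
#'
#' Scales `noise` so that `10 log10(P_signal / P_noise)` equals `snr_db`,
#' then adds it to the signal.
#'
#' @param signal_wave,noise numeric waveforms of equal length.
#' @param snr_db target signal-to-noise ratio (dB).
#' @export
mix_snr <- function(signal_wave, noise, snr_db = 10) {
  p_sig <- mean(signal_wave^2)
  p_noise <- mean(noise^2)
  if (p_noise == 0) return(signal_wave)
  signal_wave + noise * sqrt(p_sig / (p_noise * 10^(snr_db / 10)))
}

#' Synthetic keyword waveform (stand-in audio fixture)
#'
#' A synthetic substitute for a spoken wake-phrase corpus: the positive
#' class is a stereotyped sequence of three formant-like chirps
#' (band-limited tones with Hann amplitude envelopes, 0.6--2.4 kHz)
#' embedded in coloured noise at 10 dB SNR; the negative class is either
#' coloured noise alone or the same chirps in shuffled order.  The target
#' is a smooth box, high during and shortly after the keyword.  Fixed
#' length 5 s.  This generator emulates the spectro-temporal structure of
#' keyword audio, not real speech.
#'
#' @param class `"positive"` or `"negative"`.
#' @param duration waveform duration (s).
#' @param fs sample rate (Hz).
#' @param snr_db keyword-to-noise ratio (dB).
#' @param dt_target sample step of the returned target signal (s).
#' @return list with `wave`, `fs`, `label` (+1/-1), and `target`
#'   (`time_series`).
#' @export
synthetic_keyword <- function(class = c("positive", "negative"),
                              duration = 5, fs = 16000, snr_db = 10,
                              dt_target = 0.001) {
  class <- match.arg(class)
  n <- round(duration * fs)
  noise <- coloured_noise(n, fs)
  chirp_f <- c(600, 1600, 1000)     # canonical formant sequence
  chirp_len <- round(0.25 * fs)
  onset <- round(stats::runif(1, 0.5, duration - 2) * fs)
  order <- seq_along(chirp_f)
  has_chirps <- TRUE
  if (class == "negative") {
    if (stats::runif(1) < 0.5) {
      has_chirps <- FALSE
    } else {
      repeat {
        order <- sample(order)
        if (!identical(order, seq_along(chirp_f))) break
      }
    }
  }
  wave <- numeric(n)
  kw_end <- onset
  if (has_chirps) {
    env <- 0.5 * (1 - cos(2 * pi * seq_len(chirp_len) / chirp_len))
    for (j in seq_along(order)) {
      f0 <- chirp_f[order[j]]
      start <- onset + (j - 1) * round(1.2 * chirp_len)
      idx <- start + seq_len(chirp_len)
      wave[idx] <- wave[idx] +
        env * sin(2 * pi * f0 * idx / fs + 2 * pi * stats::runif(1))
    }
    kw_end <- onset + 3 * round(1.2 * chirp_len)
  }
  mixed <- if (has_chirps) mix_snr(wave, noise, snr_db) else noise
  mixed <- mixed / max(abs(mixed))
  T <- round(duration / dt_target)
  target <- numeric(T)
  if (class == "positive") {
    hi <- round(c(onset / fs, kw_end / fs + 0.5) / dt_target)
    target[max(hi[1], 1):min(hi[2], T)] <- 1
    target <- gauss_smooth(target, 0.05 / dt_target)
  }
  list(wave = mixed, fs = fs, label = if (class == "positive") 1 else -1,
       target = time_series(target, dt_target))
}

#' Keyword readout: integrate the gated output
#'
#' Integrates the output over the steps where it exceeds `gate`, and
#' reports the positive class when that integral reaches
#' `integral_threshold` (chosen on a validation set with
#' [select_integral_threshold()]).
#'
#' @param y single-channel output `time_series`.
#' @param integral_threshold decision threshold on the integral (s).
#' @param gate gating level on the output.
#' @return +1 or -1.
#' @export
classify_integral <- function(y, integral_threshold, gate = 0.5) {
  if (gated_integral(y, gate) >= integral_threshold) 1 else -1
}

#' @rdname classify_integral
#' @export
gated_integral <- function(y, gate = 0.5) {
  v <- y$values[1, ]
  sum(v[v > gate]) * y$dt
}

#' Choose the integral threshold on a validation set
#'
#' Exhaustively scans split points between sorted validation integrals and
#' returns the midpoint of the best split (ties broken toward the lowest
#' threshold).
#'
#' @param integrals gated integrals of the validation outputs.
#' @param labels matching +1/-1 labels; both classes must be present.
#' @return the selected scalar threshold.
#' @export
select_integral_threshold <- function(integrals, labels) {
  if (length(unique(labels)) < 2) {
    stop("validation set must contain both classes")
  }
  o <- order(integrals)
  x <- integrals[o]; l <- labels[o]
  cand <- c(x[1] - 1, (x[-length(x)] + x[-1]) / 2, x[length(x)] + 1)
  acc <- vapply(cand, function(th) mean((integrals >= th) * 2 - 1 == labels), 0)
  cand[which.max(acc)]
}
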