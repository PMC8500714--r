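# LFP preprocessing, Morse-wavelet time-frequency analysis, evoked and
# induced power with trial-count-matched baselines, beta-band analytic
# signal, and spike-field coupling via the pairwise phase consistency
# (PPC) estimator.

#' Preprocess a raw LFP trace
#'
#' Anti-aliased downsampling to 2 kHz (a warning is issued when the input
#' rate is below 4 kHz, in which case the trace is left at its native
#' rate if at or below 2 kHz), local linear detrending (1 s windows,
#' 50% overlap, triangular blending), line-noise removal by sinusoid
#' regression at the mains frequency and harmonics, and automated
#' artifact censoring: samples whose absolute z-score exceeds the
#' threshold mark an artifact, and the trace from 2.5 s before to 2.5 s
#' after each artifact is set to NA.
#'
#' @param raw numeric voltage trace.
#' @param fs sampling rate (Hz).
#' @param fs_out target rate (default 2000).
#' @param mains_hz line frequency (default 60), with harmonics up to
#'   Nyquist.
#' @param artifact_z artifact threshold in robust z-units (default 6).
#' @param detrend_window_s local detrend window (default 1).
#' @return list: `trace` (NA where censored), `fs`, `n_artifacts`.
#' @export
preprocess_lfp <- function(raw, fs, fs_out = 2000, mains_hz = 60,
                           artifact_z = 6, detrend_window_s = 1) {
  if (fs < 2 * fs_out)
    warning("input sampling rate below ", 2 * fs_out,
            " Hz; downsampling headroom is limited")
  if (fs > fs_out) {
    x <- fft_lowpass(raw, fs, 0.45 * fs_out)
    t_in <- (seq_along(x) - 1) / fs
    n_out <- floor(max(t_in) * fs_out) + 1
    t_out <- (seq_len(n_out) - 1) / fs_out
    x <- interp1(t_in, x, t_out)
    fs <- fs_out
  } else x <- raw
  x <- local_detrend(x, fs, detrend_window_s)
  x <- remove_line_noise(x, fs, mains_hz)
  z <- (x - stats::median(x)) / stats::mad(x)
  bad <- which(abs(z) > artifact_z)
  n_art <- 0L
  if (length(bad)) {
    n_art <- length(bad)
    pad <- round(2.5 * fs)
    mask <- rep(FALSE, length(x))
    for (b in bad) mask[max(1, b - pad):min(length(x), b + pad)] <- TRUE
    x[mask] <- NA_real_
  }
  list(trace = x, fs = fs, n_artifacts = n_art)
}

# Zero-phase FFT low-pass with a 10% cosine rolloff.
fft_lowpass <- function(x, fs, f_cut) {
  xp <- fft_pad(x)
  n_orig <- attr(xp, "n_orig")
  x <- as.numeric(xp)
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  gain <- rep(1, n)
  roll <- f > f_cut * 0.9 & f < f_cut
  gain[f >= f_cut] <- 0
  gain[roll] <- 0.5 * (1 + cos(pi * (f[roll] - 0.9 * f_cut) / (0.1 * f_cut)))
  (Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n)[seq_len(n_orig)]
}

# Overlapping-window linear detrend with triangular blending weights.
local_detrend <- function(x, fs, window_s = 1) {
  n <- length(x)
  w <- max(8L, round(window_s * fs))
  step <- max(1L, w %/% 2)
  pred <- numeric(n); wt <- numeric(n)
  starts <- unique(c(seq(1, max(1, n - w + 1), by = step), max(1, n - w + 1)))
  for (s in starts) {
    e <- min(n, s + w - 1)
    idx <- s:e
    tt <- idx - mean(idx)
    fitv <- mean(x[idx]) + (sum(tt * x[idx]) / sum(tt^2)) * tt
    tri <- 1 - abs(idx - mean(idx)) / (length(idx) / 2 + 1)
    pred[idx] <- pred[idx] + fitv * tri
    wt[idx] <- wt[idx] + tri
  }
  x - pred / pmax(wt, 1e-12)
}

# Remove mains sinusoids (and harmonics) by least-squares regression.
remove_line_noise <- function(x, fs, mains_hz = 60) {
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  harmonics <- seq(mains_hz, fs / 2 - 1, by = mains_hz)
  for (f0 in harmonics) {
    C <- cos(2 * pi * f0 * t); S <- sin(2 * pi * f0 * t)
    x <- x - C * sum(C * x) * 2 / n - S * sum(S * x) * 2 / n
  }
  x
}

#' Generalized Morse wavelet transform
#'
#' Analytic continuous wavelet transform with a generalized Morse wavelet
#' (symmetry parameter gamma, time-bandwidth product `P^2 = beta*gamma`),
#' evaluated in the frequency domain with the wavelet peak normalised to
#' 2, so a unit-amplitude sinusoid at a bin's centre frequency yields
#' unit-magnitude coefficients.
#'
#' @param x numeric trace (NAs are linearly bridged and the affected
#'   coefficients re-masked).
#' @param fs sampling rate (Hz).
#' @param freqs centre frequencies (Hz); default 30 log-spaced points
#'   from 4 to 100 Hz.
#' @param gamma symmetry parameter (default 3).
#' @param tb time-bandwidth product `P^2` (default 20).
#' @return complex matrix `[time x frequency]`, attribute `freqs`.
#' @export
morse_cwt <- function(x, fs, freqs = morse_freqs(), gamma = 3, tb = 20) {
  beta <- tb / gamma
  na_mask <- is.na(x)
  if (any(na_mask)) {
    idx <- which(!na_mask)
    x <- interp1(idx, x[idx], seq_along(x))
  }
  xp <- fft_pad(x)
  n_orig <- attr(xp, "n_orig")
  x <- as.numeric(xp)
  n <- length(x)
  X <- stats::fft(x)
  om <- 2 * pi * (seq_len(n) - 1) / n      # radian frequency per sample
  om[om > pi] <- 0                          # keep positive frequencies only
  wp <- (beta / gamma)^(1 / gamma)          # wavelet peak frequency
  lognorm <- (beta / gamma) * (1 + log(gamma / beta))  # log((e*gamma/beta)^(beta/gamma))
  out <- matrix(0i, n_orig, length(freqs))
  for (k in seq_along(freqs)) {
    s <- wp / (2 * pi * freqs[k] / fs)      # scale in samples
    w <- s * om
    psi <- numeric(n)
    pos <- w > 0
    psi[pos] <- 2 * exp(lognorm + beta * log(w[pos]) - w[pos]^gamma)
    out[, k] <- (stats::fft(X * psi, inverse = TRUE) / n)[seq_len(n_orig)]
  }
  if (any(na_mask)) out[na_mask, ] <- NA
  attr(out, "freqs") <- freqs
  out
}

#' Default analysis frequency grid: 30 log-spaced points, 4-100 Hz
#' @export
morse_freqs <- function() exp(seq(log(4), log(100), length.out = 30))

#' Evoked and induced power across trials
#'
#' Evoked power is the squared magnitude of the complex across-trial mean
#' of aligned wavelet coefficients (phase-locked component); induced
#' power is the across-trial mean squared magnitude minus the evoked
#' power.  `evoked + induced = total mean power` by construction.
#'
#' @param coeffs list per trial of aligned complex `[time x freq]`
#'   matrices of equal size.
#' @return list: `evoked`, `induced`, `total` (matrices), `n_trials`.
#' @export
evoked_induced_power <- function(coeffs) {
  n <- length(coeffs)
  if (n < 1) stop("no trials", call. = FALSE)
  mean_c <- Reduce(`+`, coeffs) / n
  evoked <- Mod(mean_c)^2
  total <- Reduce(`+`, lapply(coeffs, function(z) Mod(z)^2)) / n
  list(evoked = evoked, induced = total - evoked, total = total, n_trials = n)
}

#' Trial-count-matched baseline power distribution
#'
#' The expected evoked power of zero-mean noise falls like 1/n with the
#' trial count n, so power maps computed from different trial counts are
#' not comparable after naive baseline division.  This draws `n` trials
#' without replacement from the session's baseline-epoch coefficients
#' (with replacement, flagged, when `n` exceeds the available trials),
#' computes evoked and induced power, averages over the baseline epoch,
#' and repeats `n_rep` times; the across-repetition mean is the matched
#' baseline.
#'
#' @param baseline_coeffs list per trial of `[time x freq]` complex
#'   baseline-epoch coefficients (all session trials, any type).
#' @param n trial count to match.
#' @param n_rep repetitions (default 100).
#' @param seed optional integer seed.
#' @return list: `evoked`, `induced` (per-frequency vectors), `flagged`.
#' @export
baseline_power_distribution <- function(baseline_coeffs, n, n_rep = 100,
                                        seed = NULL) {
  avail <- length(baseline_coeffs)
  replace <- n > avail
  if (replace) warning("requested trial count exceeds available baseline trials; sampling with replacement")
  with_seed(seed, {
    ev <- ind <- 0
    for (r in seq_len(n_rep)) {
      pick <- sample.int(avail, n, replace = replace)
      p <- evoked_induced_power(baseline_coeffs[pick])
      ev <- ev + colMeans(p$evoked) / n_rep
      ind <- ind + colMeans(p$induced) / n_rep
    }
    list(evoked = ev, induced = ind, flagged = replace)
  })
}

#' Normalize power maps by a trial-count-matched baseline
#'
#' @param power result of [evoked_induced_power()].
#' @param baseline result of [baseline_power_distribution()] computed at
#'   the same trial count.
#' @return `power` with `evoked` and `induced` divided, per frequency, by
#'   the matched baseline means.
#' @export
baseline_normalize <- function(power, baseline) {
  power$evoked <- sweep(power$evoked, 2, baseline$evoked, `/`)
  power$induced <- sweep(power$induced, 2, baseline$induced, `/`)
  power
}

#' Beta-band analytic signal
#'
#' Zero-phase frequency-domain band-pass over 13-30 Hz (2 Hz cosine
#' edges) combined with the Hilbert transform: positive in-band
#' frequencies are doubled, all others zeroed, and the inverse FFT
#' returns the complex analytic signal whose modulus is the beta
#' envelope and argument the beta phase.
#'
#' @param x numeric trace (NAs bridged and re-masked).
#' @param fs sampling rate (Hz).
#' @param band pass band (Hz), default `c(13, 30)`.
#' @param edge_hz taper width (default 2).
#' @return complex vector, attributes `fs`, `band`.
#' @export
beta_band_analytic <- function(x, fs, band = c(13, 30), edge_hz = 2) {
  na_mask <- is.na(x)
  if (any(na_mask)) {
    idx <- which(!na_mask)
    x <- interp1(idx, x[idx], seq_along(x))
  }
  xp <- fft_pad(x)
  n_orig <- attr(xp, "n_orig")
  x <- as.numeric(xp)
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n          # one-sided axis; f > fs/2 = negative
  gain <- numeric(n)
  posf <- f <= fs / 2
  g <- numeric(n)
  inb <- posf & f >= band[1] & f <= band[2]
  g[inb] <- 1
  lo_edge <- posf & f >= band[1] - edge_hz & f < band[1]
  g[lo_edge] <- 0.5 * (1 + cos(pi * (band[1] - f[lo_edge]) / edge_hz))
  hi_edge <- posf & f > band[2] & f <= band[2] + edge_hz
  g[hi_edge] <- 0.5 * (1 + cos(pi * (f[hi_edge] - band[2]) / edge_hz))
  out <- (stats::fft(stats::fft(x) * (2 * g), inverse = TRUE) / n)[seq_len(n_orig)]
  if (any(na_mask)) out[na_mask] <- NA
  attr(out, "fs") <- fs
  attr(out, "band") <- band
  out
}

#' Spike-triggered phases from a complex time-frequency map
#'
#' @param coeffs complex `[time x freq]` matrix (or complex vector for a
#'   single band).
#' @param fs sampling rate of the coefficient rows.
#' @param t0 time of the first row (session clock).
#' @param spike_times spike times (session clock).
#' @return matrix `[spike x freq]` of phases (rad); NA outside the trace
#'   or where coefficients are censored.
#' @export
spike_phases <- function(coeffs, fs, t0, spike_times) {
  if (is.null(dim(coeffs))) coeffs <- matrix(coeffs, ncol = 1)
  idx <- round((spike_times - t0) * fs) + 1
  ok <- idx >= 1 & idx <= nrow(coeffs)
  ph <- matrix(NA_real_, length(spike_times), ncol(coeffs))
  ph[ok, ] <- Arg(coeffs[idx[ok], , drop = FALSE])
  ph
}

#' Pairwise phase consistency time course
#'
#' Vinck's pairwise phase consistency: for each time-frequency bin, the
#' dot products of spike-triggered unit phase vectors are averaged over
#' all pairs of spikes in the bin lying on *different* trials of the same
#' type, then over all trial pairs.  Each bin collects spikes that
#' precede the time point by at most 10 cycles of its frequency, capped
#' at 1.5 s; time points are spaced 50 ms apart by convention.  The
#' estimator is unbiased under phase independence and estimates the
#' squared population resultant length (so a sinusoidal rate modulation
#' of depth m gives PPC near `(m/2)^2`).
#'
#' @param trial_spikes list per trial: `t` (spike times relative to the
#'   alignment event) and `phase` (`[spike x freq]` matrix).
#' @param time_points bin right-edges (s, relative), e.g.
#'   `seq(-0.3, 0.3, by = 0.05)`.
#' @param freqs frequencies (Hz) matching the phase columns.
#' @param n_cycles window length in cycles (default 10).
#' @param max_window_s window cap (default 1.5 s).
#' @return a `ppc_spectrogram` list: `ppc` (`[time x freq]`),
#'   `n_pairs` (usable trial pairs per bin), `time_points`, `freqs`.
#' @export
ppc_timecourse <- function(trial_spikes, time_points, freqs,
                           n_cycles = 10, max_window_s = 1.5) {
  nT <- length(time_points); nF <- length(freqs); nTr <- length(trial_spikes)
  ppc <- matrix(NA_real_, nT, nF)
  npair <- matrix(0L, nT, nF)
  for (fi in seq_len(nF)) {
    w <- min(n_cycles / freqs[fi], max_window_s)
    for (ti in seq_len(nT)) {
      tp <- time_points[ti]
      C <- S <- Nn <- numeric(nTr)
      for (tr in seq_len(nTr)) {
        st <- trial_spikes[[tr]]
        sel <- st$t > tp - w & st$t <= tp & !is.na(st$phase[, fi])
        ph <- st$phase[sel, fi]
        C[tr] <- sum(cos(ph)); S[tr] <- sum(sin(ph)); Nn[tr] <- length(ph)
      }
      use <- which(Nn > 0)
      if (length(use) < 2) next
      tot <- 0; np <- 0L
      for (a in seq_along(use)[-length(use)]) for (b in (a + 1):length(use)) {
        i <- use[a]; j <- use[b]
        tot <- tot + (C[i] * C[j] + S[i] * S[j]) / (Nn[i] * Nn[j])
        np <- np + 1L
      }
      ppc[ti, fi] <- tot / np
      npair[ti, fi] <- np
    }
  }
  structure(list(ppc = ppc, n_pairs = npair, time_points = time_points,
                 freqs = freqs),
            class = "ppc_spectrogram")
}

#' Convert PPC to peak-to-trough firing-rate modulation
#'
#' Under a sinusoidal rate modulation `r(theta) = r0 * (1 + m*cos(theta))`
#' the spike-phase density has resultant length `m/2`, and PPC estimates
#' the squared resultant; hence `m = 2*sqrt(ppc)` and the peak-to-trough
#' modulation is `(1+m)/(1-m) - 1 = 2m/(1-m)`.
#'
#' @param ppc non-negative PPC value(s).
#' @return modulation as a fraction (0.30 means 30%).
#' @export
ppc_to_modulation <- function(ppc) {
  if (any(ppc < 0, na.rm = TRUE)) stop("ppc must be >= 0", call. = FALSE)
  m <- 2 * sqrt(ppc)
  if (any(m >= 1, na.rm = TRUE)) stop("implied depth m >= 1", call. = FALSE)
  2 * m / (1 - m)
}
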