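# Synthetic LFP: 1/f^chi background noise plus a beta-band oscillation
# whose amplitude envelope is suppressed between movement onset and
# feedback on every trial (movement-related beta desynchronization).  The
# oscillation has a deterministic phase, returned as ground truth so that
# spike generators can phase-lock to it.

#' Generate a synthetic LFP trace
#'
#' @param config a [task_config()] (only used for the seed default).
#' @param trial_table trial table from [gen_trial_schedule()].
#' @param fs sampling rate (Hz), default 1000.
#' @param beta_freq_hz beta carrier frequency, default 20.
#' @param beta_amp baseline beta amplitude (a.u.), default 1.
#' @param suppression multiplicative amplitude factor during movement
#'   (movement onset to feedback, 100 ms cosine ramps); default 0.5.
#'   1 means no suppression.
#' @param noise_sd SD of the 1/f background (a.u.), default 1.
#' @param noise_exponent chi of the 1/f^chi power spectrum, default 1.5.
#' @param seed optional integer seed.
#' @return list with `trace` (numeric), `fs`, `t0` (time of first sample),
#'   `beta_phase` (function of session time -> phase in rad),
#'   `envelope` (function of session time -> true beta amplitude),
#'   `beta_freq_hz`.
#' @export
gen_lfp <- function(config, trial_table, fs = 1000, beta_freq_hz = 20,
                    beta_amp = 1, suppression = 0.5, noise_sd = 1,
                    noise_exponent = 1.5, seed = NULL) {
  seed <- seed %||% child_seed(config$seed, 4)
  t_end <- max(trial_table$t_feedback) + 1.5
  n <- ceiling(t_end * fs)
  t <- (seq_len(n) - 1) / fs
  phi0 <- with_seed(seed, stats::runif(1, 0, 2 * pi))
  envelope <- make_envelope(trial_table, beta_amp, suppression)
  beta_phase <- function(tt) (2 * pi * beta_freq_hz * tt + phi0) %% (2 * pi)
  beta <- envelope(t) * cos(2 * pi * beta_freq_hz * t + phi0)
  noise <- with_seed(child_seed(seed, 1),
                     one_over_f_noise(n, fs, noise_exponent, noise_sd))
  list(trace = beta + noise, fs = fs, t0 = 0, beta_phase = beta_phase,
       envelope = envelope, beta_freq_hz = beta_freq_hz)
}

# Piecewise envelope: beta_amp at rest, beta_amp * suppression between each
# trial's movement onset and feedback, with 100 ms raised-cosine ramps.
make_envelope <- function(trial_table, beta_amp, suppression) {
  moves <- trial_table$t_move[!is.na(trial_table$t_move)]
  fbs <- trial_table$t_feedback[!is.na(trial_table$t_move)]
  ramp <- 0.1
  function(tt) {
    a <- rep(1, length(tt))
    for (k in seq_along(moves)) {
      lo <- moves[k]; hi <- fbs[k]
      inside <- tt > lo - ramp & tt < hi + ramp
      if (!any(inside)) next
      u <- tt[inside]
      depth <- rep(1, length(u))
      depth[u >= lo & u <= hi] <- suppression
      rise <- u > lo - ramp & u < lo
      depth[rise] <- 1 + (suppression - 1) * (1 + cos(pi * (lo - u[rise]) / ramp)) / 2
      fall <- u > hi & u < hi + ramp
      depth[fall] <- 1 + (suppression - 1) * (1 + cos(pi * (u[fall] - hi) / ramp)) / 2
      a[inside] <- pmin(a[inside], depth)
    }
    beta_amp * a
  }
}

# Gaussian noise with power spectral density proportional to 1/f^chi,
# generated by spectral shaping in the Fourier domain and rescaled to the
# requested standard deviation.
one_over_f_noise <- function(n, fs, chi, sd_out) {
  n2 <- stats::nextn(n)                 # fast FFT length
  white <- stats::rnorm(n2)
  spec <- stats::fft(white)
  f <- c(0, seq_len(n2 - 1)) * fs / n2
  f <- pmin(f, fs - f)                  # two-sided frequency axis
  shape <- c(0, (f[-1])^(-chi / 2))     # amplitude scaling, kill DC
  x <- Re(stats::fft(spec * shape, inverse = TRUE))[seq_len(n)] / n2
  x * sd_out / stats::sd(x)
}
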