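# Synthetic cursor trajectories.  Movements are built from minimum-jerk
# segments: a horizontal reach after the go cue, and for turn trials a
# vertical segment starting at turn onset.  On Impromptu Turn trials the
# in-flight horizontal motion is smoothly braked from turn onset, which
# produces the characteristic dip in total speed around the turn.

#' Generate one trial's cursor trajectory
#'
#' Samples a 2D cursor path at `fs` Hz from `t_fix - 0.6 s` to
#' `t_feedback + 0.3 s` on the session clock.  The path is stationary at
#' fixation, follows a minimum-jerk horizontal reach beginning at the
#' trial's movement-onset time, and, on turn trials, a minimum-jerk
#' vertical segment beginning at turn onset.  `direction == "lateral"`
#' mirrors the horizontal axis.  Gaussian position noise of SD
#' `config$pos_noise_sd` is added to both coordinates.
#'
#' @param trial one row of the trial table from [gen_trial_schedule()].
#' @param config a [task_config()].
#' @param seed optional integer seed.
#' @param fs sampling rate (Hz), default 100.
#' @return `data.frame` with columns `trial_id`, `t`, `x`, `y`.
#' @export
gen_trajectory <- function(trial, config, seed = NULL, fs = 100) {
  t <- seq(trial$t_fix - 0.6, trial$t_feedback + 0.3, by = 1 / fs)
  xy <- trajectory_closed_form(t, trial, config)
  with_seed(seed, {
    if (config$pos_noise_sd > 0) {
      xy$x <- xy$x + stats::rnorm(length(t), sd = config$pos_noise_sd)
      xy$y <- xy$y + stats::rnorm(length(t), sd = config$pos_noise_sd)
    }
    data.frame(trial_id = trial$trial_id, t = t, x = xy$x, y = xy$y)
  })
}

# Noise-free closed-form trajectory used both for generation and as an
# oracle in tests.
trajectory_closed_form <- function(t, trial, config) {
  Tr <- config$reach_duration_s
  Tv <- config$turn_duration_s
  D <- config$reach_dist
  x <- numeric(length(t)); y <- numeric(length(t))
  t0 <- trial$t_move
  if (trial$type == "reach") {
    x <- D * minjerk_s((t - t0) / Tr)
  } else if (trial$type == "planned") {
    Th <- Tr * trial$turn_frac
    xc <- D * trial$turn_frac
    x <- xc * minjerk_s((t - t0) / Th)
    y <- config$turn_dist * minjerk_s((t - trial$t_turn) / Tv)
  } else { # impromptu
    tt <- trial$t_turn
    Tb <- 0.18                          # horizontal braking time after turn
    full <- function(u) D * minjerk_s((u - t0) / Tr)
    dfull <- function(u) D * minjerk_ds((u - t0) / Tr) / Tr
    pre <- t <= tt
    x[pre] <- full(t[pre])
    # brake: velocity decays with a smooth quintic profile to zero
    x0 <- full(tt); v0 <- dfull(tt)
    tb <- pmin(pmax((t[!pre] - tt) / Tb, 0), 1)
    # integral of (1 - minjerk_s) velocity profile scaled to v0 over Tb
    x[!pre] <- x0 + v0 * Tb * (tb - minjerk_int(tb))
    y <- config$turn_dist * minjerk_s((t - tt) / Tv)
  }
  if (trial$direction == "lateral") x <- -x
  list(x = x, y = y)
}

# Integral of minjerk_s from 0 to s (for the braking displacement).
minjerk_int <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  10 * s^4 / 4 - 15 * s^5 / 5 + 6 * s^6 / 6
}
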