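# Event-aligned, censored, alpha-kernel-smoothed PSTHs and concatenated
# z-scored response profiles.
#
# Inter-event intervals vary from trial to trial, so spikes aligned to one
# event are censored outside the span of its neighbouring events (and
# within 500 ms of the end of the preceding trial); censored stretches are
# tracked per time point so trial averages and standard errors use only
# valid trials, never zero-filled data.

#' Event-aligned analysis windows
#'
#' Wide windows for events separated by long intervals, narrower ones for
#' movement and turn onsets (short latencies to their neighbours):
#' fixation `[-500, +300]`, instruction `[-200, +300]`, feedback
#' `[-230, +1000]`, movement `[-300, +270]`, turn `[-270, +220]` ms.
#'
#' @return named list of length-2 numeric windows (seconds).
#' @export
analysis_windows <- function() {
  list(fixation = c(-0.5, 0.3),
       instruction = c(-0.2, 0.3),
       movement = c(-0.3, 0.27),
       turn = c(-0.27, 0.22),
       feedback = c(-0.23, 1.0))
}

# Map window names to trial-table event columns.
event_column <- c(fixation = "t_fix", instruction = "t_instr", go = "t_go",
                  movement = "t_move", turncue = "t_turncue", turn = "t_turn",
                  feedback = "t_feedback")

# Ordered sequence of events present on one trial (pseudo events may have
# been injected as t_turn / t_turncue columns beforehand).
trial_event_sequence <- function(trial) {
  ev <- vapply(event_column, function(cn)
    if (!is.null(trial[[cn]])) trial[[cn]] else NA_real_, numeric(1))
  names(ev) <- names(event_column)
  ev <- ev[!is.na(ev)]
  ev[order(ev)]
}

#' Censor spikes around an alignment event
#'
#' Keeps spikes inside the open interval between the neighbouring events
#' of the alignment event, additionally removing spikes within 500 ms of
#' the end of the preceding trial.  When a neighbouring event is absent
#' the corresponding analysis-window edge is used as the bound and the
#' result is flagged.
#'
#' @param spikes numeric spike times (session clock).
#' @param trial one trial-table row.
#' @param event window name (`"fixation"`, `"instruction"`, `"movement"`,
#'   `"turn"`, `"feedback"`).
#' @param window length-2 analysis window relative to the event (s).
#' @param prev_trial_end feedback time of the preceding trial (or -Inf).
#' @return list: `kept`, `removed` (spike times), `bounds` (valid absolute
#'   interval), `flagged`.
#' @export
censor_spikes <- function(spikes, trial, event, window = analysis_windows()[[event]],
                          prev_trial_end = -Inf) {
  t_event <- trial[[event_column[[event]]]]
  if (is.null(t_event) || is.na(t_event)) stop("alignment event missing", call. = FALSE)
  ev <- trial_event_sequence(trial)
  pos <- which(names(ev) == event)[1]
  flagged <- FALSE
  lo <- if (pos > 1) ev[pos - 1] else { flagged <- TRUE; t_event + window[1] }
  hi <- if (pos < length(ev)) ev[pos + 1] else { flagged <- TRUE; t_event + window[2] }
  lo <- max(lo, prev_trial_end + 0.5)
  inwin <- spikes >= t_event + window[1] & spikes <= t_event + window[2]
  valid <- spikes > lo & spikes < hi
  list(kept = spikes[inwin & valid], removed = spikes[inwin & !valid],
       bounds = c(lo, hi), flagged = flagged)
}

#' Alpha-kernel smoothed firing rate
#'
#' Causal kernel `k(tau) = alpha^2 * tau * exp(-alpha * tau)` for
#' `tau > 0`, zero otherwise, unit mass; the rate at `t` sums the kernel
#' over spikes at `t - t_spike`, so it peaks `1/alpha` after each spike
#' and is unaffected by later spikes.
#'
#' @param spike_times numeric spike times.
#' @param grid evaluation times.
#' @param alpha kernel rate parameter (1/s), default 20.
#' @return numeric rate (Hz) on `grid`.
#' @export
alpha_kernel_rate <- function(spike_times, grid, alpha = 20) {
  if (length(spike_times) == 0) return(numeric(length(grid)))
  tau <- outer(grid, spike_times, "-")
  k <- alpha^2 * tau * exp(-alpha * tau)
  k[tau <= 0] <- 0
  rowSums(k)
}

#' Filter a series with the causal alpha kernel
#'
#' Convolves a regularly sampled series with the discretised unit-mass
#' alpha kernel (left edge padded with the first value).  Used to put
#' kinematic regressors through the same filtering as the smoothed rates.
#'
#' @param x numeric series on a regular grid.
#' @param dt grid step (s).
#' @param alpha kernel parameter (1/s).
#' @return filtered series, same length.
#' @export
alpha_filter <- function(x, dt, alpha = 20) {
  # point-sampled kernel with long support (12/alpha keeps the discrete
  # centroid within a fraction of a millisecond of the continuous 2/alpha)
  tau <- seq(0, 12 / alpha, by = dt)
  k <- alpha^2 * tau * exp(-alpha * tau)
  k <- k / sum(k)
  n <- length(x); m <- length(k)
  xp <- c(rep(x[1], m), x)
  out <- stats::filter(xp, k, sides = 1)
  as.numeric(out[(m + 1):(m + n)])
}

#' Draw surrogate event latencies for trials lacking an event
#'
#' Reach trials have no turn (and Reach/Planned trials no turn cue); to
#' compare aligned activity across types, pseudo event times are drawn
#' from the empirical donor distribution of latencies relative to
#' movement onset on trials that do have the event.
#'
#' @param n number of pseudo events.
#' @param donor_latencies latencies (s, relative to movement onset) of the
#'   real events on donor trials; must be non-empty.
#' @param seed optional integer seed.
#' @return numeric vector of sampled latencies.
#' @export
surrogate_event_times <- function(n, donor_latencies, seed = NULL) {
  donor_latencies <- donor_latencies[!is.na(donor_latencies)]
  if (length(donor_latencies) == 0) stop("empty donor distribution", call. = FALSE)
  with_seed(seed, sample(donor_latencies, n, replace = TRUE))
}

#' Inject pseudo turn-cue / turn events into a trial table
#'
#' Fills missing `t_turncue` (on Reach and Planned trials, from the
#' Impromptu turn-cue latency distribution) and missing `t_turn` (on
#' Reach trials, from the Planned + Impromptu turn-onset latency
#' distribution), all expressed relative to movement onset.
#'
#' @param trial_table trial table.
#' @param seed optional integer seed.
#' @return trial table with pseudo events filled in, plus logical columns
#'   `pseudo_turn`, `pseudo_turncue`.
#' @export
add_surrogate_events <- function(trial_table, seed = NULL) {
  tt <- trial_table
  cue_donor <- tt$t_turncue - tt$t_move
  turn_donor <- tt$t_turn - tt$t_move
  tt$pseudo_turncue <- is.na(tt$t_turncue)
  tt$pseudo_turn <- is.na(tt$t_turn)
  with_seed(seed, {
    need <- which(tt$pseudo_turncue)
    tt$t_turncue[need] <- tt$t_move[need] +
      surrogate_event_times(length(need), cue_donor)
    need <- which(tt$pseudo_turn)
    tt$t_turn[need] <- tt$t_move[need] +
      surrogate_event_times(length(need), turn_donor)
  })
  # keep event ordering sane: pseudo events beyond feedback are clipped
  tt$t_turn <- pmin(tt$t_turn, tt$t_feedback - 1e-3)
  tt$t_turncue <- pmin(tt$t_turncue, tt$t_turn - 1e-3)
  tt
}

#' Per-trial aligned smoothed rates with censor masks
#'
#' @param spikes spike times of one unit.
#' @param trial_table trial table (with pseudo events if turn-aligned
#'   windows are requested for Reach trials).
#' @param event window name.
#' @param window analysis window (s, relative).
#' @param dt grid step (s), default 0.001.
#' @param alpha kernel parameter.
#' @param warmup_s additionally censor this long a stretch after each
#'   trial's lower censoring bound (default 0).  The causal kernel needs
#'   roughly `3/alpha` to reach steady state after a censoring boundary,
#'   so rates there are biased low; analyses sensitive to rate timing
#'   (e.g. lagged regression) should exclude the warm-up.
#' @return list: `grid` (relative times), `rates` (trials x time, NA where
#'   censored), `trials` (the trial ids used).
#' @export
aligned_trial_rates <- function(spikes, trial_table, event,
                                window = analysis_windows()[[event]],
                                dt = 0.001, alpha = 20, warmup_s = 0) {
  grid <- seq(window[1], window[2], by = dt)
  col <- event_column[[event]]
  use <- which(!is.na(trial_table[[col]]))
  rates <- matrix(NA_real_, length(use), length(grid))
  for (k in seq_along(use)) {
    i <- use[k]
    trial <- trial_table[i, ]
    prev_end <- if (i > 1) trial_table$t_feedback[i - 1] else -Inf
    cen <- censor_spikes(spikes, trial, event, window, prev_end)
    t_event <- trial[[col]]
    r <- alpha_kernel_rate(cen$kept - t_event, grid, alpha)
    valid <- grid + t_event > cen$bounds[1] + warmup_s &
      grid + t_event < cen$bounds[2]
    r[!valid] <- NA_real_
    rates[k, ] <- r
  }
  list(grid = grid, rates = rates, trials = trial_table$trial_id[use])
}

#' Trial-averaged PSTH with standard errors
#'
#' Mean over valid (uncensored) trials at each time point; SE is the
#' standard error over those trials.  Time points with no valid trial are
#' NA.  A warning is issued if fewer than 2/3 of trials contribute at any
#' time point.
#'
#' @param aligned result of [aligned_trial_rates()] (possibly row-subset).
#' @param min_frac warn threshold for the valid-trial fraction, default
#'   2/3.
#' @return `data.frame` with `t`, `rate`, `se`, `n_valid`.
#' @export
build_psth <- function(aligned, min_frac = 2 / 3) {
  r <- aligned$rates
  n_valid <- colSums(!is.na(r))
  rate <- ifelse(n_valid > 0, colMeans(r, na.rm = TRUE), NA_real_)
  se <- vapply(seq_len(ncol(r)), function(j) {
    v <- r[!is.na(r[, j]), j]
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  }, numeric(1))
  if (nrow(r) > 0 && any(n_valid < min_frac * nrow(r)))
    warning("fewer than ", round(min_frac * 100), "% of trials contribute at some time points")
  data.frame(t = aligned$grid, rate = rate, se = se, n_valid = n_valid)
}

#' Unit inclusion rules
#'
#' Main analyses require at least four correct trials of each type;
#' direction-split analyses require at least four correct medial and four
#' correct lateral trials of each type.
#'
#' @param trial_table trial table.
#' @param min_trials minimum per cell, default 4.
#' @return list with logical `main` and `direction`.
#' @export
unit_inclusion <- function(trial_table, min_trials = 4) {
  tt <- trial_table[trial_table$correct, ]
  types <- c("reach", "planned", "impromptu")
  by_type <- vapply(types, function(m) sum(tt$type == m), numeric(1))
  by_cell <- outer(types, c("medial", "lateral"),
                   Vectorize(function(m, s) sum(tt$type == m & tt$direction == s)))
  list(main = all(by_type >= min_trials),
       direction = all(by_cell >= min_trials))
}

#' Concatenated z-scored response profile of one unit
#'
#' PSTHs for each trial type in each analysis window are concatenated
#' (event order: fixation, instruction, movement, turn, feedback; type
#' order: reach, planned, impromptu) and z-scored with the unit's pooled
#' mean and SD over all per-trial rate samples of all windows.  Units with
#' zero pooled SD are flagged.
#'
#' @param spikes spike times of one unit.
#' @param trial_table trial table with pseudo events (see
#'   [add_surrogate_events()]).
#' @param windows named list of analysis windows.
#' @param dt PSTH grid step (s).
#' @param alpha kernel parameter.
#' @param correct_only drop incorrect trials (default TRUE).
#' @return list: `profile` (named numeric vector, NA where censored),
#'   `segments` (data.frame event/type/t per element), `moments`
#'   (pooled mean/sd), `flagged` (zero SD), `psth` (nested list
#'   `[[event]][[type]]` of PSTH data.frames).
#' @export
response_profile <- function(spikes, trial_table, windows = analysis_windows(),
                             dt = 0.001, alpha = 20, correct_only = TRUE) {
  tt <- if (correct_only) trial_table[trial_table$correct, ] else trial_table
  types <- c("reach", "planned", "impromptu")
  all_samples <- c()
  psth <- list()
  seg_event <- seg_type <- seg_t <- c(); prof <- c()
  for (ev in c("fixation", "instruction", "movement", "turn", "feedback")) {
    ar <- aligned_trial_rates(spikes, tt, ev, windows[[ev]], dt, alpha)
    idx <- match(ar$trials, tt$trial_id)
    all_samples <- c(all_samples, ar$rates[!is.na(ar$rates)])
    psth[[ev]] <- list()
    for (m in types) {
      sub <- list(grid = ar$grid, rates = ar$rates[tt$type[idx] == m, , drop = FALSE])
      p <- suppressWarnings(build_psth(sub))
      psth[[ev]][[m]] <- p
      prof <- c(prof, p$rate)
      seg_event <- c(seg_event, rep(ev, nrow(p)))
      seg_type <- c(seg_type, rep(m, nrow(p)))
      seg_t <- c(seg_t, p$t)
    }
  }
  mu <- mean(all_samples); sdev <- stats::sd(all_samples)
  flagged <- !is.finite(sdev) || sdev < 1e-12
  z <- if (flagged) rep(NA_real_, length(prof)) else (prof - mu) / sdev
  list(profile = z,
       segments = data.frame(event = seg_event, type = seg_type, t = seg_t),
       moments = c(mean = mu, sd = sdev), flagged = flagged, psth = psth)
}
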