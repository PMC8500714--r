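# Assembly of a full synthetic session and plain-text session bundle IO.
# All times are seconds on a single session-global clock; per-event
# alignment happens downstream.  One master seed per session; each
# component (schedule, trajectories, LFP, spikes) draws from its own child
# stream so regenerating one component leaves the others unchanged.

#' Default synthetic population
#'
#' A mix of movement-like units (rates follow lagged speed/acceleration
#' with a medial direction gain after movement onset) and turn-like units
#' (acceleration-driven with trial-type gains favouring turns), plus
#' untuned units.  Fractions default to 40% movement-like, 45% turn-like,
#' 15% untuned.
#'
#' @param n_units number of units.
#' @param seed integer seed for per-unit parameter jitter.
#' @param beta_mod_depth beta phase-locking depth passed to every tuned
#'   unit.
#' @return list of [unit_spec()]s.
#' @export
default_population <- function(n_units = 20, seed = 1L, beta_mod_depth = 0.13) {
  n_mov <- round(0.40 * n_units)
  n_trn <- round(0.45 * n_units)
  n_oth <- n_units - n_mov - n_trn
  with_seed(seed, {
    specs <- c(
      lapply(seq_len(n_mov), function(i) unit_spec(
        baseline_rate_hz = stats::runif(1, 25, 45),
        beta_v = stats::runif(1, 2.0, 3.5), beta_a = stats::runif(1, 0.5, 1.5),
        lag_s = sample(c(-0.1, 0.05, 0.11, 0.19), 1),
        direction_gain = 1.3, beta_mod_depth = beta_mod_depth,
        label = "movement-like")),
      lapply(seq_len(n_trn), function(i) unit_spec(
        baseline_rate_hz = stats::runif(1, 20, 40),
        beta_v = stats::runif(1, 0.1, 0.5), beta_a = stats::runif(1, 2.5, 4.0),
        lag_s = stats::runif(1, -0.05, 0.05),
        type_gain = c(reach = 1, planned = 1.35, impromptu = 1.7),
        beta_mod_depth = beta_mod_depth, label = "turn-like")),
      lapply(seq_len(n_oth), function(i) unit_spec(
        baseline_rate_hz = stats::runif(1, 15, 35),
        label = "untuned"))
    )
    specs
  })
}

#' Generate a complete synthetic session
#'
#' Runs the full generative chain: trial schedule, per-trial trajectories,
#' session-long z-scored kinematics, LFP with movement-suppressed beta,
#' and per-unit spikes phase-locked to the beta oscillation.
#'
#' @param config a [task_config()].
#' @param unit_specs list of [unit_spec()]s (default
#'   [default_population()] with 20 units seeded from the config).
#' @param fs_lfp LFP sampling rate (Hz).
#' @param lfp_args extra arguments passed to [gen_lfp()].
#' @param with_lfp generate the LFP component (default TRUE); disabling
#'   it speeds up spike-only simulations (no beta phase locking).
#' @return a `synthetic_session` list: `trial_table`, `trajectories`
#'   (list of position data.frames), `kinematics` (z-scored
#'   `kinematics_series` list), `spikes` (list of numeric vectors),
#'   `lfp`, `session_kin` (session-long kinematic grid), and
#'   `ground_truth` (`config`, `unit_specs`, LFP envelope/phase).
#' @export
generate_session <- function(config = task_config(),
                             unit_specs = NULL,
                             fs_lfp = 1000,
                             lfp_args = list(),
                             with_lfp = TRUE) {
  unit_specs <- unit_specs %||% default_population(20, seed = child_seed(config$seed, 7))
  tt <- gen_trial_schedule(config)
  latent <- tt[, c("trial_id", "t_move", "t_turn")]
  traj <- lapply(seq_len(nrow(tt)), function(i)
    gen_trajectory(tt[i, ], config, seed = child_seed(config$seed, 100 + i)))
  # the trial table reports the operational event definitions (what the
  # detectors measure on the noise-free path); latent motion-start times
  # stay in ground_truth
  tt <- operational_events(tt, config)
  kin <- zscore_kinematics(lapply(traj, compute_kinematics))
  lfp <- if (with_lfp)
    do.call(gen_lfp, c(list(config = config, trial_table = tt, fs = fs_lfp),
                       lfp_args))
  else NULL
  skin <- session_kinematic_grid(kin, tt, fs = 100)
  spikes <- lapply(seq_along(unit_specs), function(u)
    gen_spikes(unit_specs[[u]], skin, tt, beta_phase = lfp$beta_phase,
               t_range = c(0, max(tt$t_feedback) + 1),
               seed = child_seed(config$seed, 1000 + u)))
  structure(list(trial_table = tt, trajectories = traj, kinematics = kin,
                 spikes = spikes, lfp = lfp, session_kin = skin,
                 ground_truth = list(config = config, unit_specs = unit_specs,
                                     envelope = lfp$envelope,
                                     beta_phase = lfp$beta_phase,
                                     latent_events = latent)),
            class = "synthetic_session")
}

# Replace latent motion-start / turn-start times with the operational
# event definitions, obtained by running the event detectors on the
# noise-free closed-form trajectory of each trial.
operational_events <- function(tt, config, fs = 100) {
  for (i in seq_len(nrow(tt))) {
    tr <- tt[i, ]
    t <- seq(tr$t_fix - 0.6, tr$t_feedback + 0.3, by = 1 / fs)
    xy <- trajectory_closed_form(t, tr, config)
    kin <- compute_kinematics(data.frame(t = t, x = xy$x, y = xy$y),
                              sigma_smooth = 0.03)
    mo <- detect_movement_onset(kin, tr$t_go)
    if (!is.na(mo$t_move)) tt$t_move[i] <- mo$t_move
    if (!is.na(tr$t_turn)) {
      to <- detect_turn_onset(kin, c(tr$t_move + 0.02, tr$t_feedback))
      if (!is.na(to$t_turn)) tt$t_turn[i] <- to$t_turn
    }
  }
  # preserve event ordering invariants against edge effects
  tt$t_move <- pmax(tt$t_move, tt$t_go + 0.01)
  bad <- !is.na(tt$t_turn) & tt$t_turn <= tt$t_move
  tt$t_turn[bad] <- tt$t_move[bad] + 0.01
  bad <- !is.na(tt$t_turncue) & tt$t_turncue >= tt$t_turn
  tt$t_turncue[bad] <- tt$t_turn[bad] - 0.01
  tt
}

# Session-long z-scored kinematic grid: v_z/a_z from the per-trial series,
# and the session z-score of zero speed/acceleration between trials.
session_kinematic_grid <- function(kin_list, trial_table, fs = 100) {
  vm <- attr(kin_list, "v_moments"); am <- attr(kin_list, "a_moments")
  t_end <- max(trial_table$t_feedback) + 1.5
  t <- seq(0, t_end, by = 1 / fs)
  v_z <- rep(-vm["mean"] / vm["sd"], length(t))
  a_z <- rep(-am["mean"] / am["sd"], length(t))
  for (k in kin_list) {
    ok <- !is.na(k$v_z)
    v_z[t >= min(k$t) & t <= max(k$t)] <-
      interp1(k$t[ok], k$v_z[ok], t[t >= min(k$t) & t <= max(k$t)])
    ok <- !is.na(k$a_z)
    a_z[t >= min(k$t) & t <= max(k$t)] <-
      interp1(k$t[ok], k$a_z[ok], t[t >= min(k$t) & t <= max(k$t)])
  }
  list(t = t, v_z = unname(v_z), a_z = unname(a_z))
}

#' Write a session bundle to plain-text files
#'
#' Writes `trials.csv`, `trajectories.csv` (long format), `spikes.csv`,
#' `lfp.f32` (raw little-endian float32) with a `lfp.json` sidecar
#' (`fs_hz`, `n_samples`, `units`), and `config.json`.
#'
#' @param session a `synthetic_session`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session_bundle <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tt <- session$trial_table
  write.csv(tt, file.path(dir, "trials.csv"), row.names = FALSE, na = "")
  traj <- do.call(rbind, session$trajectories)
  write.csv(traj, file.path(dir, "trajectories.csv"), row.names = FALSE)
  sp <- do.call(rbind, lapply(seq_along(session$spikes), function(u)
    if (length(session$spikes[[u]]))
      data.frame(unit_id = u, t = session$spikes[[u]]) else NULL))
  write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  con <- file(file.path(dir, "lfp.f32"), "wb")
  writeBin(as.numeric(session$lfp$trace), con, size = 4, endian = "little")
  close(con)
  jsonlite::write_json(list(fs_hz = session$lfp$fs,
                            n_samples = length(session$lfp$trace),
                            units = "a.u."),
                       file.path(dir, "lfp.json"), auto_unbox = TRUE)
  cfg <- session$ground_truth$config
  cfg_out <- lapply(cfg, function(x) if (inherits(x, "truncexp_spec")) unclass(x) else x)
  jsonlite::write_json(cfg_out, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session bundle written by [write_session_bundle()]
#'
#' @param dir bundle directory.
#' @return list with `trial_table`, `trajectories` (list of data.frames),
#'   `spikes` (list), `lfp` (list with `trace`, `fs`).
#' @export
read_session_bundle <- function(dir) {
  tt <- read.csv(file.path(dir, "trials.csv"), stringsAsFactors = FALSE)
  traj_long <- read.csv(file.path(dir, "trajectories.csv"))
  traj <- split(traj_long, traj_long$trial_id)
  traj <- traj[order(as.integer(names(traj)))]
  sp_long <- read.csv(file.path(dir, "spikes.csv"))
  n_units <- max(sp_long$unit_id)
  spikes <- lapply(seq_len(n_units), function(u) sp_long$t[sp_long$unit_id == u])
  side <- jsonlite::read_json(file.path(dir, "lfp.json"))
  con <- file(file.path(dir, "lfp.f32"), "rb")
  trace <- readBin(con, numeric(), n = side$n_samples, size = 4, endian = "little")
  close(con)
  list(trial_table = tt, trajectories = unname(traj), spikes = spikes,
       lfp = list(trace = trace, fs = side$fs_hz, t0 = 0))
}
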