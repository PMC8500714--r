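# End-to-end orchestration: synthetic generation -> analysis stages ->
# report tables, with per-stage seeds recorded in a run manifest so any
# output is reproducible from the manifest alone.

#' Build a units x types x time rate array for the cluster-mass tests
#'
#' Aligns every unit's spikes to an event, averages per trial type, and
#' stacks the PSTHs.  Time points where any unit/type cell is missing
#' are kept (the tests drop incomplete units per time point).
#'
#' @param session a `synthetic_session` (or compatible list).
#' @param event window name.
#' @param dt PSTH grid step (s).
#' @param types trial types (default the three task types).
#' @param correct_only drop incorrect trials.
#' @return list: `rates` array `[unit, type, time]`, `grid`, `types`.
#' @export
unit_type_rate_array <- function(session, event, dt = 0.005,
                                 types = c("reach", "planned", "impromptu"),
                                 correct_only = TRUE) {
  tt <- session$trial_table
  if (correct_only) tt <- tt[tt$correct, ]
  grid <- NULL
  mats <- lapply(session$spikes, function(sp) {
    ar <- aligned_trial_rates(sp, tt, event, dt = dt)
    grid <<- ar$grid
    idx <- match(ar$trials, tt$trial_id)
    vapply(types, function(m)
      suppressWarnings(build_psth(list(grid = ar$grid,
                                       rates = ar$rates[tt$type[idx] == m, , drop = FALSE])))$rate,
      numeric(length(ar$grid)))
  })
  rates <- array(NA_real_, c(length(mats), length(types), length(grid)),
                 dimnames = list(NULL, types, NULL))
  for (u in seq_along(mats)) rates[u, , ] <- t(mats[[u]])
  list(rates = rates, grid = grid, types = types)
}

#' Per-unit trial-level aligned rate matrices
#'
#' @param session session list.
#' @param event window name.
#' @param dt grid step (s).
#' @param correct_only drop incorrect trials.
#' @param drop_censored drop trials with any censored sample in the
#'   window (keeps matrices complete for permutation machinery).
#' @return list: `trial_rates` (per unit `[trial x time]`), `labels`
#'   (per unit type labels), `directions`, `grid`.
#' @export
trial_rate_matrices <- function(session, event, dt = 0.005,
                                correct_only = TRUE, drop_censored = TRUE) {
  tt <- session$trial_table
  if (correct_only) tt <- tt[tt$correct, ]
  grid <- NULL
  trial_rates <- list(); labels <- list(); dirs <- list()
  for (u in seq_along(session$spikes)) {
    ar <- aligned_trial_rates(session$spikes[[u]], tt, event, dt = dt)
    grid <- ar$grid
    idx <- match(ar$trials, tt$trial_id)
    keep <- if (drop_censored) !apply(is.na(ar$rates), 1, any)
    else rep(TRUE, nrow(ar$rates))
    trial_rates[[u]] <- ar$rates[keep, , drop = FALSE]
    labels[[u]] <- tt$type[idx][keep]
    dirs[[u]] <- tt$direction[idx][keep]
  }
  list(trial_rates = trial_rates, labels = labels, directions = dirs,
       grid = grid)
}

#' Pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed master seed; every stochastic stage derives a child seed
#'   from it.
#' @param n_trials,n_units synthetic session size.
#' @param n_perm permutation count for the cluster-mass tests.
#' @param n_iter_decode ideal-observer iterations.
#' @param dt PSTH grid step (s).
#' @param stages character vector of stages to run, in dependency order;
#'   any subset of `c("simulate", "kinematics", "psth", "population",
#'   "stats", "regression", "decoding", "spectral")`.
#' @param quick reduced permutation/iteration counts for smoke tests.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("stnreach_run_"),
                            seed = 1L, n_trials = 60, n_units = 20,
                            n_perm = 1000, n_iter_decode = 10000,
                            dt = 0.005,
                            stages = c("simulate", "kinematics", "psth",
                                       "population", "stats", "regression",
                                       "decoding", "spectral"),
                            quick = FALSE) {
  if (quick) { n_perm <- 100; n_iter_decode <- 500 }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_trials = n_trials, n_units = n_units, n_perm = n_perm,
                 n_iter_decode = n_iter_decode, dt = dt, stages = stages,
                 quick = quick),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order on a synthetic
#' session, writing stage outputs as CSV and a `manifest.json` recording
#' seeds and parameters.  Later stages require earlier ones.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  want <- function(s) s %in% config$stages
  need <- function(s, what) if (is.null(res[[what]]))
    stop(sprintf("stage '%s' requires stage '%s'", s, what), call. = FALSE)

  if (want("simulate")) {
    tc <- task_config(n_trials = config$n_trials, seed = config$seed)
    res$session <- generate_session(tc,
      unit_specs = default_population(config$n_units,
                                      seed = child_seed(config$seed, 7)))
    write_session_bundle(res$session, file.path(config$out_dir, "session"))
  }

  if (want("kinematics")) {
    need("kinematics", "session")
    s <- res$session
    det <- lapply(seq_len(nrow(s$trial_table)), function(i) {
      tr <- s$trial_table[i, ]
      mo <- detect_movement_onset(s$kinematics[[i]], tr$t_go)
      to <- if (!is.na(tr$t_turn))
        detect_turn_onset(s$kinematics[[i]], c(tr$t_move + 0.05, tr$t_feedback))
      else list(t_turn = NA_real_, flagged = FALSE)
      data.frame(trial_id = tr$trial_id, t_move_detected = mo$t_move,
                 move_flagged = mo$flagged, t_turn_detected = to$t_turn,
                 turn_flagged = to$flagged)
    })
    res$events <- do.call(rbind, det)
    write.csv(res$events, file.path(config$out_dir, "detected_events.csv"),
              row.names = FALSE)
    # mean +/- SD reach trajectory (movement-aligned segments)
    reach_idx <- which(s$trial_table$type == "reach" & s$trial_table$correct)
    if (length(reach_idx) >= 2) {
      segs <- lapply(reach_idx, function(i) {
        tr <- s$trial_table[i, ]
        p <- s$trajectories[[i]]
        p[p$t >= tr$t_move - 0.05 & p$t <= tr$t_feedback, c("t", "x", "y")]
      })
      mp <- pairwise_mean_trajectory(segs, n_points = 100)
      vp <- pairwise_var_trajectory(segs, n_points = 100)
      write.csv(cbind(mp, vp), file.path(config$out_dir, "mean_reach_trajectory.csv"),
                row.names = FALSE)
    }
  }

  if (want("psth")) {
    need("psth", "session")
    s <- res$session
    tt <- add_surrogate_events(s$trial_table, seed = child_seed(config$seed, 11))
    res$trial_table_ps <- tt
    res$profiles <- lapply(s$spikes, response_profile, trial_table = tt,
                           dt = config$dt)
    seg <- res$profiles[[1]]$segments
    prof_mat <- do.call(rbind, lapply(res$profiles, `[[`, "profile"))
    res$profile_matrix <- prof_mat
    res$segments <- seg
    long <- do.call(rbind, lapply(seq_along(res$profiles), function(u)
      cbind(unit = u, seg, z = res$profiles[[u]]$profile)))
    write.csv(long, file.path(config$out_dir, "profiles.csv"), row.names = FALSE)
  }

  if (want("population")) {
    need("population", "profiles")
    keep_cols <- stats::complete.cases(t(res$profile_matrix))
    pcs <- fit_population_pca(res$profile_matrix[, keep_cols, drop = FALSE],
                              res$segments[keep_cols, ], D = 4)
    res$pcs <- pcs
    cl <- cluster_units(pcs)
    res$unit_clusters <- cl
    write.csv(data.frame(unit = pcs$units_kept, cluster = cl$labels,
                         pcs$coefficients),
              file.path(config$out_dir, "unit_clusters.csv"), row.names = FALSE)
    write.csv(data.frame(component = seq_along(pcs$var_explained),
                         var_explained = pcs$var_explained),
              file.path(config$out_dir, "variance_explained.csv"), row.names = FALSE)
  }

  if (want("stats")) {
    need("stats", "session")
    arr <- unit_type_rate_array(res$session, "movement", dt = config$dt)
    cm <- cluster_mass_test(arr$rates, n_perm = config$n_perm,
                            seed = child_seed(config$seed, 21))
    res$cluster_test <- cm
    cl <- cm$clusters
    if (nrow(cl)) {
      cl$t_start <- arr$grid[cl$start]; cl$t_end <- arr$grid[cl$end]
    }
    write.csv(cl, file.path(config$out_dir, "cluster_test_movement.csv"),
              row.names = FALSE)
  }

  if (want("regression")) {
    need("regression", "session")
    s <- res$session
    reg <- session_lagged_fits(s, dt = config$dt)
    res$regression <- reg
    write.csv(reg$table, file.path(config$out_dir, "lagged_fits.csv"),
              row.names = FALSE)
  }

  if (want("decoding")) {
    need("decoding", "session")
    trd <- trial_rate_matrices(res$session, "movement", dt = config$dt)
    patterns <- lapply(trd$trial_rates, function(m)
      matrix(rowMeans(m), ncol = 1))
    dec <- ideal_observer(patterns, trd$labels,
                          n_iter = config$n_iter_decode,
                          seed = child_seed(config$seed, 31))
    res$decoding <- dec
    write.csv(data.frame(classes = paste(dec$classes, collapse = "/"),
                         n_iter = dec$n_iter, accuracy = dec$accuracy),
              file.path(config$out_dir, "decode_summary.csv"), row.names = FALSE)
  }

  if (want("spectral")) {
    need("spectral", "session")
    s <- res$session
    if (is.null(s$lfp)) stop("spectral stage enabled but session has no LFP", call. = FALSE)
    res$spectral <- beta_power_summary(s, seed = child_seed(config$seed, 41))
    write.csv(res$spectral$table, file.path(config$out_dir, "beta_power.csv"),
              row.names = FALSE)
  }

  manifest <- list(package = "stnreach",
                   version = as.character(utils::packageVersion("stnreach")),
                   seed = config$seed, stages = config$stages,
                   n_trials = config$n_trials, n_units = config$n_units,
                   n_perm = config$n_perm, n_iter_decode = config$n_iter_decode,
                   dt = config$dt, quick = config$quick,
                   r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(res)
}

#' Lagged kinematic fits for all units of a session
#'
#' Builds movement-aligned per-type PSTHs and mean kinematics and fits
#' the default speed + acceleration lagged model for each unit.
#'
#' @param session a `synthetic_session`.
#' @param dt grid step (s).
#' @param units unit indices (default all).
#' @param lag_grid lag grid (s).
#' @return list: `fits` (per unit `lagged_model_fit`), `table` (summary
#'   data.frame).
#' @export
session_lagged_fits <- function(session, dt = 0.005, units = NULL,
                                lag_grid = seq(-0.2, 0.2, by = 0.01),
                                alpha = 20, window = c(-0.4, 0.8)) {
  types <- c("reach", "planned", "impromptu")
  tt <- session$trial_table[session$trial_table$correct, ]
  kin_by_type <- session_mean_kinematics(session, "movement", dt = dt,
                                         window = window)
  units <- units %||% seq_along(session$spikes)
  fits <- lapply(units, function(u) {
    ar <- aligned_trial_rates(session$spikes[[u]], tt, "movement",
                              window = window, dt = dt, alpha = alpha,
                              warmup_s = 3 / alpha)
    idx <- match(ar$trials, tt$trial_id)
    psth_by_type <- lapply(types, function(m) {
      p <- suppressWarnings(build_psth(list(grid = ar$grid,
        rates = ar$rates[tt$type[idx] == m, , drop = FALSE])))
      data.frame(t = p$t, rate = p$rate, w = p$n_valid)
    })
    names(psth_by_type) <- types
    # filter the kinematic regressors with the same causal kernel used for
    # the rates: identical filtering on both sides leaves the lag estimate
    # unbiased for a linear rate model, whatever the kernel shape
    kin_f <- lapply(kin_by_type, function(k) {
      for (cn in setdiff(names(k), "t")) k[[cn]] <- alpha_filter(k[[cn]], dt, alpha)
      k
    })
    fit_lagged_model(psth_by_type, kin_f, lag_grid = lag_grid)
  })
  tab <- do.call(rbind, lapply(seq_along(fits), function(i)
    data.frame(unit = units[i], lag = fits[[i]]$lag_best,
               r2_in = fits[[i]]$r2_in, r2_out = fits[[i]]$r2_out,
               t(fits[[i]]$coef))))
  list(fits = fits, table = tab)
}

#' Movement-aligned mean z-scored kinematics per trial type
#'
#' @param session a `synthetic_session`.
#' @param event alignment window name.
#' @param dt grid step (s).
#' @param window optional window override (s, relative to the event).
#' @return named list per type of `data.frame(t, v, a, vx, vy, ax, ay)`.
#' @export
session_mean_kinematics <- function(session, event = "movement", dt = 0.005,
                                    window = NULL) {
  types <- c("reach", "planned", "impromptu")
  tt <- session$trial_table[session$trial_table$correct, ]
  win <- window %||% analysis_windows()[[event]]
  grid <- seq(win[1], win[2], by = dt)
  out <- lapply(types, function(m) {
    rows <- which(tt$type == m)
    acc <- matrix(0, length(grid), 6)
    for (i in rows) {
      k <- session$kinematics[[match(tt$trial_id[i], session$trial_table$trial_id)]]
      t0 <- tt$t_move[i]
      ok <- !is.na(k$v_z)
      acc <- acc + cbind(interp1(k$t[ok] - t0, k$v_z[ok], grid),
                         interp1(k$t[ok] - t0, k$a_z[ok], grid),
                         interp1(k$t[ok] - t0, k$vx[ok], grid),
                         interp1(k$t[ok] - t0, k$vy[ok], grid),
                         interp1(k$t[ok] - t0, k$ax[ok], grid),
                         interp1(k$t[ok] - t0, k$ay[ok], grid))
    }
    acc <- acc / length(rows)
    data.frame(t = grid, v = acc[, 1], a = acc[, 2], vx = acc[, 3],
               vy = acc[, 4], ax = acc[, 5], ay = acc[, 6])
  })
  names(out) <- types
  out
}

#' Beta-band power and spike-field coupling summary for a session
#'
#' Movement-aligned beta-band evoked/induced power normalized by the
#' trial-count-matched pre-fixation baseline, plus per-unit beta PPC and
#' the implied peak-to-trough rate modulation.
#'
#' @param session a `synthetic_session` with LFP.
#' @param seed optional seed for the baseline resampling.
#' @param units unit indices (default all).
#' @return list: `power`, `table`, `unit_ppc`, `unit_modulation`.
#' @export
beta_power_summary <- function(session, seed = NULL, units = NULL) {
  lfp <- session$lfp
  if (is.null(lfp) || length(lfp$trace) == 0)
    stop("session has no LFP; spectral analyses require one", call. = FALSE)
  analytic <- beta_band_analytic(lfp$trace, lfp$fs)
  tt <- session$trial_table
  fs <- lfp$fs
  seg <- function(center, win) {
    i0 <- round((center + win[1]) * fs) + 1
    i1 <- round((center + win[2]) * fs) + 1
    matrix(analytic[i0:i1], ncol = 1)
  }
  move_win <- c(-0.3, 0.27); base_win <- c(-0.5, -0.25)
  mv <- lapply(tt$t_move[!is.na(tt$t_move)], seg, win = move_win)
  bs <- lapply(tt$t_fix, seg, win = base_win)
  pw <- evoked_induced_power(mv)
  bl <- baseline_power_distribution(bs, n = pw$n_trials, seed = seed)
  norm <- baseline_normalize(pw, bl)
  twin <- move_win[1] + (seq_len(nrow(norm$induced)) - 1) / fs
  post <- twin >= 0.05 & twin <= 0.25    # after movement onset
  pre <- twin >= -0.3 & twin <= -0.05    # before movement onset
  units <- units %||% seq_along(session$spikes)
  tps <- seq(-0.2, 0.2, by = 0.05)
  ppc <- vapply(units, function(u) {
    trial_spikes <- lapply(which(!is.na(tt$t_move)), function(i) {
      sel <- session$spikes[[u]] >= tt$t_move[i] - 2 & session$spikes[[u]] <= tt$t_move[i] + 1
      st <- session$spikes[[u]][sel]
      list(t = st - tt$t_move[i],
           phase = spike_phases(analytic, fs, lfp$t0, st))
    })
    p <- ppc_timecourse(trial_spikes, tps, freqs = 21.5)
    mean(p$ppc, na.rm = TRUE)
  }, numeric(1))
  list(power = norm,
       table = data.frame(
         epoch = c("pre_movement", "movement"),
         induced_beta = c(mean(norm$induced[pre, ]), mean(norm$induced[post, ])),
         evoked_beta = c(mean(norm$evoked[pre, ]), mean(norm$evoked[post, ]))),
       unit_ppc = ppc,
       unit_modulation = ppc_to_modulation(pmax(ppc, 0)))
}
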