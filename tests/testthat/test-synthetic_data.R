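# Synthetic session generator: delay sampler, schedule, trajectories,
# spikes, LFP.

test_that("truncated-exponential sampler matches its analytic mean and range", {
  spec1 <- truncexp_spec(c(0.3, 0.6), 0.4)
  d1 <- sample_truncated_exponential(spec1, 1e5, seed = 11)
  expect_true(all(d1 >= 0.3 & d1 <= 0.6))
  expect_lt(abs(mean(d1) - 0.4), 0.002)

  spec2 <- truncexp_spec(c(0.4, 1.0), 0.6)
  d2 <- sample_truncated_exponential(spec2, 1e5, seed = 12)
  expect_true(all(d2 >= 0.4 & d2 <= 1.0))
  expect_lt(abs(mean(d2) - 0.6), 0.003)

  # the solved rate reproduces the target mean analytically
  lam <- stnreach:::truncexp_rate(spec1)
  expect_lt(abs(stnreach:::truncexp_mean(lam, 0.3, 0.6) - 0.4), 1e-9)
})

test_that("infeasible truncated-exponential means are rejected", {
  # mean at the midpoint or above is unreachable with decreasing density
  expect_error(truncexp_spec(c(0.3, 0.6), 0.45), "infeasible")
  expect_error(truncexp_spec(c(0.3, 0.6), 0.30), "infeasible")
  expect_error(truncexp_spec(c(0.6, 0.3), 0.4), "increasing")
})

test_that("trial schedule has the configured composition and ordered events", {
  cfg <- task_config(n_trials = 4000, seed = 5L)
  tt <- gen_trial_schedule(cfg)
  initially_reach <- tt$type %in% c("reach", "impromptu")
  frac_imp <- sum(tt$type == "impromptu") / sum(initially_reach)
  expect_lt(abs(frac_imp - 0.5), 0.03)
  expect_lt(abs(mean(initially_reach) - 0.65), 0.03)
  expect_equal(sum(tt$direction == "medial"), 2000)

  ev <- tt[, c("t_fix", "t_instr", "t_go", "t_move", "t_feedback")]
  expect_true(all(apply(ev, 1, function(r) all(diff(r) > 0))))
  turn <- !is.na(tt$t_turn)
  expect_true(all(tt$t_move[turn] < tt$t_turn[turn]))
  expect_true(all(tt$t_turn[turn] < tt$t_feedback[turn]))
  # impromptu turn cue lies between movement onset and turn onset
  imp <- tt$type == "impromptu"
  expect_true(all(tt$t_turncue[imp] > tt$t_move[imp]))
  expect_true(all(tt$t_turncue[imp] < tt$t_turn[imp]))

  # fixation and go delays respect their configured ranges
  expect_true(all(tt$t_instr - tt$t_fix >= 0.3 & tt$t_instr - tt$t_fix <= 0.6))
  expect_true(all(tt$t_go - tt$t_instr >= 0.4 & tt$t_go - tt$t_instr <= 1.0))
})

test_that("schedule edge cases: no impromptu, determinism", {
  cfg0 <- task_config(n_trials = 200, p_impromptu_given_reach = 0, seed = 9L)
  expect_equal(sum(gen_trial_schedule(cfg0)$type == "impromptu"), 0)
  cfg <- task_config(n_trials = 50, seed = 33L)
  expect_identical(gen_trial_schedule(cfg), gen_trial_schedule(cfg))
})

test_that("noise-free reach trajectory equals the closed-form minimum-jerk path", {
  cfg <- task_config(n_trials = 5, seed = 2L, pos_noise_sd = 0)
  tt <- gen_trial_schedule(cfg)
  tr <- tt[tt$type == "reach", ][1, ]
  traj <- gen_trajectory(tr, cfg, seed = 1)
  s <- pmin(pmax((traj$t - tr$t_move) / cfg$reach_duration_s, 0), 1)
  x_true <- cfg$reach_dist * (s^3 * (10 - 15 * s + 6 * s^2)) *
    (if (tr$direction == "lateral") -1 else 1)
  expect_equal(traj$x, x_true, tolerance = 1e-10)
  expect_equal(traj$y, rep(0, nrow(traj)), tolerance = 1e-10)
})

test_that("reach trials stay horizontal; impromptu speed dips near the turn", {
  s <- small_session()
  tt <- s$trial_table
  for (i in which(tt$type == "reach")) {
    p <- s$trajectories[[i]]
    expect_lt(diff(range(p$y)), 0.1 * diff(range(p$x)))
  }
  i <- which(tt$type == "impromptu")[1]
  k <- s$kinematics[[i]]
  # total speed dips (falls below half its pre-turn peak) within 250 ms
  # of turn onset, between the horizontal and vertical segments
  sel <- which(!is.na(k$v) & k$t > tt$t_move[i] + 0.1 & k$t < tt$t_turn[i] + 0.3)
  tmin <- k$t[sel][which.min(k$v[sel])]
  expect_lt(abs(tmin - tt$t_turn[i]), 0.25)
  expect_lt(min(k$v[sel]), 0.5 * max(k$v[sel]))
})

test_that("spike generator is Poisson at baseline and phase-locks to beta", {
  s <- small_session()
  tt <- s$trial_table
  dur <- max(tt$t_feedback) + 1
  # untuned unit: rate close to its 25 Hz baseline
  expect_lt(abs(length(s$spikes[[3]]) / dur - 25) / 25, 0.05)
  # Poisson dispersion of counts in 1 s bins for the untuned unit
  cnt <- tabulate(floor(s$spikes[[3]]) + 1, nbins = floor(dur))
  expect_lt(abs(var(cnt) / mean(cnt) - 1), 0.25)
  # phase-locked units: spike-phase resultant near m/2
  ph <- s$lfp$beta_phase(s$spikes[[1]])
  r <- Mod(mean(exp(1i * ph)))
  expect_lt(abs(r - 0.13 / 2), 3 / sqrt(length(ph)))
})

test_that("ground-truth lag is recoverable by brute-force lagged correlation", {
  s <- generate_session(task_config(n_trials = 60, seed = 202L),
                        unit_specs = list(unit_spec(60, beta_v = 8, beta_a = 2,
                                                    lag_s = 0.11)),
                        with_lfp = FALSE)
  grid <- s$session_kin$t
  cnt <- tabulate(pmin(findInterval(s$spikes[[1]], grid), length(grid)),
                  nbins = length(grid))
  lags <- seq(-0.3, 0.3, by = 0.01)
  cc <- vapply(lags, function(L)
    cor(cnt, approx(grid, s$session_kin$v_z, grid + L, rule = 2)$y), numeric(1))
  expect_lt(abs(lags[which.max(cc)] - 0.11), 0.031)
})

test_that("LFP beta envelope is suppressed during movement; spectrum slope matches", {
  cfg <- task_config(n_trials = 20, seed = 77L)
  tt <- gen_trial_schedule(cfg)
  lfp <- gen_lfp(cfg, tt, fs = 500, suppression = 0.5, noise_sd = 0.2,
                 noise_exponent = 1.5, seed = 3)
  t <- (seq_along(lfp$trace) - 1) / lfp$fs
  env <- lfp$envelope(t)
  mid <- (tt$t_move + tt$t_feedback) / 2
  expect_true(all(abs(lfp$envelope(mid) - 0.5) < 1e-9))
  expect_true(all(abs(lfp$envelope(tt$t_fix) - 1.0) < 1e-9))

  # no suppression -> flat envelope
  lfp1 <- gen_lfp(cfg, tt, fs = 500, suppression = 1, seed = 3)
  expect_true(all(abs(lfp1$envelope(t) - 1) < 1e-9))

  # periodogram slope of the 1/f background matches the exponent
  noise <- stnreach:::one_over_f_noise(2^16, 500, 1.5, 1)
  sp <- stats::spec.pgram(ts(noise, frequency = 500), plot = FALSE, taper = 0)
  sel <- sp$freq > 1 & sp$freq < 100
  slope <- coef(lm(log(sp$spec[sel]) ~ log(sp$freq[sel])))[2]
  expect_lt(abs(slope + 1.5), 0.15)
})

test_that("session bundle round-trips through plain-text files", {
  s <- small_session()
  dir <- tempfile("bundle_")
  write_session_bundle(s, dir)
  expect_true(all(file.exists(file.path(dir,
    c("trials.csv", "trajectories.csv", "spikes.csv", "lfp.f32", "lfp.json",
      "config.json")))))
  b <- read_session_bundle(dir)
  expect_equal(nrow(b$trial_table), nrow(s$trial_table))
  expect_equal(b$trial_table$t_move, s$trial_table$t_move, tolerance = 1e-6)
  expect_equal(length(b$spikes), length(s$spikes))
  expect_equal(b$spikes[[1]], s$spikes[[1]], tolerance = 1e-6)
  expect_equal(b$lfp$fs, s$lfp$fs)
  expect_equal(b$lfp$trace, s$lfp$trace, tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
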