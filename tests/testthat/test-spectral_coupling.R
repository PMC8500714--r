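# LFP preprocessing, Morse CWT, evoked/induced power, beta analytic
# signal, PPC and the PPC -> modulation conversion.

test_that("preprocessing removes drift, line noise and artifacts", {
  fs <- 2000
  t <- seq(0, 20, by = 1 / fs)[-1]
  set.seed(1)
  base <- rnorm(length(t), sd = 0.5)
  x <- base + 0.2 * t + 3 * sin(2 * pi * 60 * t)
  out <- suppressWarnings(preprocess_lfp(x, fs))
  # 60 Hz power reduced by > 30 dB
  p60 <- function(z) {
    z[is.na(z)] <- 0
    sp <- Mod(fft(z))^2
    f <- (seq_along(z) - 1) * fs / length(z)
    mean(sp[abs(f - 60) < 0.5])
  }
  expect_lt(p60(out$trace), p60(x) / 1000)
  # drift removed: means of first and last fifth both ~ 0
  n <- length(out$trace)
  expect_lt(abs(mean(out$trace[1:(n / 5)], na.rm = TRUE)), 0.1)
  expect_lt(abs(mean(out$trace[(4 * n / 5):n], na.rm = TRUE)), 0.1)

  # an injected artifact censors +/- 2.5 s
  x2 <- base
  x2[20000] <- 100
  out2 <- suppressWarnings(preprocess_lfp(x2, fs))
  i0 <- 20000 / (fs / out2$fs)
  pad <- 2.5 * out2$fs
  expect_true(all(is.na(out2$trace[max(1, i0 - pad + 2):(i0 + pad - 2)])))
  expect_false(anyNA(out2$trace[1:(i0 - pad - 10)]))
  # low input rates warn
  expect_warning(preprocess_lfp(rnorm(1000), 1000), "headroom")
})

test_that("Morse CWT localises sinusoids and recovers AM envelopes", {
  fs <- 500
  t <- seq(0, 8, by = 1 / fs)[-1]
  freqs <- morse_freqs()
  x <- cos(2 * pi * 20 * t)
  W <- morse_cwt(x, fs, freqs)
  prof <- colMeans(Mod(W[1000:3000, ])^2)
  expect_lt(abs(freqs[which.max(prof)] - 20) / 20, 0.15)
  # unit-amplitude sinusoid at a centre frequency -> |W| ~ amplitude
  expect_equal(mean(Mod(W[1000:3000, which.min(abs(freqs - 20))])), 1,
               tolerance = 0.05)
  # amplitude-modulated carrier: envelope recovered within 5% RMS
  env <- 1 + 0.5 * sin(2 * pi * 0.5 * t)
  Wam <- morse_cwt(env * cos(2 * pi * 20 * t), fs, 20)
  mid <- 500:3500
  rel_rms <- sqrt(mean((Mod(Wam[mid, 1]) - env[mid])^2)) / mean(env)
  expect_lt(rel_rms, 0.05)
  # total wavelet power tracks signal variance stably across noise seeds
  set.seed(2)
  ratios <- replicate(5, {
    z <- rnorm(2000)
    sum(Mod(morse_cwt(z, fs, freqs))^2) / var(z)
  })
  expect_lt(diff(range(ratios)) / mean(ratios), 0.2)
})

test_that("evoked/induced power identity and limits", {
  set.seed(3)
  n <- 40
  base <- matrix(complex(modulus = 1, argument = runif(200, 0, 2 * pi)), 20, 10)
  # identical phase-locked trials: induced ~ 0
  locked <- replicate(n, base, simplify = FALSE)
  p <- evoked_induced_power(locked)
  expect_equal(max(abs(p$induced)), 0, tolerance = 1e-12)
  expect_equal(p$evoked + p$induced, p$total, tolerance = 1e-12)
  # random-phase trials: evoked -> 0, induced -> mean power
  rand <- replicate(n, matrix(complex(modulus = 1,
                                      argument = runif(200, 0, 2 * pi)),
                              20, 10), simplify = FALSE)
  p2 <- evoked_induced_power(rand)
  expect_lt(mean(p2$evoked), 0.1)
  expect_equal(mean(p2$induced), 1, tolerance = 0.1)
  # two-trial hand-worked oracle
  z1 <- matrix(1 + 1i, 1, 1); z2 <- matrix(1 - 1i, 1, 1)
  p3 <- evoked_induced_power(list(z1, z2))
  expect_equal(as.numeric(p3$evoked), 1)    # |mean|^2 = |1|^2
  expect_equal(as.numeric(p3$total), 2)     # mean of |z|^2 = 2
  expect_equal(as.numeric(p3$induced), 1)
})

test_that("trial-count-matched baseline removes the 1/n evoked bias", {
  set.seed(4)
  # stationary zero-mean noise: evoked baseline ~ sigma^2 / n
  trials <- replicate(60, matrix(complex(real = rnorm(300), imaginary = rnorm(300)),
                                 100, 3), simplify = FALSE)
  b10 <- baseline_power_distribution(trials, 10, n_rep = 200, seed = 1)
  b40 <- baseline_power_distribution(trials, 40, n_rep = 200, seed = 2)
  expect_equal(mean(b10$evoked) / mean(b40$evoked), 4, tolerance = 0.4)
  # normalized power ~ 1 for stationary noise at the matched count
  p10 <- evoked_induced_power(trials[1:10])
  norm <- baseline_normalize(p10, b10)
  expect_equal(mean(norm$evoked), 1, tolerance = 0.35)
  expect_equal(mean(norm$induced), 1, tolerance = 0.1)
  # requesting more trials than available flags and samples with replacement
  expect_warning(baseline_power_distribution(trials[1:5], 10, n_rep = 10),
                 "replacement")
})

test_that("beta analytic signal isolates the band", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)[-1]
  a20 <- beta_band_analytic(cos(2 * pi * 20 * t), fs)
  mid <- 1000:4000
  expect_equal(mean(Mod(a20[mid])), 1, tolerance = 0.02)
  inst_f <- diff(stnreach:::unwrap_phase(Arg(a20[mid]))) * fs / (2 * pi)
  expect_equal(mean(inst_f), 20, tolerance = 0.1)
  a50 <- beta_band_analytic(cos(2 * pi * 50 * t), fs)
  expect_lt(mean(Mod(a50[mid])), 0.02)
  # chirp: envelope rises inside the band and falls outside
  ph <- 2 * pi * (10 * t + 2.5 * t^2 / 2)  # 10 -> 35 Hz over 10 s
  ch <- beta_band_analytic(cos(ph), fs)
  env <- Mod(ch)
  f_inst <- 10 + 2.5 * t
  expect_gt(mean(env[f_inst > 15 & f_inst < 28]),
            3 * mean(env[f_inst < 11 | f_inst > 34]))
})

test_that("PPC matches the analytic resultant for sinusoidal modulation", {
  set.seed(5)
  m <- 0.4
  # spikes on 40 trials with phase density (1 + m cos)/2pi at 20 Hz
  gen_trial <- function() {
    tt <- seq(0, 2, by = 1e-3)
    lam <- 30 * (1 + m * cos(2 * pi * 20 * tt))
    keep <- runif(length(tt)) < lam * 1e-3
    st <- tt[keep]
    list(t = st - 2, phase = matrix((2 * pi * 20 * st) %% (2 * pi), ncol = 1))
  }
  trials <- replicate(40, gen_trial(), simplify = FALSE)
  pp <- ppc_timecourse(trials, time_points = 0, freqs = 20)
  expect_lt(abs(as.numeric(pp$ppc) - (m / 2)^2), 0.01)

  # uniform independent phases -> PPC ~ 0
  null_trials <- lapply(trials, function(tr) {
    tr$phase[] <- runif(length(tr$phase), 0, 2 * pi); tr
  })
  pp0 <- ppc_timecourse(null_trials, time_points = 0, freqs = 20)
  expect_lt(abs(as.numeric(pp0$ppc)), 0.01)

  # identical phases -> PPC = 1
  one <- lapply(1:4, function(i) list(t = -0.25, phase = matrix(1.2, 1, 1)))
  expect_equal(as.numeric(ppc_timecourse(one, 0, 20)$ppc), 1)

  # windows: spikes after the time point are excluded (causality), and
  # the bin length is min(10 cycles, 1.5 s)
  late <- lapply(1:4, function(i) list(t = 0.5, phase = matrix(1.2, 1, 1)))
  expect_true(is.na(as.numeric(ppc_timecourse(late, 0, 20)$ppc)))
})

test_that("PPC is unbiased under independence (null average near zero)", {
  set.seed(6)
  vals <- replicate(200, {
    trials <- lapply(1:8, function(i) {
      n <- rpois(1, 15) + 1
      list(t = runif(n, -1, 0), phase = matrix(runif(n, 0, 2 * pi), ncol = 1))
    })
    as.numeric(ppc_timecourse(trials, 0, 20)$ppc)
  })
  expect_lt(abs(mean(vals)), 0.002)
})

test_that("PPC -> peak-to-trough modulation reproduces the closed form", {
  expect_equal(ppc_to_modulation(0), 0)
  m1 <- ppc_to_modulation(0.0042)
  m2 <- ppc_to_modulation(0.0056)
  expect_equal(round(100 * m1), 30)
  expect_equal(round(100 * m2), 35)
  expect_equal(m1, 2 * (2 * sqrt(0.0042)) / (1 - 2 * sqrt(0.0042)),
               tolerance = 1e-12)
  expect_error(ppc_to_modulation(-0.1), ">= 0")
  expect_error(ppc_to_modulation(0.3), "m >= 1")
})

test_that("session beta power is suppressed during movement as generated", {
  cfg <- task_config(n_trials = 16, seed = 55L)
  s <- generate_session(cfg, unit_specs = list(unit_spec(40, beta_mod_depth = 0.3)),
                        fs_lfp = 500,
                        lfp_args = list(suppression = 0.5, noise_sd = 0.1))
  bp <- beta_power_summary(s, seed = 9)
  # amplitude suppression 0.5 -> induced power ratio ~ 0.25 after
  # movement onset (plus a small in-band noise floor); pre-onset ~ 1
  post <- bp$table[bp$table$epoch == "movement", ]
  pre <- bp$table[bp$table$epoch == "pre_movement", ]
  expect_lt(post$induced_beta, 0.42)
  expect_gt(post$induced_beta, 0.1)
  expect_gt(pre$induced_beta, 0.6)
  expect_lt(pre$induced_beta, 1.5)
  # spikes phase-locked at depth 0.3: mean beta PPC near (0.15)^2
  expect_gt(bp$unit_ppc[1], 0.005)
})
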