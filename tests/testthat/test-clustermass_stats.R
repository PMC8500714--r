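# Extended cluster-mass framework: pointwise statistics against textbook
# oracles, cluster extraction, permutation calibration, follow-up tests.

test_that("repeated-measures F matches aov() on toy tables", {
  set.seed(1)
  for (rep in 1:5) {
    N <- 4; M <- 3
    tab <- matrix(rnorm(N * M, mean = 10), N, M)
    rates <- array(tab, c(N, M, 2))      # two identical time points
    out <- rm_F_timecourse(rates)
    df <- data.frame(y = as.vector(tab),
                     unit = factor(rep(1:N, M)),
                     type = factor(rep(1:M, each = N)))
    fit <- summary(stats::aov(y ~ type + Error(unit / type), data = df))
    F_oracle <- fit[["Error: unit:type"]][[1]]["type", "F value"]
    expect_equal(out$F[1], F_oracle, tolerance = 1e-10)
    expect_equal(out$F[2], F_oracle, tolerance = 1e-10)
    # Eq identity: SS_error = SS_tot - SS_M - SS_N
    expect_equal(out$SS_error, out$SS_tot - out$SS_M - out$SS_N, tolerance = 1e-10)
  }
})

test_that("repeated-measures F invariances", {
  set.seed(2)
  rates <- array(rnorm(5 * 3 * 10), c(5, 3, 10))
  base <- rm_F_timecourse(rates)
  # all types identical within unit -> F = 0
  same <- rates
  for (m in 2:3) same[, m, ] <- same[, 1, ]
  expect_equal(max(rm_F_timecourse(same)$F, na.rm = TRUE), 0, tolerance = 1e-10)
  # adding a unit-specific constant leaves F unchanged (absorbed by SS_N)
  shifted <- rates + array(rep(rnorm(5) * 10, 3 * 10), c(5, 3, 10))
  expect_equal(rm_F_timecourse(shifted)$F, base$F, tolerance = 1e-8)
  # units with missing cells are dropped per time point
  holey <- rates
  holey[2, 1, 3] <- NA
  out <- rm_F_timecourse(holey)
  expect_equal(out$N[3], 4)
  expect_equal(out$N[1], 5)
  expect_equal(out$F[-3], base$F[-3], tolerance = 1e-10)
})

test_that("two-factor main effects match explicit-sums oracle and are symmetric", {
  set.seed(3)
  N <- 5; M <- 3; S <- 2; T_ <- 4
  rates <- array(rnorm(N * M * S * T_), c(N, M, S, T_))
  out <- twofactor_F_timecourse(rates)
  # brute-force sums at one time point
  t <- 2
  R <- rates[, , , t]
  rbar <- mean(R)
  r_m <- apply(R, 2, mean); r_s <- apply(R, 3, mean); r_j <- apply(R, 1, mean)
  SS_M <- N * S * sum((r_m - rbar)^2)
  r_mj <- apply(R, c(1, 2), mean)
  SS_MN <- S * sum((r_mj - outer(r_j, rep(1, M)) -
                      outer(rep(1, N), r_m) + rbar)^2)
  expect_equal(out$SS_M[t], SS_M, tolerance = 1e-10)
  expect_equal(out$SS_MN[t], SS_MN, tolerance = 1e-10)
  F_M_oracle <- (SS_M / (M - 1)) / (SS_MN / ((N - 1) * (M - 1)))
  expect_equal(out$F_M[t], F_M_oracle, tolerance = 1e-10)
  # swapping the factors swaps the F time courses
  swapped <- twofactor_F_timecourse(aperm(rates, c(1, 3, 2, 4)))
  expect_equal(swapped$F_M, out$F_S, tolerance = 1e-10)
  expect_equal(swapped$F_S, out$F_M, tolerance = 1e-10)
})

test_that("cluster extraction finds maximal supra-threshold runs", {
  stat <- c(0, 3, 4, 0, 0, 5, 6, 7, 0)
  cl <- extract_clusters(stat, 2)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$start, c(2, 6))
  expect_equal(cl$end, c(3, 8))
  expect_equal(cl$stat, c(7, 18))
  # custom cluster series
  cl2 <- extract_clusters(stat, 2, cluster_series = rep(1, 9))
  expect_equal(cl2$stat, c(2, 3))
  expect_equal(nrow(extract_clusters(stat, 100)), 0)
  all_in <- extract_clusters(stat, -Inf)
  expect_equal(nrow(all_in), 1)
  expect_equal(c(all_in$start, all_in$end), c(1, 9))
})

test_that("one-factor cluster-mass test: identical data gives p ~ 1, effects are found", {
  set.seed(4)
  # identical types: no clusters at all (F = 0 everywhere)
  rates <- array(rnorm(6 * 1 * 30), c(6, 1, 30))[, c(1, 1, 1), ]
  r <- cluster_mass_test(rates, n_perm = 99, seed = 1)
  expect_equal(nrow(r$clusters), 0)
  # a realistic contiguous effect (1.5 SD) is detected.  NB very large
  # effects can defeat the SS_error cluster statistic: permutations leak
  # the effect variance into SS_error, inflating the null maximum (see
  # the methods vignette).
  rates <- array(rnorm(12 * 3 * 60, sd = 0.5), c(12, 3, 60))
  rates[, 2, 20:32] <- rates[, 2, 20:32] + 0.75
  r2 <- cluster_mass_test(rates, n_perm = 199, seed = 2)
  expect_gt(nrow(r2$clusters), 0)
  best <- r2$clusters[which.min(r2$clusters$p), ]
  expect_lt(best$p, 0.02)
  # detected cluster overlaps the true epoch
  expect_true(best$start <= 32 && best$end >= 20)
  # p resolution respects (1 + n_perm)
  expect_gte(min(r2$clusters$p), 1 / 200)
})

test_that("cluster-mass FWER is near nominal under the null (reduced-size check)", {
  set.seed(5)
  rej <- replicate(60, {
    rates <- array(rnorm(10 * 3 * 40), c(10, 3, 40))
    r <- cluster_mass_test(rates, n_perm = 99)
    nrow(r$clusters) > 0 && any(r$clusters$p <= 0.05)
  })
  expect_lte(mean(rej), 0.15)            # 0.05 nominal + MC error at n=60
})

test_that("two-factor cluster test: null F_S is calibrated, sum-F variant finds effects", {
  set.seed(6)
  # no direction effect: pointwise F_S follows its F distribution
  null_rates <- array(rnorm(12 * 3 * 2 * 200), c(12, 3, 2, 200))
  tc <- twofactor_F_timecourse(null_rates)
  ks <- ks.test(tc$F_S, function(q) pf(q, tc$df_S[1], tc$df_S[2]))
  expect_gt(ks$p.value, 0.01)
  # direction effect only -> detected on factor s, not on factor m
  rates <- array(rnorm(10 * 3 * 2 * 40, sd = 0.5), c(10, 3, 2, 40))
  rates[, , 2, 15:25] <- rates[, , 2, 15:25] + 2
  rs <- twofactor_cluster_test(rates, "s", n_perm = 99, cluster_stat = "f",
                               seed = 3)
  rm_ <- twofactor_cluster_test(rates, "m", n_perm = 99, cluster_stat = "f",
                                seed = 4)
  expect_true(any(rs$clusters$p <= 0.05))
  expect_false(any(rm_$clusters$p <= 0.05))
})

test_that("single-unit trial test equals squared t for two conditions", {
  set.seed(7)
  x <- matrix(rnorm(16 * 5), 16, 5)
  labels <- rep(c("a", "b"), each = 8)
  r <- single_unit_trial_test(x, labels, n_perm = 19, seed = 1)
  t2 <- vapply(1:5, function(j)
    stats::t.test(x[labels == "a", j], x[labels == "b", j],
                  var.equal = TRUE)$statistic^2, numeric(1))
  expect_equal(r$stat, unname(t2), tolerance = 1e-10)
  # identical trials: F is 0/0 (NaN) everywhere -> no clusters
  same <- matrix(5, 10, 4)
  r0 <- single_unit_trial_test(same, rep(c("a", "b"), 5), n_perm = 19)
  expect_equal(nrow(r0$clusters), 0)
})

test_that("single-unit trial-test p-values are calibrated under the null", {
  set.seed(8)
  pv <- replicate(80, {
    x <- matrix(rnorm(20 * 25), 20, 25)
    r <- single_unit_trial_test(x, rep(c("a", "b"), 10), n_perm = 49)
    if (nrow(r$clusters)) min(r$clusters$p) else 1
  })
  # not concentrated at small values (family-wise control)
  expect_lte(mean(pv <= 0.1), 0.22)
  expect_lte(mean(pv <= 0.05), 0.15)
})

test_that("binomial unit counting matches exact tail sums", {
  r <- count_significant_units(c(0.05, 0.2, 0.08, 0.5, 0.09, rep(0.9, 5)))
  expect_equal(r$k, 3); expect_equal(r$n, 10)
  expect_equal(r$p, 1 - pbinom(2, 10, 0.1), tolerance = 1e-12)
  expect_equal(round(r$p, 4), 0.0702)
  # k = 0 -> p = 1; k = n -> p = chance^n
  expect_equal(count_significant_units(rep(1, 5))$p, 1)
  expect_equal(count_significant_units(rep(0.01, 4))$p, 0.1^4, tolerance = 1e-12)
})

test_that("Holm-Bonferroni matches the hand-worked example and p.adjust", {
  expect_equal(holm_bonferroni(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(holm_bonferroni(0.2), 0.2)
  set.seed(9)
  p <- runif(12)
  expect_equal(holm_bonferroni(p), p.adjust(p, "holm"), tolerance = 1e-12)
  expect_true(all(holm_bonferroni(p) >= p))
  expect_true(all(holm_bonferroni(p) <= 1))
})

test_that("multidimensional cluster test: null SS and detected divergence", {
  set.seed(10)
  N <- 12; T_ <- 30
  basis <- qr.Q(qr(matrix(rnorm(N * 3), N, 3)))
  # identical per-type distributions -> no significant clusters
  trial_rates <- lapply(1:N, function(u) matrix(rnorm(12 * T_), 12, T_))
  labels <- lapply(1:N, function(u) rep(c("a", "b", "c"), each = 4))
  r0 <- md_cluster_test(trial_rates, labels, basis, n_perm = 99, seed = 1)
  expect_true(nrow(r0$clusters) == 0 || all(r0$clusters$p > 0.05))
  # type-specific population pattern in an epoch -> significant cluster
  pattern <- rnorm(N, sd = 2)
  trial_rates2 <- lapply(1:N, function(u) {
    m <- matrix(rnorm(12 * T_, sd = 0.5), 12, T_)
    m[labels[[u]] == "b", 10:20] <- m[labels[[u]] == "b", 10:20] + pattern[u]
    m
  })
  r1 <- md_cluster_test(trial_rates2, labels, basis, n_perm = 99, seed = 2)
  expect_true(any(r1$clusters$p <= 0.05))
  sig <- r1$clusters[which.min(r1$clusters$p), ]
  expect_true(sig$start <= 20 && sig$end >= 10)
})

test_that("pairwise distance test: exact statistic and null behaviour", {
  set.seed(11)
  N <- 8; T_ <- 10
  basis <- diag(N)[, 1:3]
  # construct two conditions with known mean separation in unit space
  trial_rates <- lapply(1:N, function(u) matrix(rnorm(8 * T_, sd = 1e-6), 8, T_))
  labels <- lapply(1:N, function(u) rep(c("a", "b"), each = 4))
  r <- pairwise_distance_test(trial_rates, labels, basis, n_perm = 49, seed = 1)
  expect_gt(r$p, 0.05)
  expect_true(r$ci[1] <= 0 & 0 <= r$ci[2] + 1e-9)
  # inject separation delta on units 1..3 (basis columns) and check statistic
  delta <- c(2, -1, 0.5)
  trial_rates2 <- trial_rates
  for (u in 1:3) trial_rates2[[u]][labels[[u]] == "b", ] <-
    trial_rates2[[u]][labels[[u]] == "b", ] + delta[u]
  r2 <- pairwise_distance_test(trial_rates2, labels, basis, n_perm = 199, seed = 2)
  # mean squared distance: projections differ by delta (up to centering)
  expect_lt(r2$p, 0.05)
  expect_gt(r2$excess, 0)
})

test_that("mixed-effects contrast recovers an injected difference", {
  set.seed(12)
  units <- 30; subj <- rep(1:5, each = 6)
  base <- rnorm(units, 20, 4) + rnorm(5, 0, 2)[subj]
  d <- 3
  df <- data.frame(rate = c(base, base + d + rnorm(units, 0, 0.5)),
                   type = rep(c("a", "b"), each = units),
                   unit = factor(rep(1:units, 2)),
                   subject = factor(rep(subj, 2)))
  r <- mixed_contrast(df)
  expect_equal(r$estimate, d, tolerance = 0.5)
  expect_lt(r$p, 0.01)
  # single subject: flagged, subject effect dropped
  df1 <- df[df$subject == 1, ]
  r1 <- mixed_contrast(df1)
  expect_true(r1$flagged)
  expect_equal(r1$estimate, d, tolerance = 1)
})
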