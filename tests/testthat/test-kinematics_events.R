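# Kinematics, event detection, DTW trajectory averaging, Frechet
# clustering.

test_that("speed and acceleration match closed forms on constructed paths", {
  t <- seq(0, 2, by = 0.01)
  # linear motion: v = |c|, a = 0
  lin <- compute_kinematics(data.frame(t = t, x = 3 * t, y = 0),
                            sigma_smooth = 0)
  interior <- 5:(length(t) - 5)
  expect_equal(lin$v[interior], rep(3, length(interior)), tolerance = 1e-8)
  expect_equal(lin$a[interior], rep(0, length(interior)), tolerance = 1e-6)

  # circular motion radius R, angular rate w: v = Rw, a = Rw^2
  R <- 2; w <- 3
  circ <- compute_kinematics(
    data.frame(t = t, x = R * cos(w * t), y = R * sin(w * t)),
    sigma_smooth = 0)
  expect_equal(mean(circ$v[interior]), R * w, tolerance = 0.01)
  expect_equal(mean(circ$a[interior]), R * w^2, tolerance = 0.05)

  # doubling the sampling rate changes interior speed by < 1%
  t2 <- seq(0, 2, by = 0.005)
  circ2 <- compute_kinematics(
    data.frame(t = t2, x = R * cos(w * t2), y = R * sin(w * t2)),
    sigma_smooth = 0)
  expect_lt(abs(mean(circ2$v[10:390]) / mean(circ$v[interior]) - 1), 0.01)

  expect_error(compute_kinematics(data.frame(t = c(0, 0, 1), x = 1:3, y = 0)),
               "increasing")
})

test_that("session z-scoring uses pooled moments", {
  s <- small_session()
  kin <- s$kinematics
  v_all <- unlist(lapply(kin, function(k) k$v_z))
  expect_lt(abs(mean(v_all, na.rm = TRUE)), 1e-8)
  expect_equal(sd(v_all, na.rm = TRUE), 1, tolerance = 1e-8)
  # two identical sessions concatenated give the same z-scores as one
  kin2 <- zscore_kinematics(c(lapply(s$trajectories, compute_kinematics),
                              lapply(s$trajectories, compute_kinematics)))
  # identical up to the n-1 sample-SD correction
  expect_equal(kin2[[1]]$v_z, kin[[1]]$v_z, tolerance = 1e-4)
  # constant-speed session cannot be z-scored
  t <- seq(0, 1, by = 0.01)
  const <- compute_kinematics(data.frame(t = t, x = t, y = 0), sigma_smooth = 0)
  expect_error(zscore_kinematics(list(const)), "variance")
})

test_that("movement onset detection recovers ground truth and flags flat traces", {
  s <- small_session()
  tt <- s$trial_table
  kin <- lapply(s$trajectories, compute_kinematics, sigma_smooth = 0.03)
  err <- vapply(seq_len(nrow(tt)), function(i)
    detect_movement_onset(kin[[i]], tt$t_go[i])$t_move - tt$t_move[i],
    numeric(1))
  expect_lt(median(abs(err)), 0.011)      # within one kinematic sample
  expect_lt(quantile(abs(err), 0.9), 0.05)

  flat <- compute_kinematics(toy_path(rep(0, 100), rep(0, 100)))
  res <- detect_movement_onset(flat, 0)
  expect_true(res$flagged)

  # windowing to the first of two reaches detects the first
  t <- seq(0, 3, by = 0.01)
  two <- compute_kinematics(data.frame(
    t = t,
    x = stnreach:::minjerk_s((t - 0.5) / 0.5) +
        stnreach:::minjerk_s((t - 2.0) / 0.5),
    y = 0), sigma_smooth = 0)
  first <- detect_movement_onset(two, 0, t_max = 1.5)$t_move
  expect_true(first > 0.5 && first < 1.0)
})

test_that("turn onset detection recovers ground truth; straight reaches yield none", {
  s <- small_session()
  tt <- s$trial_table
  kin <- lapply(s$trajectories, compute_kinematics, sigma_smooth = 0.03)
  ti <- which(!is.na(tt$t_turn) & tt$type == "planned")
  err <- vapply(ti, function(i)
    detect_turn_onset(kin[[i]], c(tt$t_move[i] + 0.02, tt$t_feedback[i]))$t_turn -
      tt$t_turn[i], numeric(1))
  expect_lt(median(abs(err)), 0.031)

  # heading wrap across +/- pi does not disturb the estimate
  ph <- c(seq(3.0, 3.14, by = 0.01), seq(-3.14, -3.0, by = 0.01))
  unwrapped <- stnreach:::unwrap_phase(ph)
  expect_true(all(diff(unwrapped) > 0))
})

test_that("pairwise DTW mean reduces to the direct mean for aligned inputs", {
  t <- seq(0, 1, length.out = 60)
  base <- data.frame(t = t, x = stnreach:::minjerk_s(t), y = 0.2 * t)
  # identical trajectories: mean equals the trajectory resampled to n pts
  m <- pairwise_mean_trajectory(list(base, base, base), n_points = 50)
  expect_equal(m$x, approx(base$t, base$x, seq(0, 1, length.out = 50))$y,
               tolerance = 1e-8)
  # equal-length aligned trajectories: pointwise arithmetic mean
  shift <- base; shift$y <- base$y + 1
  m2 <- pairwise_mean_trajectory(list(base, shift), n_points = 60)
  expect_equal(m2$y, base$y + 0.5, tolerance = 0.02)
  # identical trajectories have zero pairwise variance
  v <- pairwise_var_trajectory(list(base, base), n_points = 40)
  expect_equal(v$var_x, rep(0, 40), tolerance = 1e-12)
})

test_that("pairwise estimators match the explicit double-loop oracle", {
  # aligned same-length paths: DTW returns the identity warp, so Eq-style
  # pairwise mean/variance must equal the direct mean and population
  # variance per time point
  t <- seq(0, 1, length.out = 30)
  set.seed(4)
  # offsets well below the sample spacing keep the DTW optimum at the
  # identity coupling, which is what the oracle equivalence assumes
  offs <- c(-0.04, 0.02, 0.08)
  paths <- lapply(offs, function(o) data.frame(t = t, x = 5 * t, y = o + t))
  m <- pairwise_mean_trajectory(paths, n_points = 30)
  expect_equal(m$y, t + mean(offs), tolerance = 1e-8)
  v <- pairwise_var_trajectory(paths, n_points = 30)
  pop_var <- mean((offs - mean(offs))^2)
  expect_equal(v$var_y, rep(pop_var, 30), tolerance = 1e-8)
  # homogeneity: scaling both coordinates by c preserves the DTW
  # couplings and scales the variance by c^2
  paths2 <- lapply(paths, function(p) { p$x <- 3 * p$x; p$y <- 3 * p$y; p })
  v2 <- pairwise_var_trajectory(paths2, n_points = 30)
  expect_equal(v2$var_y, 9 * v$var_y, tolerance = 1e-8)
})

test_that("discrete Frechet distance matches brute-force coupling search on toys", {
  # brute-force over all monotone couplings of two 3-point paths
  brute_frechet <- function(A, B) {
    n <- nrow(A); m <- nrow(B)
    d <- function(i, j) sqrt(sum((A[i, ] - B[j, ])^2))
    best <- Inf
    # enumerate all coupling sequences by DFS
    rec <- function(i, j, cur) {
      cur <- max(cur, d(i, j))
      if (cur >= best) return()
      if (i == n && j == m) { best <<- cur; return() }
      if (i < n) rec(i + 1, j, cur)
      if (j < m) rec(i, j + 1, cur)
      if (i < n && j < m) rec(i + 1, j + 1, cur)
    }
    rec(1, 1, 0)
    best
  }
  set.seed(7)
  for (rep in 1:5) {
    A <- matrix(rnorm(6), 3, 2); B <- matrix(rnorm(8), 4, 2)
    pa <- data.frame(t = 1:3, x = A[, 1], y = A[, 2])
    pb <- data.frame(t = 1:4, x = B[, 1], y = B[, 2])
    expect_equal(frechet_distance(pa, pb), brute_frechet(A, B), tolerance = 1e-12)
    expect_equal(frechet_distance(pa, pb), frechet_distance(pb, pa))
  }
  p <- toy_path(1:5, c(0, 1, 0, 1, 0))
  expect_equal(frechet_distance(p, p), 0)
})

test_that("trajectory clustering separates reach from turn shapes", {
  s <- small_session()
  tt <- s$trial_table
  idx <- which(tt$type %in% c("reach", "planned"))
  segs <- lapply(idx, function(i) {
    tr <- tt[i, ]
    p <- s$trajectories[[i]]
    p <- p[p$t >= tr$t_move - 0.05 & p$t <= tr$t_feedback, ]
    p$x <- abs(p$x)                      # fold directions together
    p
  })
  cl <- cluster_trajectories(segs, k = 2)
  truth <- as.integer(factor(tt$type[idx]))
  purity <- max(mean(cl$labels == truth), mean(cl$labels == 3 - truth))
  expect_gt(purity, 0.95)
})
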