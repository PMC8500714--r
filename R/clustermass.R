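# Extended cluster-mass permutation framework for repeated-measures time
# series.
#
# Choosing analysis intervals in time series invites Type I error; the
# cluster mass test instead thresholds a pointwise statistic, forms
# contiguous supra-threshold time clusters, and assesses each cluster's
# mass against a permutation null of the maximum cluster mass, giving
# family-wise control over time.  Units are repeated measures (random
# effects) and trial types fixed effects, so the pointwise statistic is a
# repeated-measures ANOVA F; the framework extends to two factors, to
# multidimensional (PC-space) data where sums of squares replace F, and to
# trial-level tests within single units.

#' One-factor repeated-measures F time course
#'
#' For rates `r[j, m](t)` with units j as repeated measures and trial
#' types m as the factor:
#' `SS_tot = sum_jm (r - rbar)^2`, `SS_M = N sum_m (rbar_m - rbar)^2`,
#' `SS_N = M sum_j (rbar_j - rbar)^2`, `SS_error = SS_tot - SS_M - SS_N`,
#' and `F = (SS_M / (M-1)) / (SS_error / ((N-1)(M-1)))`.
#'
#' Units with a missing cell at a time point are dropped from that time
#' point only; the per-time unit count is returned.
#'
#' @param rates numeric array `[unit, type, time]`.
#' @return list: `F`, `SS_M`, `SS_N`, `SS_tot`, `SS_error` (vectors over
#'   time), `N` (units used per time point), `M`, `df1`, `df2` (per time
#'   point).
#' @export
rm_F_timecourse <- function(rates) {
  stopifnot(length(dim(rates)) == 3)
  N <- dim(rates)[1]; M <- dim(rates)[2]; T_ <- dim(rates)[3]
  if (N < 2 || M < 2) stop("need at least 2 units and 2 types", call. = FALSE)
  flat <- matrix(rates, N * M, T_)
  if (!anyNA(flat)) {
    rbar <- colMeans(flat)
    Am <- matrix(NA_real_, M, T_); Aj <- matrix(NA_real_, N, T_)
    for (m in seq_len(M)) Am[m, ] <- colMeans(matrix(rates[, m, ], N, T_))
    for (j in seq_len(N)) Aj[j, ] <- colMeans(matrix(rates[j, , ], M, T_))
    SS_tot <- colSums(sweep(flat, 2, rbar)^2)
    SS_M <- N * colSums(sweep(Am, 2, rbar)^2)
    SS_N <- M * colSums(sweep(Aj, 2, rbar)^2)
    Nt <- rep(N, T_)
  } else {
    SS_tot <- SS_M <- SS_N <- numeric(T_); Nt <- integer(T_)
    for (t in seq_len(T_)) {
      R <- rates[, , t]
      keep <- stats::complete.cases(R)
      Nt[t] <- sum(keep)
      if (Nt[t] < 2) { SS_tot[t] <- SS_M[t] <- SS_N[t] <- NA_real_; next }
      R <- R[keep, , drop = FALSE]
      rb <- mean(R)
      SS_tot[t] <- sum((R - rb)^2)
      SS_M[t] <- Nt[t] * sum((colMeans(R) - rb)^2)
      SS_N[t] <- M * sum((rowMeans(R) - rb)^2)
    }
  }
  SS_error <- SS_tot - SS_M - SS_N
  df1 <- M - 1; df2 <- (Nt - 1) * (M - 1)
  Fv <- (SS_M / df1) / (SS_error / df2)
  list(F = Fv, SS_M = SS_M, SS_N = SS_N, SS_tot = SS_tot,
       SS_error = SS_error, N = Nt, M = M, df1 = df1, df2 = df2)
}

#' Two-factor repeated-measures main-effect F time courses
#'
#' For rates `r[j, m, s](t)` with factors m (M levels) and s (S levels):
#' `SS_M = N S sum_m (rbar_m - rbar)^2` and analogously for s; each main
#' effect is tested against its factor-by-unit interaction,
#' `SS_MN = S sum_m sum_j (rbar_mj - rbar_m - rbar_j + rbar)^2`, giving
#' `F_M = (SS_M/(M-1)) / (SS_MN/((N-1)(M-1)))` and the analogous `F_S`.
#'
#' @param rates numeric array `[unit, m, s, time]` (complete).
#' @return list with `F_M`, `F_S`, `SS_M`, `SS_S`, `SS_MN`, `SS_SN`, and
#'   the degrees of freedom.
#' @export
twofactor_F_timecourse <- function(rates) {
  stopifnot(length(dim(rates)) == 4, !anyNA(rates))
  N <- dim(rates)[1]; M <- dim(rates)[2]; S <- dim(rates)[3]; T_ <- dim(rates)[4]
  rbar <- apply(rates, 4, mean)
  r_m <- apply(rates, c(2, 4), mean)    # M x T
  r_s <- apply(rates, c(3, 4), mean)    # S x T
  r_j <- apply(rates, c(1, 4), mean)    # N x T
  r_mj <- apply(rates, c(1, 2, 4), mean) # N x M x T
  r_sj <- apply(rates, c(1, 3, 4), mean) # N x S x T
  SS_M <- N * S * colSums(sweep(r_m, 2, rbar)^2)
  SS_S <- N * M * colSums(sweep(r_s, 2, rbar)^2)
  SS_MN <- SS_SN <- numeric(T_)
  for (t in seq_len(T_)) {
    d1 <- r_mj[, , t] - matrix(r_m[, t], N, M, byrow = TRUE) -
      matrix(r_j[, t], N, M) + rbar[t]
    SS_MN[t] <- S * sum(d1^2)
    d2 <- r_sj[, , t] - matrix(r_s[, t], N, S, byrow = TRUE) -
      matrix(r_j[, t], N, S) + rbar[t]
    SS_SN[t] <- M * sum(d2^2)
  }
  F_M <- (SS_M / (M - 1)) / (SS_MN / ((N - 1) * (M - 1)))
  F_S <- (SS_S / (S - 1)) / (SS_SN / ((N - 1) * (S - 1)))
  list(F_M = F_M, F_S = F_S, SS_M = SS_M, SS_S = SS_S,
       SS_MN = SS_MN, SS_SN = SS_SN, N = N, M = M, S = S,
       df_M = c(M - 1, (N - 1) * (M - 1)), df_S = c(S - 1, (N - 1) * (S - 1)))
}

#' Extract supra-threshold clusters
#'
#' Maximal contiguous runs where the statistic exceeds the threshold.
#' The cluster statistic is the sum of `cluster_series` (by default the
#' thresholded statistic itself) within each run.
#'
#' @param stat numeric statistic time course (NA treated as below
#'   threshold).
#' @param threshold scalar or per-time-point threshold.
#' @param cluster_series series summed within clusters (default `stat`).
#' @return `data.frame` with `start`, `end` (indices), `stat`.
#' @export
extract_clusters <- function(stat, threshold, cluster_series = stat) {
  above <- !is.na(stat) & stat > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  sel <- which(r$values)
  data.frame(start = starts[sel], end = ends[sel],
             stat = vapply(sel, function(k)
               sum(cluster_series[starts[k]:ends[k]]), numeric(1)))
}

# Permute type labels within each unit: rates[j, perm_j, t].
permute_within_units <- function(rates) {
  N <- dim(rates)[1]; M <- dim(rates)[2]
  out <- rates
  for (j in seq_len(N)) out[j, , ] <- rates[j, sample(M), ]
  out
}

#' One-factor cluster-mass permutation test
#'
#' Computes the repeated-measures F time course, thresholds it at the
#' 90th percentile of the F distribution, forms clusters whose statistic
#' is the within-cluster sum of `SS_error` (options: `SS_M` or `F`), and
#' compares each cluster against the permutation distribution of the
#' maximum cluster statistic obtained by permuting trial-type labels
#' within each unit.  `p = (1 + #(null >= obs)) / (1 + n_perm)`.
#'
#' @param rates array `[unit, type, time]`.
#' @param n_perm number of permutations (default 1000).
#' @param threshold_quantile F-distribution quantile for the pointwise
#'   threshold (default 0.9).
#' @param cluster_stat `"ss_error"` (default), `"ss_m"`, or `"f"`.
#' @param seed optional integer seed.
#' @return a `cluster_mass_result`: `stat` (F time course), `threshold`,
#'   `clusters` (`start`, `end`, `stat`, `p`), `null` (max cluster stats),
#'   `n_perm`, `effect`.
#' @export
cluster_mass_test <- function(rates, n_perm = 1000, threshold_quantile = 0.9,
                              cluster_stat = c("ss_error", "ss_m", "f"),
                              seed = NULL) {
  cluster_stat <- match.arg(cluster_stat)
  if (n_perm < 19) warning("n_perm too small for alpha = 0.05")
  obs <- rm_F_timecourse(rates)
  thr <- stats::qf(threshold_quantile, obs$df1, obs$df2)
  series <- switch(cluster_stat, ss_error = obs$SS_error, ss_m = obs$SS_M, f = obs$F)
  clusters <- extract_clusters(obs$F, thr, series)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- rm_F_timecourse(permute_within_units(rates))
    ps <- switch(cluster_stat, ss_error = p$SS_error, ss_m = p$SS_M, f = p$F)
    cl <- extract_clusters(p$F, stats::qf(threshold_quantile, p$df1, p$df2), ps)
    if (nrow(cl)) max(cl$stat) else 0
  }, numeric(1)))
  clusters$p <- vapply(clusters$stat, function(s)
    (1 + sum(null >= s)) / (1 + n_perm), numeric(1))
  structure(list(stat = obs$F, threshold = thr, clusters = clusters,
                 null = null, n_perm = n_perm, effect = "type",
                 pointwise = obs),
            class = "cluster_mass_result")
}

#' Two-factor cluster-mass permutation test
#'
#' Main-effect version of [cluster_mass_test()] for rates
#' `[unit, m, s, time]`.  Only the tested factor's labels are permuted
#' within each unit (the exchangeable units under its null); the cluster
#' statistic is the within-cluster sum of the denominator sum of squares
#' of the respective F.
#'
#' @param rates array `[unit, m, s, time]`.
#' @param effect `"m"` or `"s"`.
#' @param cluster_stat `"denominator"` (default; within-cluster sum of the
#'   tested F's denominator sum of squares) or `"f"` (sum of F values,
#'   which can be more sensitive when an effect is homogeneous across
#'   units and contributes little to the interaction term).
#' @inheritParams cluster_mass_test
#' @return a `cluster_mass_result`.
#' @export
twofactor_cluster_test <- function(rates, effect = c("m", "s"), n_perm = 1000,
                                   threshold_quantile = 0.9,
                                   cluster_stat = c("denominator", "f"),
                                   seed = NULL) {
  effect <- match.arg(effect)
  cluster_stat <- match.arg(cluster_stat)
  N <- dim(rates)[1]
  pick <- function(tc) {
    out <- if (effect == "m") list(F = tc$F_M, den = tc$SS_MN, df = tc$df_M)
    else list(F = tc$F_S, den = tc$SS_SN, df = tc$df_S)
    if (cluster_stat == "f") out$den <- out$F
    out
  }
  obs <- pick(twofactor_F_timecourse(rates))
  thr <- stats::qf(threshold_quantile, obs$df[1], obs$df[2])
  clusters <- extract_clusters(obs$F, thr, obs$den)
  permute_effect <- function(r) {
    out <- r
    for (j in seq_len(N)) {
      if (effect == "m") out[j, , , ] <- r[j, sample(dim(r)[2]), , ]
      else out[j, , , ] <- r[j, , sample(dim(r)[3]), ]
    }
    out
  }
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- pick(twofactor_F_timecourse(permute_effect(rates)))
    cl <- extract_clusters(p$F, thr, p$den)
    if (nrow(cl)) max(cl$stat) else 0
  }, numeric(1)))
  clusters$p <- vapply(clusters$stat, function(s)
    (1 + sum(null >= s)) / (1 + n_perm), numeric(1))
  structure(list(stat = obs$F, threshold = thr, clusters = clusters,
                 null = null, n_perm = n_perm, effect = effect),
            class = "cluster_mass_result")
}

# Project per-unit condition means onto a unit-space basis.
# unit_means: units x time matrix for one condition; basis: units x D.
project_condition <- function(unit_means, basis) {
  ctr <- colMeans(unit_means)           # across-unit mean per time point
  t(unit_means - matrix(ctr, nrow(unit_means), ncol(unit_means),
                        byrow = TRUE)) %*% basis   # time x D
}

# Per-unit mean rates per level from trial-level data.
# trial_rates: list per unit of [trials x T]; labels: list per unit.
unit_level_means <- function(trial_rates, labels, levels) {
  N <- length(trial_rates); T_ <- ncol(trial_rates[[1]])
  out <- lapply(levels, function(lv) {
    m <- matrix(NA_real_, N, T_)
    for (j in seq_len(N)) {
      sel <- labels[[j]] == lv
      m[j, ] <- colMeans(trial_rates[[j]][sel, , drop = FALSE])
    }
    m
  })
  names(out) <- levels
  out
}

#' Multidimensional (PC-space) cluster-mass test
#'
#' Projected population trajectories have no repeated measures, so sums
#' of squares replace F: `SS_M(t) = S sum_m ||Qbar_m(t) - Qbar(t)||^2` in
#' the D-dimensional component space.  The pointwise threshold is the
#' 90th percentile of the permutation distribution of `SS_M` at each time
#' point; permutations shuffle trial labels of the tested factor within
#' each unit, recompute unit condition means, and re-project onto the
#' same components as the original data.  Cluster statistics are
#' within-cluster sums of `SS_M`, compared to the permutation maximum.
#'
#' @param trial_rates list (one per unit) of `[trial x time]` rate
#'   matrices.
#' @param labels list (one per unit) of per-trial factor labels.
#' @param basis units x D unit-space basis (from [fit_population_pca()]).
#' @param n_perm permutations (default 1000).
#' @param threshold_quantile percentile for the pointwise threshold.
#' @param S number of levels of the (already-averaged-out) second factor,
#'   used only as the multiplier in `SS_M` (default 1).
#' @param seed optional integer seed.
#' @return a `cluster_mass_result` with `stat` = SS time course.
#' @export
md_cluster_test <- function(trial_rates, labels, basis, n_perm = 1000,
                            threshold_quantile = 0.9, S = 1, seed = NULL) {
  levels_m <- sort(unique(unlist(labels)))
  ss_series <- function(lab) {
    um <- unit_level_means(trial_rates, lab, levels_m)
    Q <- lapply(um, project_condition, basis = basis)   # time x D each
    Qbar <- Reduce(`+`, Q) / length(Q)
    S * Reduce(`+`, lapply(Q, function(q) rowSums((q - Qbar)^2)))
  }
  obs <- ss_series(labels)
  perms <- with_seed(seed, lapply(seq_len(n_perm), function(i)
    ss_series(lapply(labels, sample))))
  perm_mat <- do.call(rbind, perms)     # n_perm x T
  thr <- apply(perm_mat, 2, stats::quantile, probs = threshold_quantile)
  clusters <- extract_clusters(obs, thr, obs)
  null <- vapply(seq_len(n_perm), function(i) {
    cl <- extract_clusters(perm_mat[i, ], thr, perm_mat[i, ])
    if (nrow(cl)) max(cl$stat) else 0
  }, numeric(1))
  clusters$p <- vapply(clusters$stat, function(s)
    (1 + sum(null >= s)) / (1 + n_perm), numeric(1))
  structure(list(stat = obs, threshold = thr, clusters = clusters,
                 null = null, n_perm = n_perm, effect = "type (PC space)"),
            class = "cluster_mass_result")
}

#' Pairwise state-space distance permutation test
#'
#' Statistic: time-averaged squared Euclidean distance between two
#' condition trajectories within a window.  The permutation null shuffles
#' the two conditions' trial labels within each unit and re-projects onto
#' the fixed components.  The observed statistic minus each null value
#' forms the distribution of distance-above-chance, summarised by its
#' mean and 95% percentile interval.
#'
#' @param trial_rates,labels,basis as in [md_cluster_test()], with labels
#'   restricted to the two compared levels.
#' @param window integer index range (length 2) over time, default all.
#' @param n_perm permutations (1000 supports a minimum Holm-Bonferroni
#'   corrected p of 0.001 for a single comparison; use 3000 for three).
#' @param seed optional integer seed.
#' @return list: `p`, `distance` (observed mean squared distance),
#'   `excess` (mean distance above chance), `ci` (95% interval), `null`.
#' @export
pairwise_distance_test <- function(trial_rates, labels, basis,
                                   window = NULL, n_perm = 1000, seed = NULL) {
  lv <- sort(unique(unlist(labels)))
  if (length(lv) != 2) stop("labels must have exactly 2 levels", call. = FALSE)
  msd <- function(lab) {
    um <- unit_level_means(trial_rates, lab, lv)
    Q <- lapply(um, project_condition, basis = basis)
    d2 <- rowSums((Q[[1]] - Q[[2]])^2)
    if (!is.null(window)) d2 <- d2[window[1]:window[2]]
    mean(d2)
  }
  obs <- msd(labels)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    msd(lapply(labels, sample)), numeric(1)))
  excess_dist <- obs - null
  list(p = (1 + sum(null >= obs)) / (1 + n_perm),
       distance = obs,
       excess = mean(excess_dist),
       ci = unname(stats::quantile(excess_dist, c(0.025, 0.975))),
       null = null)
}

#' Single-unit trial-level cluster-mass test
#'
#' One-way between-trials F at each time point (`F = t^2` for two
#' conditions), thresholded at the 90th percentile of the F distribution;
#' cluster statistic is the within-cluster sum of `SS_error`; the null
#' randomly partitions trials among conditions keeping counts fixed.
#'
#' @param trial_rates `[trial x time]` matrix for one unit.
#' @param labels per-trial condition labels.
#' @param n_perm permutations (default 1000).
#' @param threshold_quantile F quantile (default 0.9).
#' @param seed optional integer seed.
#' @return a `cluster_mass_result`.
#' @export
single_unit_trial_test <- function(trial_rates, labels, n_perm = 1000,
                                   threshold_quantile = 0.9, seed = NULL) {
  lv <- sort(unique(labels)); M <- length(lv); N <- length(labels)
  if (M < 2) stop("need at least 2 conditions", call. = FALSE)
  fstat <- function(lab) {
    rbar <- colMeans(trial_rates)
    SS_tot <- colSums(sweep(trial_rates, 2, rbar)^2)
    SS_M <- 0
    for (m in lv) {
      sel <- lab == m
      SS_M <- SS_M + sum(sel) * (colMeans(trial_rates[sel, , drop = FALSE]) - rbar)^2
    }
    SS_err <- SS_tot - SS_M
    list(F = (SS_M / (M - 1)) / (SS_err / (N - M)), SS_err = SS_err)
  }
  obs <- fstat(labels)
  thr <- stats::qf(threshold_quantile, M - 1, N - M)
  clusters <- extract_clusters(obs$F, thr, obs$SS_err)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- fstat(sample(labels))
    cl <- extract_clusters(p$F, thr, p$SS_err)
    if (nrow(cl)) max(cl$stat) else 0
  }, numeric(1)))
  clusters$p <- vapply(clusters$stat, function(s)
    (1 + sum(null >= s)) / (1 + n_perm), numeric(1))
  structure(list(stat = obs$F, threshold = thr, clusters = clusters,
                 null = null, n_perm = n_perm, effect = "trial condition"),
            class = "cluster_mass_result")
}

#' Binomial counting of significant units
#'
#' With a per-unit cluster significance criterion of `p < p_thresh`, the
#' chance expectation is that a fraction `chance` of units shows a
#' significant cluster; the upper-tail binomial probability of observing
#' at least `k` such units among `n` tests that null hypothesis.
#'
#' @param unit_pvals list (or vector) of per-unit minimum cluster
#'   p-values (NA = no cluster, counts as not significant).
#' @param p_thresh per-unit criterion (default 0.1).
#' @param chance null success rate (default 0.1).
#' @return list: `k`, `n`, `p` (`P(X >= k)` under Binomial(n, chance)).
#' @export
count_significant_units <- function(unit_pvals, p_thresh = 0.1, chance = 0.1) {
  pv <- unlist(unit_pvals)
  sig <- !is.na(pv) & pv < p_thresh
  k <- sum(sig); n <- length(pv)
  p <- stats::pbinom(k - 1, n, chance, lower.tail = FALSE)
  list(k = k, n = n, p = p)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Ordered p-values `p_(i)` are multiplied by `(n - i + 1)`, a running
#' maximum enforces monotonicity, and results are capped at 1.
#'
#' @param pvals numeric p-values.
#' @return adjusted p-values in the original order.
#' @export
holm_bonferroni <- function(pvals) {
  n <- length(pvals)
  o <- order(pvals)
  adj <- pmin(1, cummax(pvals[o] * (n - seq_len(n) + 1)))
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Mixed-effects pairwise contrast of firing rates
#'
#' Thin contract over an established mixed-model routine: the fixed
#' effect is the firing-rate difference between two trial types, with
#' random intercepts for subjects and units nested within subjects.
#' Rates should be pre-averaged within the interval of interest (one
#' value per unit and type).  With a single subject the subject effect is
#' dropped; on a singular or failed fit the routine falls back to a
#' unit-level paired t-test, flagged.
#'
#' @param df `data.frame` with columns `rate`, `type` (2 levels),
#'   `unit`, `subject`.
#' @return list: `estimate` (type difference), `p`, `method`, `flagged`.
#' @export
mixed_contrast <- function(df) {
  stopifnot(all(c("rate", "type", "unit", "subject") %in% names(df)))
  df$type <- factor(df$type)
  if (nlevels(df$type) != 2) stop("exactly two trial types required", call. = FALSE)
  one_subject <- length(unique(df$subject)) < 2
  form <- if (one_subject) rate ~ type + (1 | unit)
  else rate ~ type + (1 | subject / unit)
  fit <- tryCatch(lme4::lmer(form, data = df, REML = FALSE),
                  error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
    est <- lme4::fixef(fit)[2]
    # likelihood-ratio p against the no-type model
    fit0 <- lme4::lmer(stats::update(form, . ~ . - type), data = df, REML = FALSE)
    p <- stats::anova(fit0, fit)[2, "Pr(>Chisq)"]
    return(list(estimate = unname(est), p = p,
                method = if (one_subject) "lmm (no subject effect)" else "lmm",
                flagged = one_subject))
  }
  # fallback: paired t-test over units
  w <- stats::reshape(df[, c("rate", "type", "unit")], direction = "wide",
                      idvar = "unit", timevar = "type")
  tt <- stats::t.test(w[[3]], w[[2]], paired = TRUE)
  list(estimate = unname(tt$estimate), p = tt$p.value,
       method = "paired t (fallback)", flagged = TRUE)
}
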