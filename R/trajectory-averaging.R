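# Trajectory averaging and clustering.  Self-paced movements take
# different times, so averaging positions at a fixed clock time misstates
# spatial variability.  The pairwise estimators instead align every
# ordered pair of trajectories with dynamic time warping, average the
# aligned positions, and combine the N^2 pairwise results; with identity
# alignments they reduce exactly to the ordinary mean and population
# variance.

#' Align a pair of 2D trajectories with dynamic time warping
#'
#' Symmetric step pattern, Euclidean local cost, no window constraint.
#'
#' @param a,b `data.frame`s with columns `t`, `x`, `y`.
#' @return list with index vectors `i`, `j` (the coupling), the total
#'   alignment `distance`, and `mean_path`: a data.frame of the averaged
#'   aligned positions with `t` the mean of the two aligned times.
#' @export
dtw_align <- function(a, b) {
  al <- dtw_path_cpp(cbind(a$x, a$y), cbind(b$x, b$y))
  mp <- data.frame(t = (a$t[al$i] + b$t[al$j]) / 2,
                   x = (a$x[al$i] + b$x[al$j]) / 2,
                   y = (a$y[al$i] + b$y[al$j]) / 2)
  list(i = al$i, j = al$j, distance = al$distance, mean_path = mp)
}

# Resample a path to n_out points equally spaced in its (warped) time.
resample_path <- function(p, n_out = 200) {
  tt <- seq(min(p$t), max(p$t), length.out = n_out)
  data.frame(t = tt, x = interp1(p$t, p$x, tt), y = interp1(p$t, p$y, tt))
}

#' Pairwise mean trajectory
#'
#' For every ordered pair (i, j) of trajectories -- including i = j, as in
#' the identity the estimator is derived from -- the pair is DTW-aligned,
#' the aligned positions averaged, and the pairwise mean resampled to
#' `n_points` equally spaced warped-time points.  The mean trajectory is
#' the pointwise average of all N^2 pairwise means.
#'
#' @param trajectories list of `data.frame`s (`t`, `x`, `y`);
#'   trajectories with fewer than 2 points are excluded with a warning.
#' @param n_points number of resampled points (default 200).
#' @return `data.frame` with `t` (index 1..n_points mapped to mean warped
#'   time), `x`, `y`.
#' @export
pairwise_mean_trajectory <- function(trajectories, n_points = 200) {
  trajectories <- drop_degenerate(trajectories)
  n <- length(trajectories)
  if (n < 2) stop("need at least 2 usable trajectories", call. = FALSE)
  acc <- matrix(0, n_points, 3)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    mp <- resample_path(dtw_align(trajectories[[i]], trajectories[[j]])$mean_path,
                        n_points)
    acc <- acc + as.matrix(mp)
  }
  acc <- acc / n^2
  data.frame(t = acc[, 1], x = acc[, 2], y = acc[, 3])
}

#' Pairwise trajectory variance
#'
#' Variance of a trajectory set from aligned pairs:
#' `sigma^2(t) = N^-3 * sum_k (sum_l delta_kl(t))^2` per coordinate, where
#' `delta_kl(t)` is the difference of DTW-aligned positions of pair
#' (k, l), resampled to the common grid.  For identity alignments this is
#' exactly the population variance per time point.
#'
#' @inheritParams pairwise_mean_trajectory
#' @return `data.frame` with `var_x`, `var_y`, `sd_x`, `sd_y` per
#'   resampled point.
#' @export
pairwise_var_trajectory <- function(trajectories, n_points = 200) {
  trajectories <- drop_degenerate(trajectories)
  n <- length(trajectories)
  if (n < 2) stop("need at least 2 usable trajectories", call. = FALSE)
  sx <- matrix(0, n_points, n)          # sum over l of delta_kl, per k
  sy <- matrix(0, n_points, n)
  for (k in seq_len(n)) for (l in seq_len(n)) {
    al <- dtw_align(trajectories[[k]], trajectories[[l]])
    a <- trajectories[[k]]; b <- trajectories[[l]]
    dp <- data.frame(t = (a$t[al$i] + b$t[al$j]) / 2,
                     x = a$x[al$i] - b$x[al$j],
                     y = a$y[al$i] - b$y[al$j])
    dp <- resample_path(dp, n_points)
    sx[, k] <- sx[, k] + dp$x
    sy[, k] <- sy[, k] + dp$y
  }
  vx <- rowSums(sx^2) / n^3
  vy <- rowSums(sy^2) / n^3
  data.frame(var_x = vx, var_y = vy, sd_x = sqrt(vx), sd_y = sqrt(vy))
}

drop_degenerate <- function(trajectories) {
  bad <- vapply(trajectories, function(p) nrow(p) < 2, logical(1))
  if (any(bad)) warning(sum(bad), " trajectory(ies) with <2 points excluded")
  trajectories[!bad]
}

#' Discrete Frechet distance between two trajectories
#'
#' @param a,b `data.frame`s with `x`, `y`.
#' @return the discrete Frechet distance.
#' @export
frechet_distance <- function(a, b) {
  frechet_dist_cpp(cbind(a$x, a$y), cbind(b$x, b$y))
}

#' Hierarchically cluster trajectories by shape
#'
#' Pairwise discrete Frechet distance matrix, Ward linkage (`ward.D2`),
#' tree cut at `k` clusters.
#'
#' @param trajectories list of `data.frame`s (`t`, `x`, `y`).
#' @param k number of clusters to cut (default 2).
#' @return list with `tree` (hclust), `labels` (integer vector), `dist`
#'   (the Frechet distance matrix).
#' @export
cluster_trajectories <- function(trajectories, k = 2) {
  n <- length(trajectories)
  dmat <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    dmat[i, j] <- dmat[j, i] <- frechet_distance(trajectories[[i]], trajectories[[j]])
  tree <- stats::hclust(stats::as.dist(dmat), method = "ward.D2")
  list(tree = tree, labels = stats::cutree(tree, k = k), dist = dmat)
}
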