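# Kinematics: Gaussian-smoothed positions, backward-difference speed and
# acceleration, session z-scoring, and detection of movement and turn
# onsets from the cursor path.

#' Compute speed and acceleration from cursor positions
#'
#' Positions are smoothed with a Gaussian kernel (default SD 10 ms,
#' reflection padding at the edges), then differentiated with backward
#' differences, dividing by the actual sample interval so irregular
#' sampling is handled:
#' `v(t) = (x(t) - x(t - dt)) / dt`, and acceleration is the backward
#' difference of the velocity.  Magnitudes are Euclidean norms of the
#' component vectors.
#'
#' @param positions `data.frame` with columns `t`, `x`, `y` (t strictly
#'   increasing, at least 3 samples).
#' @param sigma_smooth Gaussian smoothing SD in seconds (default 0.010).
#' @return a `kinematics_series`: the input plus `vx, vy, v, ax, ay, a`
#'   (first samples of each difference order are NA).
#' @export
compute_kinematics <- function(positions, sigma_smooth = 0.010) {
  t <- positions$t
  if (length(t) < 3) stop("need at least 3 samples", call. = FALSE)
  if (any(diff(t) <= 0)) stop("t must be strictly increasing", call. = FALSE)
  dt_med <- stats::median(diff(t))
  x <- gauss_smooth(positions$x, dt_med, sigma_smooth)
  y <- gauss_smooth(positions$y, dt_med, sigma_smooth)
  dt <- diff(t)
  bdiff <- function(z) c(NA, diff(z) / dt)
  vx <- bdiff(x); vy <- bdiff(y)
  ax <- bdiff(vx); ay <- bdiff(vy)
  out <- positions
  out$x_s <- x; out$y_s <- y
  out$vx <- vx; out$vy <- vy; out$v <- sqrt(vx^2 + vy^2)
  out$ax <- ax; out$ay <- ay; out$a <- sqrt(ax^2 + ay^2)
  class(out) <- c("kinematics_series", class(out))
  out
}

#' Z-score kinematic magnitudes across a session
#'
#' Speed and acceleration magnitudes are z-scored with the pooled mean and
#' SD over all samples of all trials in the session, adding `v_z` and
#' `a_z` columns to every series.
#'
#' @param kin_list list of `kinematics_series` (one per trial).
#' @return the list with `v_z`, `a_z` columns added, plus attributes
#'   `v_moments` and `a_moments` (`c(mean, sd)`).
#' @export
zscore_kinematics <- function(kin_list) {
  v_all <- unlist(lapply(kin_list, function(k) k$v))
  a_all <- unlist(lapply(kin_list, function(k) k$a))
  mv <- mean(v_all, na.rm = TRUE); sv <- stats::sd(v_all, na.rm = TRUE)
  ma <- mean(a_all, na.rm = TRUE); sa <- stats::sd(a_all, na.rm = TRUE)
  if (!is.finite(sv) || sv == 0 || !is.finite(sa) || sa == 0)
    stop("zero variance in session kinematics; cannot z-score", call. = FALSE)
  out <- lapply(kin_list, function(k) {
    k$v_z <- (k$v - mv) / sv
    k$a_z <- (k$a - ma) / sa
    k
  })
  attr(out, "v_moments") <- c(mean = mv, sd = sv)
  attr(out, "a_moments") <- c(mean = ma, sd = sa)
  out
}

#' Detect movement onset
#'
#' Movement onset is the period of maximum acceleration that most closely
#' precedes the peak cursor velocity: the global speed peak after the go
#' cue is found first, then the latest local maximum of the acceleration
#' magnitude at or before that peak is returned (ties broken toward later
#' time).  If no acceleration peak precedes the speed peak, the first
#' crossing of 10% of peak speed is returned with `flagged = TRUE`.
#'
#' @param kin a `kinematics_series` covering go to feedback.
#' @param go_time search start (s).
#' @param t_max optional search end (s).
#' @param min_height candidate acceleration peaks must reach this fraction
#'   of the window's acceleration maximum (default 0.5); guards the
#'   "latest local maximum" rule against spurious noise maxima.
#' @return list with `t_move` (NA if the trace is flat), `flagged`.
#' @export
detect_movement_onset <- function(kin, go_time, t_max = Inf, min_height = 0.5) {
  sel <- which(kin$t >= go_time & kin$t <= t_max & !is.na(kin$v) & !is.na(kin$a))
  if (length(sel) < 3) return(list(t_move = NA_real_, flagged = TRUE))
  v <- kin$v[sel]; a <- kin$a[sel]; tt <- kin$t[sel]
  vmax <- max(v)
  if (vmax < 1e-9) return(list(t_move = NA_real_, flagged = TRUE))
  ipk <- which.max(v)
  # local maxima of acceleration at or before the speed peak, restricted
  # to peaks of substantial height
  am <- a[seq_len(ipk)]
  loc <- which(diff(sign(diff(am))) < 0) + 1
  if (ipk >= 2 && am[ipk] > am[ipk - 1]) loc <- c(loc, ipk)
  loc <- loc[am[loc] >= min_height * max(am)]
  if (length(loc) == 0) {
    cross <- which(v >= 0.1 * vmax)[1]
    return(list(t_move = tt[cross], flagged = TRUE))
  }
  list(t_move = tt[max(loc)], flagged = FALSE)
}

#' Detect turn onset
#'
#' Turn onset is the time of maximum angular acceleration of the cursor.
#' The movement heading is computed from the velocity vector, unwrapped,
#' and masked where speed falls below 5% of the trial's peak speed (the
#' heading is undefined near rest); angular velocity and acceleration are
#' successive differences of the unwrapped heading.  The maximum of the
#' absolute angular acceleration within the search window is returned.
#'
#' @param kin a `kinematics_series`.
#' @param turn_window length-2 search window (s, session clock).
#' @param speed_floor_frac heading mask threshold as a fraction of peak
#'   speed (default 0.05).
#' @param heading_smooth_s Gaussian smoothing SD applied to the unwrapped
#'   heading before differentiation (default 30 ms); heading derivatives
#'   are otherwise dominated by position noise.
#' @return list with `t_turn` (NA if no valid samples in the window) and
#'   `flagged`.
#' @export
detect_turn_onset <- function(kin, turn_window, speed_floor_frac = 0.05,
                              heading_smooth_s = 0.03) {
  ok <- !is.na(kin$v)
  vmax <- max(kin$v[ok])
  heading <- atan2(kin$vy, kin$vx)
  masked <- !ok | kin$v < speed_floor_frac * vmax
  heading[masked] <- NA
  heading <- unwrap_phase(heading)
  # bridge masked stretches and smooth before differentiating
  idx <- which(!is.na(heading))
  if (length(idx) < 5) return(list(t_turn = NA_real_, flagged = TRUE))
  hfill <- interp1(kin$t[idx], heading[idx], kin$t)
  hfill <- gauss_smooth(hfill, stats::median(diff(kin$t)), heading_smooth_s)
  hfill[masked] <- NA
  dt <- c(NA, diff(kin$t))
  omega <- c(NA, diff(hfill)) / dt
  alpha <- abs(c(NA, diff(omega)) / dt)
  sel <- kin$t >= turn_window[1] & kin$t <= turn_window[2] & !is.na(alpha)
  if (!any(sel)) return(list(t_turn = NA_real_, flagged = TRUE))
  idx <- which(sel)[which.max(alpha[sel])]
  list(t_turn = kin$t[idx], flagged = FALSE)
}

# Unwrap a phase series (NA-tolerant): cumulative correction of jumps
# larger than pi between consecutive non-NA samples.
unwrap_phase <- function(ph) {
  out <- ph
  idx <- which(!is.na(ph))
  if (length(idx) < 2) return(out)
  d <- diff(ph[idx])
  corr <- cumsum(round(d / (2 * pi)))
  out[idx[-1]] <- ph[idx[-1]] - 2 * pi * corr
  out
}
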