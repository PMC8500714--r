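# Inhomogeneous-Poisson spike generation by thinning.  The firing
# intensity follows lagged session-z-scored speed and acceleration, with
# multiplicative trial-type and direction gains and sinusoidal modulation
# by the beta-band LFP phase:
#
#   lambda(t) = max(0, [b + b1*v_z(t+dt) + b2*a_z(t+dt)]
#                      * g_type * g_dir(t) * [1 + m*cos(phi_beta(t))])

#' Specification of a synthetic unit
#'
#' @param baseline_rate_hz baseline intensity b (Hz), > 0.
#' @param beta_v,beta_a gains on z-scored speed / acceleration (Hz per
#'   z-unit).
#' @param lag_s encoding lag `dt` in seconds; positive means the rate leads
#'   the kinematics (the unit is predictive).
#' @param type_gain named multiplicative gain per trial type
#'   (`reach`, `planned`, `impromptu`).
#' @param direction_gain multiplicative gain applied on medial trials
#'   within a window around movement onset (see `direction_window_s`).
#' @param direction_window_s window (s, relative to movement onset) in
#'   which the direction gain is active; default `c(-0.01, 0.27)`.
#' @param beta_mod_depth sinusoidal modulation depth m in `[0, 1)`.
#' @param impromptu_offset_hz additive rate offset on Impromptu trials
#'   between turn cue and turn onset, not mediated by kinematics (default
#'   0); used to embed non-kinematic turn signals.
#' @param label intended functional class, `"movement-like"` or
#'   `"turn-like"` (bookkeeping only).
#' @return object of class `unit_spec`.
#' @export
unit_spec <- function(baseline_rate_hz = 40,
                      beta_v = 0, beta_a = 0, lag_s = 0,
                      type_gain = c(reach = 1, planned = 1, impromptu = 1),
                      direction_gain = 1,
                      direction_window_s = c(-0.01, 0.27),
                      beta_mod_depth = 0,
                      impromptu_offset_hz = 0,
                      label = "movement-like") {
  if (baseline_rate_hz <= 0) stop("baseline_rate_hz must be > 0", call. = FALSE)
  if (beta_mod_depth < 0 || beta_mod_depth >= 1)
    stop("beta_mod_depth must be in [0, 1)", call. = FALSE)
  if (!all(c("reach", "planned", "impromptu") %in% names(type_gain)))
    stop("type_gain must name reach, planned and impromptu", call. = FALSE)
  structure(as.list(environment()), class = "unit_spec")
}

#' Generate spikes for one unit over a session
#'
#' Thinning of a homogeneous Poisson process at the intensity ceiling.
#' The intensity is evaluated from session-long z-scored speed and
#' acceleration traces (linear interpolation), shifted by the unit's
#' encoding lag, scaled by the trial-type and direction gains active at
#' each time, and modulated by the beta phase.  Negative intensities are
#' clipped at zero (part of the generative model).
#'
#' @param spec a [unit_spec()].
#' @param kin list with `t`, `v_z`, `a_z`: session-long kinematic grid.
#' @param trial_table trial table (for gains and windows).
#' @param beta_phase function of time returning beta phase (rad), or NULL
#'   for no modulation.
#' @param t_range length-2 session time span to simulate.
#' @param seed optional integer seed.
#' @return numeric vector of spike times (s, session clock), sorted.
#' @export
gen_spikes <- function(spec, kin, trial_table, beta_phase = NULL,
                       t_range = range(kin$t), seed = NULL) {
  lam <- function(tt) {
    drive <- spec$baseline_rate_hz +
      spec$beta_v * interp1(kin$t, kin$v_z, tt + spec$lag_s) +
      spec$beta_a * interp1(kin$t, kin$a_z, tt + spec$lag_s)
    g <- gain_at(spec, trial_table, tt)
    mod <- if (!is.null(beta_phase) && spec$beta_mod_depth > 0)
      1 + spec$beta_mod_depth * cos(beta_phase(tt)) else 1
    pmax(0, (drive + g$offset) * g$gain * mod)
  }
  # intensity ceiling: evaluate on a moderately fine grid and add margin
  grid <- seq(t_range[1], t_range[2], by = 0.005)
  lmax <- max(lam(grid)) * 1.1 + 1e-6
  with_seed(seed, {
    n_cand <- stats::rpois(1, lmax * diff(t_range))
    cand <- sort(stats::runif(n_cand, t_range[1], t_range[2]))
    keep <- stats::runif(n_cand) < lam(cand) / lmax
    cand[keep]
  })
}

# Multiplicative gain and additive offset active at each time, from the
# trial type / direction of the enclosing trial (gain 1 between trials).
gain_at <- function(spec, tt_table, t) {
  gain <- rep(1, length(t)); offset <- rep(0, length(t))
  for (i in seq_len(nrow(tt_table))) {
    tr <- tt_table[i, ]
    inside <- t >= tr$t_fix & t <= tr$t_feedback
    if (!any(inside)) next
    g <- spec$type_gain[[tr$type]]
    if (tr$direction == "medial" && spec$direction_gain != 1 && !is.na(tr$t_move)) {
      w <- spec$direction_window_s
      dirwin <- inside & t >= tr$t_move + w[1] & t <= tr$t_move + w[2]
      gain[dirwin] <- gain[dirwin] * spec$direction_gain
    }
    gain[inside] <- gain[inside] * g
    if (tr$type == "impromptu" && spec$impromptu_offset_hz != 0 &&
        !is.na(tr$t_turncue) && !is.na(tr$t_turn)) {
      pre <- t >= tr$t_turncue & t <= tr$t_turn
      offset[pre] <- offset[pre] + spec$impromptu_offset_hz
    }
  }
  list(gain = gain, offset = offset)
}
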