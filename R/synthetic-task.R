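# Task configuration and trial scheduling for the synthetic session
# generator.  The task: subjects hold a cursor at fixation, receive an
# instruction cue (Reach or Planned Turn), wait for a go cue, then reach
# toward a lateral target; on half of the initially-Reach trials the cue
# changes mid-movement (turn cue), forcing an upward turn (Impromptu Turn).

#' Truncated-exponential delay specification
#'
#' @param range_s length-2 numeric, support `[a, b]` in seconds (a < b).
#' @param mean_s target mean in seconds; must lie strictly between `a` and
#'   the midpoint `(a+b)/2` (the mean of a truncated exponential with
#'   decreasing density is confined to that interval).
#' @return an object of class `truncexp_spec`.
#' @export
truncexp_spec <- function(range_s, mean_s) {
  if (length(range_s) != 2 || !is.numeric(range_s) || diff(range_s) <= 0)
    stop("range_s must be an increasing pair", call. = FALSE)
  if (mean_s <= range_s[1] || mean_s >= mean(range_s))
    stop(sprintf(
      "infeasible truncated-exponential mean %.4g: must be in (%.4g, %.4g)",
      mean_s, range_s[1], mean(range_s)), call. = FALSE)
  structure(list(range_s = as.numeric(range_s), mean_s = as.numeric(mean_s)),
            class = "truncexp_spec")
}

# Mean of an exponential with rate `lambda` truncated to [a, b].
truncexp_mean <- function(lambda, a, b) {
  w <- b - a
  # numerically stable for small lambda*w
  lw <- lambda * w
  if (lw < 1e-8) return(a + w / 2)
  a + 1 / lambda - w / (exp(lw) - 1)
}

# Solve the rate so the truncated mean equals spec$mean_s (bisection via
# uniroot, tolerance 1e-12 on the mean).
truncexp_rate <- function(spec) {
  a <- spec$range_s[1]; b <- spec$range_s[2]
  f <- function(l) truncexp_mean(l, a, b) - spec$mean_s
  lo <- 1e-9; hi <- 1
  while (f(hi) > 0) hi <- hi * 2        # mean decreases with lambda
  stats::uniroot(f, c(lo, hi), tol = 1e-13)$root
}

#' Sample truncated-exponential delays
#'
#' Draws from an exponential distribution truncated to the spec's range,
#' with the rate solved numerically so the analytic truncated mean matches
#' the spec's target mean (to better than 1e-9 s).
#'
#' @param spec a [truncexp_spec()].
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return numeric vector of `n` delays in seconds, all within the range.
#' @export
sample_truncated_exponential <- function(spec, n, seed = NULL) {
  if (!inherits(spec, "truncexp_spec")) spec <- truncexp_spec(spec$range_s, spec$mean_s)
  lambda <- truncexp_rate(spec)
  a <- spec$range_s[1]; b <- spec$range_s[2]
  with_seed(seed, {
    u <- stats::runif(n)
    a - log(1 - u * (1 - exp(-lambda * (b - a)))) / lambda
  })
}

#' Task configuration for the synthetic session generator
#'
#' Defaults follow the study design: initial Reach cue probability 0.65
#' (60-70% of trials), half of initially-Reach trials converted to Impromptu
#' Turns, fixation delay truncated-exponential on 300-600 ms with mean
#' 400 ms, go delay on 400-1000 ms with mean 600 ms, turn-cue window centre
#' uniform over 35-65% of the fixation-to-target distance, 1.5 s
#' inter-trial interval.
#'
#' The remaining fields parameterise behaviour the task description leaves
#' open (latencies and movement extents); see the methods vignette for the
#' rationale behind their defaults.
#'
#' @param n_trials number of trials.
#' @param p_reach_initial probability the instruction cue is Reach.
#' @param p_impromptu_given_reach probability an initially-Reach trial
#'   receives a mid-movement turn cue.
#' @param fix_delay,go_delay [truncexp_spec()]s for the fixation and go
#'   delays.
#' @param turn_cue_window_frac range of the turn-cue window centre as a
#'   fraction of the fixation-to-target distance.
#' @param iti_s inter-trial interval (s).
#' @param move_latency_mean_s,move_latency_sd_s movement-onset latency from
#'   the go cue (Gaussian, truncated at 100 ms).
#' @param turn_latency_mean_s,turn_latency_sd_s impromptu turn-onset
#'   latency from the turn cue; mean must exceed `move_latency_mean_s`.
#' @param reach_duration_s duration of an uninterrupted horizontal reach.
#' @param turn_duration_s duration of the vertical (post-turn) segment.
#' @param reach_dist,turn_dist horizontal and vertical movement extents
#'   (screen units).
#' @param pos_noise_sd additive cursor position noise SD (screen units).
#' @param p_correct probability a trial is marked correct.
#' @param seed session master seed.
#' @return object of class `task_config`.
#' @export
task_config <- function(n_trials = 60,
                        p_reach_initial = 0.65,
                        p_impromptu_given_reach = 0.5,
                        fix_delay = truncexp_spec(c(0.3, 0.6), 0.4),
                        go_delay = truncexp_spec(c(0.4, 1.0), 0.6),
                        turn_cue_window_frac = c(0.35, 0.65),
                        iti_s = 1.5,
                        move_latency_mean_s = 0.25,
                        move_latency_sd_s = 0.04,
                        turn_latency_mean_s = 0.33,
                        turn_latency_sd_s = 0.05,
                        reach_duration_s = 0.7,
                        turn_duration_s = 0.55,
                        reach_dist = 10,
                        turn_dist = 6,
                        pos_noise_sd = 0.005,
                        p_correct = 1,
                        seed = 1L) {
  stopifnot_scalar_prob(p_reach_initial, "p_reach_initial")
  stopifnot_scalar_prob(p_impromptu_given_reach, "p_impromptu_given_reach")
  stopifnot_scalar_prob(p_correct, "p_correct")
  if (length(turn_cue_window_frac) != 2 || turn_cue_window_frac[1] <= 0 ||
      turn_cue_window_frac[2] >= 1 || diff(turn_cue_window_frac) < 0)
    stop("turn_cue_window_frac must be an increasing pair inside (0,1)", call. = FALSE)
  if (turn_latency_mean_s <= move_latency_mean_s)
    stop("impromptu turn latency mean must exceed movement latency mean", call. = FALSE)
  structure(as.list(environment()), class = "task_config")
}

#' Generate a trial schedule
#'
#' Assigns each trial a type (`reach`, `planned`, `impromptu`), a balanced
#' direction (`medial` / `lateral`), and a full set of event times on the
#' session-global clock, built from the configured delay distributions.
#' Impromptu trials are a Bernoulli subset of initially-Reach trials.
#'
#' Behavioural event times (movement onset, turn cue, turn onset, feedback)
#' are derived from the sampled latencies together with the minimum-jerk
#' trajectory model used by [gen_trajectory()], so they are exact ground
#' truth for the event detectors.
#'
#' @param config a [task_config()].
#' @param seed optional integer seed; defaults to a child stream of
#'   `config$seed`.
#' @return a `data.frame` (the trial table) with columns `trial_id`, `type`,
#'   `direction`, `correct`, `t_fix`, `t_instr`, `t_go`, `t_move`,
#'   `t_turncue`, `t_turn`, `t_feedback`, `turn_frac` (NA where an event
#'   does not occur on that trial type).
#' @export
gen_trial_schedule <- function(config, seed = NULL) {
  n <- config$n_trials
  seed <- seed %||% child_seed(config$seed, 1)
  with_seed(seed, {
    initially_reach <- stats::runif(n) < config$p_reach_initial
    impromptu <- initially_reach & (stats::runif(n) < config$p_impromptu_given_reach)
    type <- ifelse(impromptu, "impromptu", ifelse(initially_reach, "reach", "planned"))
    direction <- sample(rep(c("medial", "lateral"), length.out = n))
    fix_delay <- sample_truncated_exponential(config$fix_delay, n)
    go_delay <- sample_truncated_exponential(config$go_delay, n)
    move_lat <- pmax(0.1, stats::rnorm(n, config$move_latency_mean_s, config$move_latency_sd_s))
    turn_lat <- pmax(0.12, stats::rnorm(n, config$turn_latency_mean_s, config$turn_latency_sd_s))
    turn_frac <- stats::runif(n, config$turn_cue_window_frac[1], config$turn_cue_window_frac[2])
    correct <- stats::runif(n) < config$p_correct

    t_fix <- t_instr <- t_go <- t_move <- t_turncue <- t_turn <- t_feedback <-
      rep(NA_real_, n)
    clock <- 0.5                        # pre-session padding for LFP baseline
    for (i in seq_len(n)) {
      t_fix[i] <- clock + 0.75          # baseline window needs 500 ms pre-fix
      t_instr[i] <- t_fix[i] + fix_delay[i]
      t_go[i] <- t_instr[i] + go_delay[i]
      t_move[i] <- t_go[i] + move_lat[i]
      tim <- trial_movement_times(type[i], config, move_lat[i], turn_lat[i], turn_frac[i])
      if (!is.na(tim$turn_cue_rel)) t_turncue[i] <- t_move[i] + tim$turn_cue_rel
      if (!is.na(tim$turn_rel)) t_turn[i] <- t_move[i] + tim$turn_rel
      t_feedback[i] <- t_move[i] + tim$end_rel + 0.05
      clock <- t_feedback[i] + config$iti_s
    }
    data.frame(trial_id = seq_len(n), type = type, direction = direction,
               correct = correct, t_fix = t_fix, t_instr = t_instr,
               t_go = t_go, t_move = t_move, t_turncue = t_turncue,
               t_turn = t_turn, t_feedback = t_feedback,
               turn_frac = turn_frac, stringsAsFactors = FALSE)
  })
}

# Within-movement timing (relative to movement onset) implied by the
# minimum-jerk trajectory model.  Returns turn cue time, turn onset time and
# movement end time, all relative to movement onset (NA where absent).
trial_movement_times <- function(type, config, move_lat, turn_lat, turn_frac) {
  Tr <- config$reach_duration_s
  if (type == "reach")
    return(list(turn_cue_rel = NA_real_, turn_rel = NA_real_, end_rel = Tr))
  if (type == "planned") {
    # horizontal minimum-jerk segment ends (speed ~0) at the planned
    # corner; duration scales with distance so peak speed matches reaches
    Th <- Tr * turn_frac
    return(list(turn_cue_rel = NA_real_, turn_rel = Th,
                end_rel = Th + config$turn_duration_s))
  }
  # impromptu: cue fires when the cursor crosses turn_frac of the reach
  # distance along the full minimum-jerk reach; turn follows after turn_lat
  s_cross <- minjerk_invert(turn_frac)
  cue <- s_cross * Tr
  turn <- cue + turn_lat
  list(turn_cue_rel = cue, turn_rel = turn,
       end_rel = turn + config$turn_duration_s)
}

# Invert the minimum-jerk position profile: find s with minjerk_s(s) = frac.
minjerk_invert <- function(frac) {
  stats::uniroot(function(s) minjerk_s(s) - frac, c(0, 1), tol = 1e-10)$root
}
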