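# Shared small fixtures, built in code.  Sessions are cached per test run
# so several test files can reuse the same simulation.

small_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_session(
        task_config(n_trials = 36, seed = 101L),
        unit_specs = list(
          unit_spec(40, beta_v = 3, beta_a = 1, lag_s = 0.11,
                    direction_gain = 1.3, beta_mod_depth = 0.13,
                    label = "movement-like"),
          unit_spec(30, beta_v = 0.3, beta_a = 3, lag_s = 0,
                    type_gain = c(reach = 1, planned = 1.35, impromptu = 1.7),
                    beta_mod_depth = 0.13, label = "turn-like"),
          unit_spec(25, label = "untuned")))
    }
    cache
  }
})

# A toy trial table with fully specified events (times in s).
toy_trial <- function(type = "impromptu", direction = "medial") {
  data.frame(trial_id = 1L, type = type, direction = direction, correct = TRUE,
             t_fix = 1.0, t_instr = 1.4, t_go = 2.0, t_move = 2.25,
             t_turncue = if (type == "impromptu") 2.55 else NA_real_,
             t_turn = if (type != "reach") 2.85 else NA_real_,
             t_feedback = 3.4, turn_frac = 0.5)
}

# Deterministic zig-zag paths for trajectory oracles.
toy_path <- function(x, y, t = seq_along(x) * 0.01) data.frame(t = t, x = x, y = y)
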