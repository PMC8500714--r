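# Lagged linear encoding models of firing rate on movement kinematics.
#
# The mean rate on each trial type is modelled as
#   rbar_m(t) = b0 + b1 * vbar_m(t + dt) + b2 * abar_m(t + dt)
# with the lag dt searched on a grid.  So that every lag (and every unit)
# is fitted on identical time points, the fitted range is fixed by the
# grid extremes: for r on [t_start, t_end] and lags in [dt_min, dt_max],
# fitting is restricted to [t_start - dt_min, t_end - dt_max]; points
# outside the fit range but inside [t_start - dt, t_end - dt] at the best
# lag form the held-out test set.

#' Fit a lagged kinematic model for one unit
#'
#' Ordinary least squares of the type-mean firing rate on lagged type-mean
#' kinematic predictors, pooled over trial types, for each lag on the
#' grid; the best lag maximises in-sample R^2 and the out-of-sample R^2
#' is computed on the held-out points at that lag.
#'
#' @param psth_by_type named list per trial type of `data.frame(t, rate)`
#'   on a common within-type grid; an optional `w` column (e.g. the
#'   number of uncensored trials behind each sample) is used as weights
#'   in the least-squares fits.
#' @param kin_by_type named list per trial type of
#'   `data.frame(t, v, a)` (z-scored speed / acceleration, same grid
#'   span); extra predictor columns are allowed and selected by
#'   `predictors`.
#' @param lag_grid lags to search (s); default `seq(-0.2, 0.2, 0.01)`,
#'   bracketing reported STN encoding lags with margin.
#' @param predictors character vector of predictor column names and/or
#'   interactions written as `"v:a"` (default `c("v", "a")`).
#' @return a `lagged_model_fit`: `lag_best`, `coef` (named), `r2_in`,
#'   `r2_out`, `r2_by_lag`, `lag_grid`, `fit_range`, `n_fit`, `n_test`,
#'   plus the assembled fit/test frames for downstream residuals.
#' @export
fit_lagged_model <- function(psth_by_type, kin_by_type,
                             lag_grid = seq(-0.2, 0.2, by = 0.01),
                             predictors = c("v", "a")) {
  stopifnot(identical(sort(names(psth_by_type)), sort(names(kin_by_type))))
  dt_min <- min(lag_grid); dt_max <- max(lag_grid)
  pred_cols <- gsub(":", "_x_", predictors, fixed = TRUE)
  design <- function(lag, fit_range_only = TRUE) {
    do.call(rbind, lapply(names(psth_by_type), function(m) {
      p <- psth_by_type[[m]]; k <- kin_by_type[[m]]
      t_start <- min(p$t); t_end <- max(p$t)
      lo <- t_start - dt_min; hi <- t_end - dt_max
      if (lo > hi) stop("empty feasible fit range for the lag grid", call. = FALSE)
      eps <- 1e-9                        # guard against seq() rounding
      sel <- if (fit_range_only) p$t >= lo - eps & p$t <= hi + eps
      else (p$t >= t_start - lag - eps & p$t <= t_end - lag + eps) &
        !(p$t >= lo - eps & p$t <= hi + eps)
      tt <- p$t[sel]
      X <- vapply(predictors, function(nm) {
        if (grepl(":", nm)) {
          parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
          Reduce(`*`, lapply(parts, function(q) interp1(k$t, k[[q]], tt + lag)))
        } else interp1(k$t, k[[nm]], tt + lag)
      }, numeric(length(tt)))
      if (length(tt) == 1) X <- matrix(X, 1)
      colnames(X) <- pred_cols
      w <- if (!is.null(p$w)) p$w[sel] else rep(1, length(tt))
      cbind(data.frame(type = m, t = tt, rate = p$rate[sel], w = w), X)
    }))
  }
  r2_of <- function(fit, newdata) {
    y <- newdata$rate
    yhat <- stats::predict(fit, newdata)
    1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  }
  form <- stats::as.formula(paste("rate ~", paste(pred_cols, collapse = " + ")))
  r2_by_lag <- numeric(length(lag_grid))
  fits <- vector("list", length(lag_grid))
  for (i in seq_along(lag_grid)) {
    d <- design(lag_grid[i])
    d <- d[stats::complete.cases(d), ]
    fits[[i]] <- stats::lm(form, data = d, weights = w)
    r2_by_lag[i] <- summary(fits[[i]])$r.squared
  }
  best <- which.max(r2_by_lag)
  lag_best <- lag_grid[best]
  d_fit <- design(lag_best)
  d_test <- design(lag_best, fit_range_only = FALSE)
  d_test <- d_test[stats::complete.cases(d_test), ]
  r2_out <- if (nrow(d_test) > 1) r2_of(fits[[best]], d_test) else NA_real_
  structure(list(lag_best = lag_best, coef = stats::coef(fits[[best]]),
                 r2_in = r2_by_lag[best], r2_out = r2_out,
                 r2_by_lag = r2_by_lag, lag_grid = lag_grid,
                 predictors = predictors, model = fits[[best]],
                 fit_data = d_fit, test_data = d_test),
            class = "lagged_model_fit")
}

#' The 14-model encoding family
#'
#' Documented reconstruction of the compared family: combinations of
#' total speed and acceleration magnitudes, their interaction, and
#' variants replacing the magnitudes with signed or absolute x/y
#' components (x taken toward the target).  `kin_by_type` must provide
#' columns `v, a, vx, vy, ax, ay` (and absolute values are derived).
#'
#' @return named list of predictor vectors, one per model.
#' @export
model_family <- function() {
  list(m01_v = c("v"),
       m02_a = c("a"),
       m03_va = c("v", "a"),
       m04_va_int = c("v", "a", "v:a"),
       m05_vxy = c("vx", "vy"),
       m06_axy = c("ax", "ay"),
       m07_vxy_axy = c("vx", "vy", "ax", "ay"),
       m08_absvxy = c("avx", "avy"),
       m09_absaxy = c("aax", "aay"),
       m10_absvxy_absaxy = c("avx", "avy", "aax", "aay"),
       m11_vxy_a = c("vx", "vy", "a"),
       m12_v_axy = c("v", "ax", "ay"),
       m13_absvxy_a = c("avx", "avy", "a"),
       m14_v_absaxy = c("v", "aax", "aay"))
}

# Add absolute-component columns used by the family.
augment_kinematics <- function(kin_by_type) {
  lapply(kin_by_type, function(k) {
    k$avx <- abs(k$vx); k$avy <- abs(k$vy)
    k$aax <- abs(k$ax); k$aay <- abs(k$ay)
    k
  })
}

#' Fit the model family across units and select the best model
#'
#' Every model in [model_family()] is fitted to every unit; the selected
#' model has the highest out-of-sample R^2 averaged across units.
#'
#' @param units_psth list per unit of `psth_by_type`.
#' @param kin_by_type shared kinematics per type (with component columns).
#' @param lag_grid lag grid.
#' @param family model family (default [model_family()]).
#' @return list: `best_model`, `mean_r2_out` (named), `fits`
#'   (unit x model list of `lagged_model_fit`s).
#' @export
model_family_fit <- function(units_psth, kin_by_type,
                             lag_grid = seq(-0.2, 0.2, by = 0.01),
                             family = model_family()) {
  kin_by_type <- augment_kinematics(kin_by_type)
  fits <- lapply(units_psth, function(pu)
    lapply(family, function(preds)
      fit_lagged_model(pu, kin_by_type, lag_grid, predictors = preds)))
  r2 <- sapply(names(family), function(mn)
    mean(vapply(fits, function(fu) fu[[mn]]$r2_out, numeric(1)), na.rm = TRUE))
  list(best_model = names(family)[which.max(r2)], mean_r2_out = r2, fits = fits)
}

#' Residual firing rates after removing the kinematic model
#'
#' Observed minus predicted rate at the best lag, over the fitted and
#' held-out range, split back by trial type.
#'
#' @param fit a `lagged_model_fit`.
#' @return named list per type of `data.frame(t, residual)`.
#' @export
residual_rates <- function(fit) {
  d <- rbind(fit$fit_data, fit$test_data)
  d <- d[order(d$type, d$t), ]
  d$residual <- d$rate - stats::predict(fit$model, d)
  split(d[, c("t", "residual")], d$type)
}

#' Block-bootstrap confidence interval for R^2
#'
#' Contiguous blocks of fitted time points (default 50 ms) are resampled
#' with replacement within each trial type, the model is refitted, and
#' the percentile interval of the resampled in-sample R^2 is returned.
#' Blocks respect the autocorrelation left by rate smoothing.
#'
#' @param fit a `lagged_model_fit`.
#' @param n_boot bootstrap iterations (default 1000).
#' @param block_s block length in seconds (default 0.05).
#' @param level confidence level (default 0.95).
#' @param seed optional integer seed.
#' @return list: `ci` (length 2), `boot` (replicates).
#' @export
bootstrap_r2_ci <- function(fit, n_boot = 1000, block_s = 0.05, level = 0.95,
                            seed = NULL) {
  d <- fit$fit_data
  d <- d[stats::complete.cases(d), ]
  dt <- stats::median(diff(sort(unique(d$t))))
  bl <- max(1L, round(block_s / dt))
  idx_by_type <- split(seq_len(nrow(d)), d$type)
  form <- stats::formula(fit$model)
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    take <- unlist(lapply(idx_by_type, function(ix) {
      n <- length(ix)
      nb <- ceiling(n / bl)
      starts <- sample(seq_len(max(1, n - bl + 1)), nb, replace = TRUE)
      unlist(lapply(starts, function(s) ix[s:min(s + bl - 1, n)]))[seq_len(n)]
    }))
    db <- d[take, ]
    summary(stats::lm(form, data = db))$r.squared
  }, numeric(1)))
  a <- (1 - level) / 2
  list(ci = unname(stats::quantile(boot, c(a, 1 - a))), boot = boot)
}
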