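# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers do not disturb
#' the caller's RNG stream.
#'
#' @param seed integer seed, or NULL to leave the RNG alone.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic child seed for a named component, kept below 2^31.
child_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (i in seq_len(k)) s <- (s * 48271) %% 2147483647
  as.integer(s)
}

# Linear interpolation clamped to the end values (rule = 2).
interp1 <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2, ties = "ordered")$y
}

# Gaussian smoothing of a regularly sampled series with reflection padding.
# sigma and dt in the same units.
gauss_smooth <- function(y, dt, sigma) {
  if (sigma <= 0) return(y)
  half <- max(1L, ceiling(4 * sigma / dt))
  k <- stats::dnorm(seq(-half, half) * dt, sd = sigma)
  k <- k / sum(k)
  n <- length(y)
  pad <- function(v, m) c(rev(v[seq_len(min(m, n))]), v, rev(v[n + 1 - seq_len(min(m, n))]))
  m <- min(half, n)
  yp <- pad(y, m)
  out <- stats::filter(yp, k, sides = 2)
  as.numeric(out[(m + 1):(m + n)])
}

# Minimum-jerk position profile from 0 to 1 over normalized time s in [0,1].
minjerk_s <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  s^3 * (10 - 15 * s + 6 * s^2)
}

# d/ds of minjerk_s (normalized velocity profile).
minjerk_ds <- function(s) {
  inside <- s > 0 & s < 1
  out <- numeric(length(s))
  out[inside] <- 30 * s[inside]^2 - 60 * s[inside]^3 + 30 * s[inside]^4
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reflection-pad a series to the next fast FFT length (avoids the severe
# slowdown of R's mixed-radix FFT on awkward lengths).  Returns the padded
# vector and the original length as an attribute.
fft_pad <- function(x) {
  n <- length(x)
  if (n == 0) stop("empty signal", call. = FALSE)
  n2 <- stats::nextn(n)
  if (n2 > n) {
    extra <- n2 - n
    tailref <- rev(x)[seq_len(min(extra, n))]
    while (length(tailref) < extra) tailref <- c(tailref, rev(tailref))[seq_len(extra)]
    x <- c(x, tailref[seq_len(extra)])
  }
  attr(x, "n_orig") <- n
  x
}

stopifnot_scalar_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
    stop(sprintf("'%s' must be a probability in [0,1]", name), call. = FALSE)
}
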