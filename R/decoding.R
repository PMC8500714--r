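# Cross-validated ideal-observer (nearest class-centroid) decoding of
# trial type from population firing-rate patterns.  Units were recorded
# in separate sessions, so trials are paired across units only by
# within-class index resampling (pseudo-population).

#' Ideal-observer decoder
#'
#' On each iteration a class is drawn uniformly, one trial of that class
#' is held out from each unit, class centroids are computed from the
#' remaining trials, and the held-out population pattern is classified by
#' the smallest Euclidean distance to the centroids (ties broken
#' uniformly at random).  Accuracy is the fraction of iterations
#' classified correctly.
#'
#' @param patterns list (one per unit) of `[trial x feature]` matrices
#'   (a single column for scalar rate patterns).
#' @param labels list (one per unit) of per-trial class labels.  Units
#'   with fewer than 2 trials of any class are dropped, with a message.
#' @param n_iter iterations (default 10000).
#' @param seed optional integer seed.
#' @return a `decode_result`: `accuracy`, `n_iter`, `classes`,
#'   `outcomes` (logical per iteration), `units_used`.
#' @export
ideal_observer <- function(patterns, labels, n_iter = 10000, seed = NULL) {
  classes <- sort(unique(unlist(labels)))
  K <- length(classes)
  if (K < 2) stop("need at least 2 classes to decode", call. = FALSE)
  ok <- vapply(seq_along(patterns), function(u)
    all(vapply(classes, function(cl) sum(labels[[u]] == cl), numeric(1)) >= 2),
    logical(1))
  if (!all(ok)) message(sum(!ok), " unit(s) dropped (class with <2 trials)")
  if (!any(ok)) stop("no usable units", call. = FALSE)
  patterns <- patterns[ok]; labels <- labels[ok]
  U <- length(patterns)
  by_class <- lapply(seq_len(U), function(u)
    lapply(classes, function(cl) which(labels[[u]] == cl)))
  # per-unit, per-class feature sums and counts: the centroid excluding a
  # held-out trial is (sum - x) / (n - 1), so iterations avoid colMeans
  class_sums <- lapply(seq_len(U), function(u)
    lapply(by_class[[u]], function(ix)
      list(s = colSums(patterns[[u]][ix, , drop = FALSE]), n = length(ix))))
  with_seed(seed, {
    outcomes <- logical(n_iter)
    for (it in seq_len(n_iter)) {
      true_k <- sample.int(K, 1)
      d2 <- numeric(K)   # squared distance to each class centroid, summed over units
      for (u in seq_len(U)) {
        idx <- by_class[[u]][[true_k]]
        hold <- idx[sample.int(length(idx), 1)]
        x <- patterns[[u]][hold, ]
        for (k in seq_len(K)) {
          cs <- class_sums[[u]][[k]]
          cen <- if (k == true_k) (cs$s - x) / (cs$n - 1) else cs$s / cs$n
          d2[k] <- d2[k] + sum((x - cen)^2)
        }
      }
      best <- which(d2 == min(d2))
      pick <- if (length(best) > 1) best[sample.int(length(best), 1)] else best
      outcomes[it] <- pick == true_k
    }
    structure(list(accuracy = mean(outcomes), n_iter = n_iter,
                   classes = classes, outcomes = outcomes,
                   units_used = which(ok)),
              class = "decode_result")
  })
}
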