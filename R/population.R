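# Population geometry: PCA over unit response profiles, projection of
# population activity into the component space, hierarchical clustering of
# units by their component coefficients, and condition-wise state-space
# trajectories.
#
# The profile matrix is units x features (concatenated z-scored PSTHs).
# Because Reach trials lack a turn event, components are fitted on the
# Planned + Impromptu segments only; Reach segments are then projected
# onto the same unit-space basis.

#' Fit population PCA on turn-trial response profiles
#'
#' Centres each fitted feature across units (profiles are already
#' per-unit z-scored; no further scaling), takes the SVD, and returns the
#' top `D` components.  Units with missing values in the fitted segments
#' are dropped with a message.
#'
#' @param profiles units x features matrix of response profiles.
#' @param segments data.frame describing the feature columns (`event`,
#'   `type`, `t`), as from [response_profile()].
#' @param D number of components (default 4).
#' @param fit_types trial types whose segments are fitted (default
#'   planned + impromptu).
#' @return a `pc_space` list: `basis` (kept-units x D, orthonormal
#'   unit-space directions), `patterns` (D x fitted features),
#'   `coefficients` (units x D, for clustering), `var_explained`,
#'   `units_kept`, `segments`, `center`.
#' @export
fit_population_pca <- function(profiles, segments, D = 4,
                               fit_types = c("planned", "impromptu")) {
  fit_cols <- segments$type %in% fit_types
  X <- profiles[, fit_cols, drop = FALSE]
  keep <- stats::complete.cases(X)
  if (sum(keep) < D)
    stop("need at least D units with complete fitted profiles", call. = FALSE)
  if (any(!keep)) message(sum(!keep), " unit(s) dropped for missing fitted values")
  X <- X[keep, , drop = FALSE]
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  D <- min(D, length(sv$d))
  ve <- sv$d^2 / sum(sv$d^2)
  structure(list(basis = sv$u[, seq_len(D), drop = FALSE],
                 patterns = t(sv$v[, seq_len(D), drop = FALSE] %*% diag(sv$d[seq_len(D)], D)),
                 coefficients = sv$u[, seq_len(D), drop = FALSE] %*% diag(sv$d[seq_len(D)], D),
                 var_explained = ve[seq_len(D)],
                 singular_values = sv$d,
                 units_kept = which(keep),
                 fit_cols = fit_cols,
                 segments = segments,
                 center = ctr),
            class = "pc_space")
}

#' Project population activity onto the fitted components
#'
#' Projects an N-unit population vector time series (rows = features or
#' time points, columns = kept units) onto the unit-space basis.  Each
#' feature is centred with the across-unit mean of the projected data
#' itself, mirroring the centring used in the fit.
#'
#' @param pcs a `pc_space`.
#' @param activity matrix (time/features x kept units), column order equal
#'   to `pcs$units_kept`.
#' @return matrix (time/features x D) of scores.
#' @export
project_population <- function(pcs, activity) {
  act_c <- activity - rowMeans(activity, na.rm = TRUE)
  act_c %*% pcs$basis
}

#' Hierarchically cluster units by component coefficients
#'
#' Chebyshev (maximum-coordinate) distance on the D coefficient columns,
#' complete linkage.  The tree is cut at `k` clusters and the fraction of
#' units covered by the two largest clusters is reported.
#'
#' @param pcs a `pc_space` (or a units x D coefficient matrix).
#' @param k number of clusters at the cut (default 3: two main clusters
#'   plus a remainder).
#' @return list: `tree`, `labels`, `sizes`, `fractions`, `top2_coverage`.
#' @export
cluster_units <- function(pcs, k = 3) {
  co <- if (inherits(pcs, "pc_space")) pcs$coefficients else pcs
  if (nrow(co) < 3) stop("need at least 3 units to cluster", call. = FALSE)
  d <- stats::dist(co, method = "maximum")
  tree <- stats::hclust(d, method = "complete")
  k <- min(k, nrow(co))
  labels <- stats::cutree(tree, k = k)
  sizes <- sort(table(labels), decreasing = TRUE)
  fractions <- as.numeric(sizes) / nrow(co)
  list(tree = tree, labels = labels, sizes = sizes, fractions = fractions,
       top2_coverage = sum(fractions[seq_len(min(2, length(fractions)))]))
}

#' Condition-wise state-space trajectories
#'
#' Projects per-condition population PSTH matrices onto the component
#' space and returns one D-dimensional trajectory per condition, with
#' optional bootstrap (over units) standard errors.
#'
#' @param pcs a `pc_space`.
#' @param cond_activity named list of matrices (time x kept units), one
#'   per condition.
#' @param n_boot bootstrap resamples over units for SEs (0 to skip;
#'   default 0; the conventional choice for figures is 1000).
#' @param seed optional seed for the bootstrap.
#' @return list per condition: `scores` (time x D), `se` (time x D or
#'   NULL).
#' @export
state_space_trajectories <- function(pcs, cond_activity, n_boot = 0, seed = NULL) {
  out <- lapply(cond_activity, function(act) {
    sc <- project_population(pcs, act)
    se <- NULL
    if (n_boot > 0) {
      N <- ncol(act)
      boots <- with_seed(seed, replicate(n_boot, {
        idx <- sample(N, replace = TRUE)
        bc <- act[, idx, drop = FALSE] - rowMeans(act[, idx, drop = FALSE])
        bc %*% pcs$basis[idx, , drop = FALSE]
      }, simplify = "array"))
      se <- apply(boots, c(1, 2), stats::sd)
    }
    list(scores = sc, se = se)
  })
  out
}

#' PCA on kinematic-model residual profiles
#'
#' Identical machinery to [fit_population_pca()] applied to residual
#' firing-rate profiles (observed minus lagged-kinematic-model
#' prediction); separations that survive residualisation are not carried
#' by the modelled kinematics.
#'
#' @inheritParams fit_population_pca
#' @return a `pc_space`.
#' @export
residual_population_pca <- function(profiles, segments, D = 4,
                                    fit_types = c("planned", "impromptu")) {
  fit_population_pca(profiles, segments, D = D, fit_types = fit_types)
}
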