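#' Gaussian kernel weights in age
#'
#' Each observation is weighted by a Gaussian kernel in its age distance
#' from the target age: \eqn{w_i = \exp(-(a_i - a)^2 / 2h^2)} with kernel
#' width \eqn{h} (years). Cases within one kernel width of the target age
#' have the most influence; cases more than two widths away have close to
#' zero influence (\eqn{\exp(-2) \approx 0.135} at exactly two widths).
#'
#' @param ages numeric vector of observed ages (years).
#' @param a target age (years).
#' @param width kernel width \eqn{h > 0} (years).
#' @return weights in `(0, 1]`, strictly decreasing in `|ages - a|`.
#' @export
kernel_weights <- function(ages, a, width) {
  if (length(ages) == 0L) stopf("ages must be non-empty")
  if (!is_scalar_number(width) || width <= 0) stopf("width must be > 0")
  exp(-((ages - a)^2) / (2 * width^2))
}

#' Weighted partial least-squares fit of responses on age
#'
#' Fits a weighted linear PLS regression of a (possibly very wide) response
#' matrix on the single predictor age. Predictor and responses are
#' weighted-mean centered before fitting and the intercept restored at
#' prediction, which gives local-linear behaviour at kernel edges. With a
#' single predictor the PLS score direction is the predictor itself, so the
#' fit coincides with the weighted least-squares slope for every component
#' count; `n_components` is validated but does not change the fit.
#'
#' @param responses `n x d` numeric matrix (rows are flattened
#'   configurations, or a one-column matrix of sizes).
#' @param ages numeric vector of length `n`.
#' @param weights non-negative case weights with positive sum.
#' @param n_components number of PLS components (>= 1).
#' @return list with `intercept` (weighted response means, length `d`),
#'   `coef` (slope per response dimension, units per year), and
#'   `age_center` (weighted mean age); prediction at age `a` is
#'   `intercept + coef * (a - age_center)`.
#' @export
weighted_pls_fit <- function(responses, ages, weights, n_components = 1L) {
  responses <- as.matrix(responses)
  n <- nrow(responses)
  if (length(ages) != n || length(weights) != n)
    stopf("responses, ages and weights must agree in length")
  if (n_components < 1L) stopf("n_components must be >= 1")
  sw <- sum(weights)
  if (!is.finite(sw) || sw <= .Machine$double.eps)
    stopf("total weight is not positive")
  abar <- sum(weights * ages) / sw
  ac <- ages - abar
  denom <- sum(weights * ac^2)
  if (denom <= .Machine$double.eps * max(1, abar^2))
    stopf("all (effectively weighted) ages identical: predictor is singular")
  ybar <- as.vector(crossprod(weights, responses)) / sw
  coef <- as.vector(crossprod(weights * ac, responses)) / denom
  list(intercept = ybar, coef = coef, age_center = abar)
}

#' Fit a kernel-regression growth trajectory for one group
#'
#' Builds the growth-curve model of one group: at any target age the
#' expected response (head configuration or size) is the prediction of a
#' weighted linear PLS regression of the responses on age, with Gaussian
#' kernel weights centered on the target age. The same local regression
#' yields per-vertex growth vectors (its slopes). The model stores its
#' valid [evaluation_range()], outside which predictions are extrapolation.
#'
#' @param x an aligned [cohort()].
#' @param group group label to model (default: first level).
#' @param response `"shape"` (per-vertex coordinates) or `"size"` (recorded
#'   centroid sizes in mm).
#' @param width kernel width in years; defaults to 2.75 for shape and 0.75
#'   for size.
#' @param support_threshold balance threshold defining the evaluation range
#'   (default 0.4).
#' @param n_components PLS components (see [weighted_pls_fit()]).
#' @return object of class `trajectory_model`.
#' @export
fit_trajectory <- function(x, group = levels(x$groups)[1L],
                           response = c("shape", "size"), width = NULL,
                           support_threshold = 0.4, n_components = 1L) {
  stopifnot(inherits(x, "cohort"))
  response <- match.arg(response)
  if (response == "shape" && !x$aligned)
    warnf("cohort is not aligned; shape trajectories assume a common Procrustes frame")
  if (is.null(width)) width <- if (response == "shape") 2.75 else 0.75
  keep <- x$groups == group
  if (!any(keep)) stopf("no cases with group label '%s'", group)
  ages <- x$ages[keep]
  Y <- if (response == "shape") flatten_configs(x$coords[, , keep, drop = FALSE])
       else matrix(x$sizes[keep], ncol = 1L)
  rng <- evaluation_range(ages, width, threshold = support_threshold)
  structure(
    list(ages = ages, responses = Y, width = width, response = response,
         n_components = as.integer(n_components), group = as.character(group),
         n_vertices = dim(x$coords)[1L], range = rng),
    class = "trajectory_model"
  )
}

#' @export
print.trajectory_model <- function(x, ...) {
  cat(sprintf(
    "Growth trajectory (%s) for group '%s': n = %d, kernel width %.2f y, evaluable on [%.2f, %.2f] y\n",
    x$response, x$group, length(x$ages), x$width, x$range$a_min, x$range$a_max))
  invisible(x)
}

# local weighted fit at one target age; shared by expected_at/growth_field_at
local_fit <- function(model, a) {
  w <- kernel_weights(model$ages, a, model$width)
  if (sum(w) < 1e-300)
    stopf("total kernel weight at age %.3g is numerically zero", a)
  weighted_pls_fit(model$responses, model$ages, w, model$n_components)
}

check_in_range <- function(model, a, warn = TRUE) {
  if (warn && (a < model$range$a_min || a > model$range$a_max))
    warnf("age %.3g lies outside the evaluation range [%.2f, %.2f]: extrapolating",
          a, model$range$a_min, model$range$a_max)
}

#' Expected configuration or size at an age
#'
#' Evaluates the group's growth curve: the prediction of the locally
#' weighted PLS regression at target age `a` — the "expected head" (a
#' `p x 3` configuration) for shape models, or the expected centroid size
#' (mm) for size models.
#'
#' @param model a [fit_trajectory()] model.
#' @param a target age in years; ages outside the model's evaluation range
#'   trigger a warning (`warn = FALSE` suppresses it).
#' @param warn warn on extrapolation?
#' @return `p x 3` matrix (shape) or scalar (size).
#' @export
expected_at <- function(model, a, warn = TRUE) {
  stopifnot(inherits(model, "trajectory_model"))
  check_in_range(model, a, warn)
  fit <- local_fit(model, a)
  pred <- fit$intercept + fit$coef * (a - fit$age_center)
  if (model$response == "shape") unflatten_config(pred, model$n_vertices)
  else as.numeric(pred)
}

#' Growth vector field at an age
#'
#' The per-vertex 3D slope of the local weighted regression at age `a`:
#' the predicted displacement of each vertex per year, i.e. a 3D growth
#' vector at each point on the head.
#'
#' @inheritParams expected_at
#' @return `p x 3` matrix of class `growth_field` with attribute `age`;
#'   units are coordinate units per year.
#' @export
growth_field_at <- function(model, a, warn = TRUE) {
  stopifnot(inherits(model, "trajectory_model"))
  if (model$response != "shape")
    stopf("growth fields are defined for shape models")
  check_in_range(model, a, warn)
  fit <- local_fit(model, a)
  structure(unflatten_config(fit$coef, model$n_vertices),
            age = a, class = c("growth_field", "matrix", "array"))
}

#' Overall growth rate of a field
#'
#' The mean Euclidean length of the per-vertex growth vectors: the overall
#' rate of shape change at that age, in coordinate units per year.
#'
#' @param field a [growth_field_at()] result (or any `p x 3` matrix).
#' @return non-negative scalar.
#' @export
growth_rate <- function(field) {
  mean(row_norms(unclass(field)))
}

#' Supported evaluation range of a kernel regression
#'
#' At the edges of the sampled ages the kernel regression becomes an
#' extrapolation: almost all weight sits on one side of the target age. The
#' evaluation range is the maximal contiguous age interval (scanned on a
#' fine grid) on which the ratio of the kernel-weight sum of cases older
#' than the target age to that of younger cases, or its inverse, stays at
#' or above `threshold`.
#'
#' @param ages numeric vector of observed ages (>= 2 distinct values).
#' @param width kernel width in years.
#' @param threshold balance threshold in `[0, 1]` (default 0.4).
#' @param step grid step in years (default 0.01).
#' @return list with `a_min`, `a_max`, `threshold`, `step`.
#' @export
evaluation_range <- function(ages, width, threshold = 0.4, step = 0.01) {
  if (length(unique(ages)) < 2L) stopf("need at least 2 distinct ages")
  grid <- unique(c(seq(min(ages), max(ages), by = step), max(ages)))
  W <- exp(-(outer(grid, ages, "-")^2) / (2 * width^2))
  older <- outer(grid, ages, function(g, x) x > g)
  s_old <- rowSums(W * older)
  s_young <- rowSums(W * (!older & outer(grid, ages, function(g, x) x < g)))
  ratio <- ifelse(s_old == 0 | s_young == 0, 0,
                  pmin(s_old / s_young, s_young / s_old))
  ok <- ratio >= threshold
  if (!any(ok)) stopf("no age satisfies the support criterion (threshold %.2f)", threshold)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  list(a_min = grid[starts[best]], a_max = grid[ends[best]],
       threshold = threshold, step = step)
}

#' Tune the kernel width by repeated cross-validated grid search
#'
#' For every candidate width, the mean held-out prediction error (Euclidean
#' distance between each held-out response and the expected value at its
#' age, fitted on the remaining folds) is averaged over `repeats` random
#' k-fold splits; the width with the smallest mean error wins. Widths whose
#' training folds have an empty evaluation range are marked invalid.
#'
#' @param x an aligned [cohort()].
#' @param grid numeric vector of candidate widths (years).
#' @param group group label to tune on.
#' @param response `"shape"` or `"size"`.
#' @param k number of folds.
#' @param repeats number of random splits.
#' @param support_threshold passed to [evaluation_range()].
#' @param seed integer seed for the fold draws.
#' @return the selected width, with the full error table (one row per
#'   width: mean error, number of valid folds) in attribute `"errors"`.
#' @export
tune_kernel_width <- function(x, grid, group = levels(x$groups)[1L],
                              response = c("shape", "size"), k = 10L,
                              repeats = 10L, support_threshold = 0.4,
                              seed = 1L) {
  stopifnot(inherits(x, "cohort"))
  response <- match.arg(response)
  if (length(grid) == 0L) stopf("width grid is empty")
  keep <- x$groups == group
  ages <- x$ages[keep]
  Y <- if (response == "shape") flatten_configs(x$coords[, , keep, drop = FALSE])
       else matrix(x$sizes[keep], ncol = 1L)
  n <- length(ages)
  k <- min(k, n)

  set.seed(seed)
  splits <- replicate(repeats, sample(rep_len(seq_len(k), n)), simplify = FALSE)

  errs <- numeric(length(grid))
  valid <- logical(length(grid))
  for (gi in seq_along(grid)) {
    h <- grid[gi]
    fold_errs <- c()
    bad <- FALSE
    for (sp in splits) {
      for (f in seq_len(k)) {
        tr <- sp != f
        te <- which(!tr)
        ok <- tryCatch({
          evaluation_range(ages[tr], h, threshold = support_threshold)
          TRUE
        }, error = function(e) FALSE)
        if (!ok) { bad <- TRUE; break }
        for (i in te) {
          w <- kernel_weights(ages[tr], ages[i], h)
          fit <- weighted_pls_fit(Y[tr, , drop = FALSE], ages[tr], w)
          pred <- fit$intercept + fit$coef * (ages[i] - fit$age_center)
          fold_errs <- c(fold_errs, sqrt(sum((Y[i, ] - pred)^2)))
        }
      }
      if (bad) break
    }
    valid[gi] <- !bad
    errs[gi] <- if (bad) NA_real_ else mean(fold_errs)
  }
  if (!any(valid)) stopf("every candidate width was invalid")
  best <- grid[which.min(ifelse(valid, errs, Inf))]
  structure(best, errors = data.frame(width = grid, mean_error = errs,
                                      valid = valid))
}
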