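#' Dimorphism-magnitude curve between two trajectories
#'
#' The Procrustes distance between the two groups' expected heads at each
#' grid age: the overall magnitude of the group difference as a function of
#' age. Ages outside the intersection of the two models' evaluation ranges
#' are dropped with a warning.
#'
#' @param model_a,model_b shape [fit_trajectory()] models in a common
#'   Procrustes frame.
#' @param ages numeric grid of target ages (years).
#' @return data.frame with columns `age` and `magnitude`.
#' @export
dimorphism_curve <- function(model_a, model_b, ages) {
  stopifnot(inherits(model_a, "trajectory_model"),
            inherits(model_b, "trajectory_model"))
  lo <- max(model_a$range$a_min, model_b$range$a_min)
  hi <- min(model_a$range$a_max, model_b$range$a_max)
  keep <- ages >= lo & ages <= hi
  if (!all(keep)) {
    warnf("%d grid ages outside the joint evaluation range [%.2f, %.2f] dropped",
          sum(!keep), lo, hi)
    ages <- ages[keep]
  }
  mag <- vapply(ages, function(a)
    shape_distance(expected_at(model_a, a, warn = FALSE),
                   expected_at(model_b, a, warn = FALSE)), numeric(1L))
  data.frame(age = ages, magnitude = mag)
}

# distance between the two groups' local predictions at each age, for a
# given label assignment; the workhorse of the permutation test
group_distance_curve <- function(Y, ages_obs, groups, ages, width) {
  lv <- levels(groups)
  ia <- groups == lv[1L]
  vapply(ages, function(a) {
    w <- kernel_weights(ages_obs, a, width)
    fa <- weighted_pls_fit(Y[ia, , drop = FALSE], ages_obs[ia], w[ia])
    fb <- weighted_pls_fit(Y[!ia, , drop = FALSE], ages_obs[!ia], w[!ia])
    pa <- fa$intercept + fa$coef * (a - fa$age_center)
    pb <- fb$intercept + fb$coef * (a - fb$age_center)
    sqrt(sum((pa - pb)^2))
  }, numeric(1L))
}

#' Permutation test of the dimorphism-magnitude curve
#'
#' Tests, at each grid age, whether the observed between-group Procrustes
#' distance exceeds what label exchange alone produces: group labels are
#' permuted (group sizes preserved), both kernel regressions are refitted
#' with the same kernel width, and the distance recomputed. P-values use
#' the add-one estimator `p = (1 + #{D* >= D}) / (1 + n_perm)`, so they lie
#' in `(0, 1]`.
#'
#' @param x an aligned [cohort()].
#' @param ages numeric grid of target ages.
#' @param width shape kernel width in years (default 2.75).
#' @param n_perm number of permutations (the study-scale default is
#'   10,000); capped with a warning at the number of distinct
#'   non-identity label assignments.
#' @param seed integer seed.
#' @param p_adjust optional multiple-testing correction across ages
#'   (`"none"`, default, or `"BH"`).
#' @return data.frame with `age`, `magnitude` (observed) and `p_value`.
#' @export
permutation_test <- function(x, ages, width = 2.75, n_perm = 10000L,
                             seed = 1L, p_adjust = c("none", "BH")) {
  stopifnot(inherits(x, "cohort"))
  p_adjust <- match.arg(p_adjust)
  if (n_perm < 1L) stopf("n_perm must be >= 1")
  if (!x$aligned) warnf("cohort is not aligned; permutation test assumes a common frame")
  Y <- flatten_configs(x$coords)
  n <- length(x)
  n1 <- sum(x$groups == levels(x$groups)[1L])
  max_distinct <- exp(lchoose(n, n1)) - 1
  if (is.finite(max_distinct) && n_perm > max_distinct) {
    warnf("only %d distinct permutations exist; capping n_perm", floor(max_distinct))
    n_perm <- as.integer(max_distinct)
  }
  observed <- group_distance_curve(Y, x$ages, x$groups, ages, width)
  set.seed(seed)
  exceed <- numeric(length(ages))
  for (b in seq_len(n_perm)) {
    gperm <- factor(sample(as.character(x$groups)), levels = levels(x$groups))
    dstar <- group_distance_curve(Y, x$ages, gperm, ages, width)
    exceed <- exceed + (dstar >= observed)
  }
  p <- (1 + exceed) / (1 + n_perm)
  if (p_adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  data.frame(age = ages, magnitude = observed, p_value = p)
}

#' Bootstrap confidence band for a cohort-level curve estimator
#'
#' Percentile bootstrap: cases are resampled with replacement within each
#' group (group sizes preserved, since the comparison is conditional on
#' group membership), the estimator is recomputed on each resample, and
#' pointwise percentile intervals are formed. Resamples on which the
#' estimator fails are dropped with a warning.
#'
#' @param x a [cohort()].
#' @param estimator function taking a cohort and returning a numeric vector
#'   (e.g. a curve over a fixed age grid).
#' @param n_boot number of bootstrap resamples (study-scale default
#'   10,000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return list with `estimate` (on the original cohort), `ci_low`,
#'   `ci_high` (same length), and `n_effective` resamples used.
#' @export
bootstrap_ci <- function(x, estimator, n_boot = 10000L, level = 0.95,
                         seed = 1L) {
  stopifnot(inherits(x, "cohort"), is.function(estimator))
  if (n_boot < 2L) stopf("n_boot must be >= 2")
  est <- estimator(x)
  set.seed(seed)
  idx_by_group <- split(seq_along(x$ages), x$groups)
  draws <- matrix(NA_real_, n_boot, length(est))
  failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(idx_by_group, function(ii)
      sample(ii, length(ii), replace = TRUE)), use.names = FALSE)
    xb <- x[idx]
    xb$ids <- sprintf("bs%06d", seq_along(idx)) # resampling duplicates ids
    val <- tryCatch(estimator(xb), error = function(e) NULL)
    if (is.null(val)) failed <- failed + 1L else draws[b, ] <- val
  }
  if (failed > 0L)
    warnf("estimator failed on %d of %d resamples; intervals use the rest",
          failed, n_boot)
  alpha <- (1 - level) / 2
  qs <- apply(draws, 2L, stats::quantile,
              probs = c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  list(estimate = est, ci_low = qs[1L, ], ci_high = qs[2L, ],
       n_effective = n_boot - failed)
}

#' Signed surface-normal displacement map
#'
#' For each vertex, the component of the displacement from `ref` to `other`
#' along `ref`'s outward unit normal: positive values are outward of the
#' reference surface, negative inward. This is the per-vertex "shape
#' difference" field used to colour difference maps.
#'
#' @param ref reference configuration (supplies the normals).
#' @param other second configuration in the same frame.
#' @param topo a [template_topology()].
#' @return numeric vector of length `p`; `NA` where the normal is zero.
#' @export
normal_displacement_map <- function(ref, other, topo) {
  check_config(ref, topo, "ref"); check_config(other, topo, "other")
  nrm <- suppressWarnings(vertex_normals(ref, topo))
  out <- rowSums((other - ref) * nrm)
  out[row_norms(nrm) == 0] <- NA_real_
  out
}

#' Signed axis displacement map
#'
#' Per-vertex coordinate difference `other - ref` along one axis: lateral
#' (x), vertical or depth depending on the template's axis convention.
#'
#' @inheritParams normal_displacement_map
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @return numeric vector of length `p`.
#' @export
axis_displacement_map <- function(ref, other, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  if (!all(dim(ref) == dim(other))) stopf("configurations must match in size")
  (other - ref)[, axis_index(axis)]
}

#' Per-vertex growth-rate difference map
#'
#' Compares the growth of two groups point by point. The default `"normal"`
#' mode differences the components of the two growth fields along the
#' supplied outward normals (the inward/outward rate of change); the
#' `"magnitude"` mode differences the vector lengths. Positive values mean
#' group A changes faster (outward or in magnitude).
#'
#' @param field_a,field_b `p x 3` growth fields on the same template.
#' @param normals `p x 3` outward unit normals (required for `"normal"`
#'   mode).
#' @param mode `"normal"` or `"magnitude"`.
#' @return signed numeric vector of length `p`.
#' @export
rate_difference_map <- function(field_a, field_b, normals = NULL,
                                mode = c("normal", "magnitude")) {
  mode <- match.arg(mode)
  a <- unclass(field_a); b <- unclass(field_b)
  if (!all(dim(a) == dim(b))) stopf("growth fields must match in size")
  if (mode == "normal") {
    if (is.null(normals)) stopf("normal mode needs the normals argument")
    rowSums(a * normals) - rowSums(b * normals)
  } else {
    row_norms(a) - row_norms(b)
  }
}

#' Per-vertex growth-direction angle map
#'
#' The angle, in degrees, between the two groups' growth vectors at each
#' vertex: 0 means the groups grow in the same direction at that point,
#' 180 in opposite directions. Vertices where either vector is numerically
#' zero get `NA`.
#'
#' @param field_a,field_b `p x 3` growth fields on the same template.
#' @param tol length below which a vector counts as zero.
#' @return numeric vector in `[0, 180]` (degrees), with `NA`s.
#' @export
direction_angle_map <- function(field_a, field_b, tol = 1e-12) {
  a <- unclass(field_a); b <- unclass(field_b)
  if (!all(dim(a) == dim(b))) stopf("growth fields must match in size")
  na <- row_norms(a); nb <- row_norms(b)
  cosang <- rowSums(a * b) / (na * nb)
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- acos(cosang) * 180 / pi
  ang[na < tol | nb < tol] <- NA_real_
  ang
}

#' Exaggeration morph between two configurations
#'
#' Linear extrapolation along the difference between two configurations:
#' `ref + factor * (other - ref)`. Factors beyond 1 exaggerate the
#' difference, which makes subtle group contrasts visible.
#'
#' @inheritParams axis_displacement_map
#' @param factor morphing factor (0 returns `ref`, 1 returns `other`).
#' @return `p x 3` configuration.
#' @export
morph <- function(ref, other, factor) {
  if (!all(dim(ref) == dim(other))) stopf("configurations must match in size")
  ref + factor * (other - ref)
}

#' Full two-group trajectory comparison
#'
#' Convenience wrapper producing the comparison outputs on one age grid:
#' the dimorphism-magnitude curve, both groups' overall growth-rate curves,
#' and (optionally) permutation p-values and bootstrap confidence
#' intervals for the magnitude curve.
#'
#' @param x an aligned [cohort()].
#' @param ages age grid; defaults to the joint evaluation range in steps of
#'   0.25 y.
#' @param width shape kernel width (years).
#' @param n_perm permutations for the p-values (0 skips the test).
#' @param n_boot bootstrap resamples for the CIs (0 skips them).
#' @param level confidence level for the bootstrap band.
#' @param seed integer seed.
#' @return object of class `trajectory_comparison`: a list with `curve`
#'   (data.frame: age, magnitude, rate_a, rate_b, and p_value / ci columns
#'   when computed), the two fitted models, and the group labels.
#' @export
compare_trajectories <- function(x, ages = NULL, width = 2.75, n_perm = 0L,
                                 n_boot = 0L, level = 0.95, seed = 1L) {
  stopifnot(inherits(x, "cohort"))
  lv <- levels(x$groups)
  ma <- fit_trajectory(x, lv[1L], "shape", width)
  mb <- fit_trajectory(x, lv[2L], "shape", width)
  if (is.null(ages)) {
    lo <- max(ma$range$a_min, mb$range$a_min)
    hi <- min(ma$range$a_max, mb$range$a_max)
    ages <- seq(lo, hi, by = 0.25)
  }
  curve <- dimorphism_curve(ma, mb, ages)
  curve$rate_a <- vapply(curve$age, function(a)
    growth_rate(growth_field_at(ma, a, warn = FALSE)), numeric(1L))
  curve$rate_b <- vapply(curve$age, function(a)
    growth_rate(growth_field_at(mb, a, warn = FALSE)), numeric(1L))
  if (n_perm > 0L) {
    pt <- permutation_test(x, curve$age, width, n_perm, seed)
    curve$p_value <- pt$p_value
  }
  if (n_boot > 0L) {
    est <- function(xb) # direct refit on the fixed grid (no range machinery,
      group_distance_curve(flatten_configs(xb$coords), xb$ages, xb$groups,
                           curve$age, width) # so every resample is evaluable)
    ci <- bootstrap_ci(x, est, n_boot, level, seed)
    curve$ci_low <- ci$ci_low
    curve$ci_high <- ci$ci_high
  }
  structure(list(curve = curve, model_a = ma, model_b = mb, groups = lv),
            class = "trajectory_comparison")
}

#' @export
print.trajectory_comparison <- function(x, ...) {
  cat(sprintf("Trajectory comparison %s vs %s over ages %.2f-%.2f y (%d grid points)\n",
              x$groups[1L], x$groups[2L], min(x$curve$age), max(x$curve$age),
              nrow(x$curve)))
  print(utils::head(x$curve))
  invisible(x)
}
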