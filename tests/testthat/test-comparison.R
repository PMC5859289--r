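test_that("dimorphism curve is zero for identical groups and recovers a known offset", {
  ch <- small_cohort("null", n_per_group = 40L, seed = 20L)
  # identical training data for both groups
  chA <- ch
  idx_a <- which(ch$groups == "A")
  for (j in seq_along(idx_a))
    chA$coords[, , which(ch$groups == "B")[j]] <- ch$coords[, , idx_a[j]]
  chA$ages[ch$groups == "B"] <- ch$ages[idx_a]
  ma <- fit_trajectory(chA, "A", width = 2.75, support_threshold = 0)
  mb <- fit_trajectory(chA, "B", width = 2.75, support_threshold = 0)
  grid <- seq(5, 14, by = 1)
  expect_equal(dimorphism_curve(ma, mb, grid)$magnitude, rep(0, length(grid)),
               tolerance = 1e-9)

  # group B translated by a fixed shape-space vector (large relative to the
  # local-fit noise floor, which adds in quadrature)
  v <- matrix(rnorm(26 * 3, sd = 2), 26, 3)
  chB <- ch
  for (i in which(ch$groups == "B"))
    chB$coords[, , i] <- chB$coords[, , i] + v
  ma <- fit_trajectory(chB, "A", width = 2.75, support_threshold = 0)
  mb <- fit_trajectory(chB, "B", width = 2.75, support_threshold = 0)
  curve <- dimorphism_curve(ma, mb, grid)$magnitude
  expect_equal(curve, rep(sqrt(sum(v^2)), length(grid)), tolerance = 0.1)

  # label swap leaves the curve unchanged
  expect_equal(dimorphism_curve(mb, ma, grid)$magnitude, curve)
})

test_that("permutation p-values are extreme for separated groups and well-formed", {
  spec <- growth_scenario(tpl1, "separated", separation = 20, nuisance = NULL)
  ch <- simulate_cohort(spec, 30, seed = 21)
  res <- permutation_test(ch, c(5, 9, 13), width = 2.75, n_perm = 99,
                          seed = 1)
  expect_equal(res$p_value, rep(1 / 100, 3L))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))

  # cap when fewer distinct permutations exist than requested
  chs <- ch[c(1:3, 31:33)]
  expect_warning(
    res2 <- permutation_test(chs, 9, width = 5, n_perm = 100, seed = 1),
    "distinct permutations")
})

test_that("bootstrap intervals behave on degenerate and scalar-mean cases", {
  ch <- small_cohort("null", n_per_group = 8L, seed = 22L)
  # zero-variance cohort: every config identical within group
  for (g in c("A", "B")) {
    idx <- which(ch$groups == g)
    for (i in idx) ch$coords[, , i] <- ch$coords[, , idx[1L]]
  }
  est <- function(x) {
    m <- apply(x$coords[, , x$groups == "A", drop = FALSE], c(1, 2), mean)
    sqrt(sum(m^2))
  }
  ci <- bootstrap_ci(ch, est, n_boot = 50L, seed = 3L)
  expect_equal(ci$ci_low, ci$ci_high, tolerance = 1e-12)
  expect_equal(ci$n_effective, 50L)

  # coverage of the within-group mean on simulated cohorts (reduced scale)
  set.seed(23)
  cover <- 0L
  nsim <- 60L
  spec0 <- growth_scenario(tpl1, "null", nuisance = NULL)
  for (s in seq_len(nsim)) {
    ch <- small_cohort("null", n_per_group = 25L, seed = 3000L + s)
    true_mean <- mean(vapply(
      seq_along(ch$ages), function(i)
        centroid_size(spec0$mean_fn(as.character(ch$groups[i]), ch$ages[i])),
      numeric(1L)))
    est <- function(x) mean(x$sizes)
    ci <- bootstrap_ci(ch, est, n_boot = 99L, seed = s)
    cover <- cover + (ci$ci_low <= true_mean && true_mean <= ci$ci_high)
  }
  expect_gt(cover / nsim, 0.80)
  expect_lte(cover / nsim, 1)
})

test_that("displacement maps isolate the normal and axis components", {
  topo <- tpl_sphere$topology
  ref <- tpl_sphere$base
  nrm <- vertex_normals(ref, topo)

  expect_equal(normal_displacement_map(ref, ref, topo), rep(0, nrow(ref)))
  out <- normal_displacement_map(ref, ref + 0.7 * nrm, topo)
  expect_equal(out, rep(0.7, nrow(ref)), tolerance = 1e-9)

  # tangential displacement is invisible to the normal map
  tang <- cbind(-nrm[, 2L], nrm[, 1L], 0)
  expect_equal(normal_displacement_map(ref, ref + 0.5 * tang, topo),
               rep(0, nrow(ref)), tolerance = 1e-9)

  other <- ref + matrix(rnorm(3 * nrow(ref)), ncol = 3L)
  mx <- axis_displacement_map(ref, other, "x")
  my <- axis_displacement_map(ref, other, "y")
  mz <- axis_displacement_map(ref, other, "z")
  expect_equal(mx^2 + my^2 + mz^2, rowSums((other - ref)^2))
  shift <- ref; shift[, 1L] <- shift[, 1L] + 2.5
  expect_equal(axis_displacement_map(ref, shift, "x"), rep(2.5, nrow(ref)))
  expect_equal(axis_displacement_map(ref, shift, "y"), rep(0, nrow(ref)))
})

test_that("rate and direction maps compare growth fields pointwise", {
  nrm <- vertex_normals(tpl_sphere$base, tpl_sphere$topology)
  f <- 0.8 * nrm # purely outward growth
  expect_equal(rate_difference_map(f, f, nrm), rep(0, nrow(nrm)))
  expect_true(all(rate_difference_map(2 * f, f, nrm) > 0))
  expect_true(all(rate_difference_map(2 * f, f, mode = "magnitude") > 0))
  expect_equal(rate_difference_map(f, 2 * f, mode = "magnitude"),
               -rate_difference_map(2 * f, f, mode = "magnitude"))

  expect_equal(direction_angle_map(f, f), rep(0, nrow(nrm)),
               tolerance = 1e-5)
  expect_equal(direction_angle_map(f, -f), rep(180, nrow(nrm)),
               tolerance = 1e-5)
  orth <- cbind(-f[, 2L], f[, 1L], 0) # vanishes at the two poles
  ang_orth <- direction_angle_map(f, orth)
  expect_equal(sum(is.na(ang_orth)), 2L)
  expect_equal(ang_orth[!is.na(ang_orth)],
               rep(90, sum(!is.na(ang_orth))), tolerance = 1e-9)
  zf <- f; zf[1L, ] <- 0
  expect_true(is.na(direction_angle_map(f, zf)[1L]))
  # label swap: angle maps unchanged
  g <- f + matrix(rnorm(length(f), sd = 0.1), nrow(f), 3L)
  expect_equal(direction_angle_map(f, g), direction_angle_map(g, f))
})

test_that("morphs interpolate and exaggerate linearly", {
  set.seed(24)
  a <- random_config(8); b <- random_config(8)
  expect_equal(morph(a, b, 0), a)
  expect_equal(morph(a, b, 1), b)
  expect_equal(morph(a, b, 2), b + (b - a))
})

test_that("compare_trajectories assembles curves with rates, p-values and CIs", {
  ch <- small_cohort("rate", n_per_group = 40L, seed = 25L)
  cmpr <- compare_trajectories(ch, width = 2.75,
                               n_perm = 49L, n_boot = 30L, seed = 2L)
  cv <- cmpr$curve
  expect_named(cv, c("age", "magnitude", "rate_a", "rate_b", "p_value",
                     "ci_low", "ci_high"))
  expect_true(all(cv$magnitude >= 0))
  expect_true(all(cv$p_value > 0 & cv$p_value <= 1))
  expect_true(all(cv$ci_low <= cv$ci_high))
  # "rate" scenario: group B changes faster
  expect_true(all(cv$rate_b > cv$rate_a))
})
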