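test_that("kernel weights follow the Gaussian age profile", {
  ages <- c(1, 3, 5, 9)
  expect_equal(kernel_weights(ages, 3, width = 2)[2L], 1)
  expect_equal(kernel_weights(5, a = 1, width = 2), exp(-2)) # two widths away
  w <- kernel_weights(seq(0, 10, by = 0.5), 4, width = 1.5)
  d <- abs(seq(0, 10, by = 0.5) - 4)
  expect_true(all(diff(w[order(d)]) <= 1e-15))
  expect_error(kernel_weights(numeric(), 1, 1), "non-empty")
  expect_error(kernel_weights(ages, 1, width = 0), "width")
})

test_that("weighted PLS on one predictor equals the weighted regression slope", {
  # exact linear fit
  fit <- weighted_pls_fit(matrix(c(0, 1, 2)), c(0, 1, 2), rep(1, 3))
  expect_equal(fit$coef, 1)
  expect_equal(fit$intercept + fit$coef * (0 - fit$age_center), 0)

  # independent oracle: weighted lm
  set.seed(10)
  for (i in 1:5) {
    a <- runif(30, 0, 18)
    y <- 2 - 0.4 * a + rnorm(30)
    w <- runif(30, 0.01, 1)
    fit <- weighted_pls_fit(matrix(y), a, w)
    ora <- lm(y ~ a, weights = w)
    expect_equal(fit$coef, unname(coef(ora)[2L]), tolerance = 1e-10)
    expect_equal(fit$intercept + fit$coef * (0 - fit$age_center),
                 unname(coef(ora)[1L]), tolerance = 1e-10)
  }

  # noiseless multivariate linear responses: slopes recovered exactly
  a <- seq(1, 10)
  B <- matrix(rnorm(15), 1, 15)
  Y <- outer(a, as.vector(B)) + matrix(rnorm(15), 10, 15, byrow = TRUE)
  fit <- weighted_pls_fit(Y, a, runif(10, 0.5, 1))
  expect_equal(fit$coef, as.vector(B), tolerance = 1e-8)

  expect_error(weighted_pls_fit(matrix(1:3), c(2, 2, 2), rep(1, 3)),
               "singular")
  expect_error(weighted_pls_fit(matrix(1:3), 1:3, rep(0, 3)), "weight")
})

test_that("expected_at reproduces constants and the wide-kernel linear limit", {
  ch <- small_cohort("rate", n_per_group = 60L, seed = 11L)
  m <- fit_trajectory(ch, "A", "shape", width = 2.75)

  # constant-in-age data
  const <- ch
  for (i in seq_len(length(ch))) const$coords[, , i] <- ch$coords[, , 1L]
  mc <- fit_trajectory(const, "A", "shape", width = 2.75)
  expect_equal(expected_at(mc, 5, warn = FALSE), ch$coords[, , 1L],
               tolerance = 1e-9)

  # width -> infinity: global unweighted linear fit (lm oracle)
  mw <- fit_trajectory(ch, "A", "shape", width = 1e6, support_threshold = 0)
  Y <- as.matrix(ch)[ch$groups == "A", ]
  a <- ch$ages[ch$groups == "A"]
  ora <- lm.fit(cbind(1, a), Y)
  for (age in c(4, 9, 14)) {
    pred <- ora$coefficients[1L, ] + ora$coefficients[2L, ] * age
    expect_equal(as.vector(expected_at(mw, age, warn = FALSE)), unname(pred),
                 tolerance = 1e-6)
    expect_equal(as.vector(growth_field_at(mw, age, warn = FALSE)),
                 unname(ora$coefficients[2L, ]), tolerance = 1e-6)
  }

  # continuity in the target age
  d1 <- shape_distance(expected_at(m, 9, warn = FALSE),
                       expected_at(m, 9 + 1e-4, warn = FALSE))
  expect_lt(d1, 1e-2)

  # extrapolation warning outside the evaluation range
  expect_warning(expected_at(m, 0.51), "extrapolating")
})

test_that("growth fields scale correctly and average into the growth rate", {
  ch <- small_cohort("rate", n_per_group = 60L, seed = 12L)
  m <- fit_trajectory(ch, "A", "shape", width = 2.75)
  f <- growth_field_at(m, 9, warn = FALSE)
  expect_equal(dim(unclass(f)), c(26L, 3L))

  # doubling all ages halves per-year coefficients at the doubled target
  ch2 <- ch
  ch2$ages <- 2 * ch$ages
  m2 <- fit_trajectory(ch2, "A", "shape", width = 2 * 2.75,
                       support_threshold = 0)
  f2 <- growth_field_at(m2, 18, warn = FALSE)
  expect_equal(unclass(f2), unclass(f) / 2, tolerance = 1e-9,
               ignore_attr = TRUE)

  # growth_rate is the mean vector length
  fld <- rbind(c(1, 0, 0), c(0, 3, 0))
  expect_equal(growth_rate(fld), 2)
  expect_equal(growth_rate(matrix(0, 5, 3)), 0)
  expect_equal(growth_rate(matrix(rep(c(3, 4, 0), each = 4), 4, 3)), 5)
})

test_that("size trajectories track recorded physical sizes", {
  spec <- growth_scenario(tpl1, "rate", nuisance = NULL)
  ch <- simulate_cohort(spec, 80, seed = 13)
  m <- fit_trajectory(ch, "A", "size", width = 0.75)
  expect_equal(m$width, 0.75)
  s9 <- expected_at(m, 9, warn = FALSE)
  # sizes grow roughly linearly under the linear radial growth field
  expect_gt(expected_at(m, 14, warn = FALSE), s9)
  expect_gt(s9, expected_at(m, 4, warn = FALSE))
})

# brute-force oracle: scan a grid, test the balance ratio at each age
range_oracle <- function(ages, width, threshold, step = 0.01) {
  grid <- unique(c(seq(min(ages), max(ages), by = step), max(ages)))
  ok <- logical(length(grid))
  for (i in seq_along(grid)) {
    w <- exp(-(ages - grid[i])^2 / (2 * width^2))
    so <- sum(w[ages > grid[i]]); sy <- sum(w[ages < grid[i]])
    r <- if (so == 0 || sy == 0) 0 else min(so / sy, sy / so)
    ok[i] <- r >= threshold
  }
  runs <- rle(ok); ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  c(grid[starts[best]], grid[ends[best]])
}

test_that("evaluation range matches the brute-force oracle and edge cases", {
  set.seed(14)
  ages <- runif(100, 0, 18)
  r0 <- evaluation_range(ages, 2.75, threshold = 0)
  expect_equal(c(r0$a_min, r0$a_max), range(ages))

  ages_u <- seq(0, 18, length.out = 181)
  ru <- evaluation_range(ages_u, 2.75, threshold = 0.4)
  expect_lt(abs((ru$a_min + ru$a_max) / 2 - 9), ru$step + 1e-9)

  for (i in 1:5) {
    ages <- runif(60, 0, 18)
    for (thr in c(0, 0.2, 0.4)) {
      got <- evaluation_range(ages, 2.75, threshold = thr)
      expect_identical(c(got$a_min, got$a_max), range_oracle(ages, 2.75, thr))
    }
  }
  expect_error(evaluation_range(c(3, 3, 3), 1), "distinct")
})

test_that("kernel-width tuning prefers wide kernels for linear truth, narrower for curved", {
  set.seed(15)
  n <- 160L
  a <- runif(n, 0, 18)
  coords <- array(rep(tpl1$base, n), c(26L, 3L, n)) # coords irrelevant: size response
  lin <- cohort(coords, a, rep(c("A", "B"), n / 2),
                sizes = 70 + 1.5 * a + rnorm(n, sd = 2))
  crv <- cohort(coords, a, rep(c("A", "B"), n / 2),
                sizes = 70 + 10 * sin(a / 1.6) + rnorm(n, sd = 2))
  grid <- c(0.5, 2, 8)
  w_lin <- tune_kernel_width(lin, grid, group = "A", response = "size",
                             k = 5L, repeats = 3L, support_threshold = 0,
                             seed = 99L)
  w_crv <- tune_kernel_width(crv, grid, group = "A", response = "size",
                             k = 5L, repeats = 3L, support_threshold = 0,
                             seed = 99L)
  expect_equal(as.numeric(w_lin), 8)
  expect_lt(as.numeric(w_crv), 8)
  # CV error monotone decreasing in width for linear truth, increasing for
  # a sharply curved one
  expect_true(all(diff(attr(w_lin, "errors")$mean_error) < 0))
  expect_true(all(diff(attr(w_crv, "errors")$mean_error) > 0))
  expect_s3_class(attr(w_lin, "errors"), "data.frame")

  expect_equal(as.numeric(tune_kernel_width(lin, 2.75, group = "A",
                                            response = "size", k = 4L,
                                            repeats = 1L,
                                            support_threshold = 0)), 2.75)
})
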