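test_that("centroid size is the mean vertex-centroid distance", {
  sq <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0))
  expect_equal(centroid_size(sq), sqrt(2))
  expect_equal(centroid_size(matrix(5, 4, 3)), 0)
  set.seed(1)
  x <- random_config(12)
  expect_equal(centroid_size(3.7 * x), 3.7 * centroid_size(x))
  expect_error(centroid_size(matrix(1, 1, 3)), "at least 2")
})

test_that("symmetrize averages a configuration with its mirrored relabelled copy", {
  x <- cbind(c(1, -2), c(0, 0), c(0, 0))
  out <- symmetrize(x, tiny_pair_topo)
  expect_equal(out, cbind(c(1.5, -1.5), c(0, 0), c(0, 0)))

  # fixed point on an already-symmetric centered configuration
  expect_equal(symmetrize(tpl1$base, tpl1$topology), tpl1$base,
               tolerance = 1e-12)

  set.seed(2)
  x <- random_config(tpl1$topology$n_vertices)
  s1 <- symmetrize(x, tpl1$topology)
  # idempotent, reflect-relabel invariant, commutes with reflect-relabel
  expect_equal(symmetrize(s1, tpl1$topology), s1, tolerance = 1e-9)
  expect_equal(morphotraj:::reflect_relabel(s1, tpl1$topology), s1,
               tolerance = 1e-9)
  expect_equal(symmetrize(morphotraj:::reflect_relabel(x, tpl1$topology),
                          tpl1$topology), s1, tolerance = 1e-9)

  expect_error(symmetrize(x[-1, ], tpl1$topology), "vertices")
})

# independent closed-form orthogonal Procrustes oracle (Kabsch)
ols_procrustes_oracle <- function(src, tgt) {
  xs <- scale(src, scale = FALSE)
  xt <- scale(tgt, scale = FALSE)
  s <- svd(t(xs) %*% xt)
  R <- s$u %*% diag(c(1, 1, sign(det(s$u) * det(s$v)))) %*% t(s$v)
  sweep(xs %*% R, 2L, colMeans(tgt), "+")
}

test_that("robust alignment recovers exact transforms and matches OLS on clean data", {
  set.seed(3)
  tgt <- random_config(15)
  src <- transform_config(tgt)
  fit <- robust_align(src, tgt)
  expect_lt(sqrt(sum((fit$aligned - tgt)^2)), 1e-8)

  # clean but non-identical configurations: robust == ordinary within 1e-6
  for (i in 1:5) {
    tgt <- random_config(20)
    src <- transform_config(tgt + matrix(rnorm(60, sd = 0.5), 20, 3))
    expect_equal(robust_align(src, tgt)$aligned,
                 ols_procrustes_oracle(src, tgt), tolerance = 1e-6)
  }
})

test_that("robust alignment resists a gross single-vertex outlier", {
  set.seed(4)
  noise_sd <- 0.1
  tgt <- random_config(25)
  src <- tgt + matrix(rnorm(75, sd = noise_sd), 25, 3)
  src <- transform_config(src)
  src[1L, ] <- src[1L, ] + c(50 * noise_sd * 10, 0, 0)

  rob <- robust_align(src, tgt)$aligned
  ols <- ols_procrustes_oracle(src, tgt)
  trimmed <- function(al) sum((al[-1L, ] - tgt[-1L, ])^2)
  expect_lt(trimmed(rob), trimmed(ols))
})

test_that("gpa recovers identical shapes from random similarity transforms", {
  set.seed(5)
  x0 <- morphotraj:::center_config(tpl1$base)
  n <- 8L
  coords <- array(0, c(nrow(x0), 3L, n))
  for (i in seq_len(n))
    coords[, , i] <- transform_config(x0, scale = runif(1, 0.8, 1.2))
  ch <- cohort(coords, ages = seq(1, 8), groups = rep(c("A", "B"), 4L))
  al <- gpa(ch, scale = TRUE, robust = TRUE)
  rng <- apply(al$coords, c(1L, 2L), function(v) diff(range(v)))
  expect_lt(max(rng), 1e-6)
  expect_true(al$converged)
})

test_that("gpa output is invariant to input similarity transforms", {
  ch <- small_cohort("rate", n_per_group = 15L, seed = 6L)
  al1 <- gpa(ch, scale = TRUE, robust = TRUE)
  set.seed(7)
  ch2 <- ch
  for (i in seq_len(length(ch)))
    ch2$coords[, , i] <- transform_config(ch$coords[, , i],
                                          scale = runif(1, 0.7, 1.4))
  al2 <- gpa(ch2, scale = TRUE, robust = TRUE)
  expect_lt(max(abs(al1$coords - al2$coords)), 1e-6)

  # unit sizes and centered consensus under scaling
  expect_lt(max(abs(apply(al1$coords, 3L, centroid_size) - 1)), 1e-9)
  expect_lt(max(abs(colMeans(al1$consensus))), 1e-9)
})

test_that("gpa with scale = FALSE conserves sizes", {
  ch <- small_cohort("null", n_per_group = 10L, seed = 8L)
  sizes_in <- apply(ch$coords, 3L, centroid_size)
  al <- gpa(ch, scale = FALSE, robust = FALSE)
  expect_equal(apply(al$coords, 3L, centroid_size), sizes_in,
               tolerance = 1e-9)
})

test_that("shape distance is a metric with the expected scale", {
  a <- matrix(0, 5, 3)
  b <- a; b[2, 1] <- 0.3
  expect_equal(shape_distance(a, b), 0.3)
  expect_equal(shape_distance(a, a), 0)
  set.seed(9)
  for (i in 1:20) {
    x <- random_config(6); y <- random_config(6); z <- random_config(6)
    expect_gte(shape_distance(x, y), 0)
    expect_equal(shape_distance(x, y), shape_distance(y, x))
    expect_lte(shape_distance(x, z),
               shape_distance(x, y) + shape_distance(y, z) + 1e-12)
  }
  expect_error(shape_distance(a, a[-1, ]), "dimensions")
})

test_that("vertex normals are unit, outward and radial on a sphere", {
  nrm <- vertex_normals(tpl_sphere$base, tpl_sphere$topology)
  expect_equal(unname(sqrt(rowSums(nrm^2))), rep(1, nrow(nrm)),
               tolerance = 1e-9)
  radial <- tpl_sphere$base / sqrt(rowSums(tpl_sphere$base^2))
  expect_gt(min(rowSums(nrm * radial)), 0.99)
})

test_that("vertex normals on a flat patch point along z; isolated vertices warn", {
  patch <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  topo <- template_topology(4L, rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)),
                            matrix(integer(), ncol = 2L), 1:4, "x")
  nrm <- vertex_normals(patch, topo)
  expect_equal(nrm, matrix(rep(c(0, 0, 1), each = 4L), 4L, 3L))

  topo_iso <- template_topology(4L, rbind(c(1L, 2L, 3L)),
                                matrix(integer(), ncol = 2L), 1:4, "x")
  expect_warning(n2 <- vertex_normals(patch, topo_iso), "isolated")
  expect_equal(n2[4L, ], c(0, 0, 0))
})
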