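# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# p x 3 x n array -> n x 3p matrix (column-major flattening: all x, all y, all z)
flatten_configs <- function(arr) {
  d <- dim(arr)
  t(matrix(arr, d[1L] * d[2L], d[3L]))
}

# length-3p vector -> p x 3 matrix
unflatten_config <- function(v, p) {
  matrix(v, nrow = p, ncol = 3L)
}

row_norms <- function(m) sqrt(rowSums(m * m))

center_config <- function(x) {
  sweep(x, 2L, colMeans(x), "-")
}

# Rodrigues rotation matrix about unit axis u by angle theta (radians)
rotation_about_axis <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3L], -u[2L], -u[3L], 0, u[1L], u[2L], -u[1L], 0), 3L, 3L)
  diag(3L) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# random rotation with angle uniform on [0, max_angle] and uniform random axis
random_rotation <- function(max_angle) {
  u <- stats::rnorm(3L)
  rotation_about_axis(u, stats::runif(1L, 0, max_angle))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
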