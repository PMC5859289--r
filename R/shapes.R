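#' Centroid size of a configuration
#'
#' Size is measured as the mean Euclidean distance of all vertices from
#' their centroid. This mean-distance measure is used both for reporting
#' physical size (in mm) and for unit-size scaling during [gpa()]; it
#' differs from the classical root-sum-of-squares centroid size only by a
#' constant factor for a fixed template.
#'
#' @param config `p x 3` coordinate matrix.
#' @return scalar size, in the units of `config`.
#' @examples
#' sq <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0))
#' centroid_size(sq) # sqrt(2)
#' @export
centroid_size <- function(config) {
  check_config(config)
  if (nrow(config) < 2L)
    stopf("centroid_size needs at least 2 vertices")
  mean(row_norms(center_config(config)))
}

# reflect across the plane through the centroid normal to the template's
# mirror axis, then swap left/right vertex labels; output is centered
reflect_relabel <- function(config, topo) {
  check_config(config, topo)
  xc <- center_config(config)
  ax <- axis_index(topo$reflection_axis)
  xc[, ax] <- -xc[, ax]
  xc[symmetry_permutation(topo), , drop = FALSE]
}

#' Symmetrize a configuration
#'
#' Forms the symmetric component of a configuration by averaging it with
#' its reflected-and-relabelled copy: the configuration is centered,
#' mirrored across the plane through the centroid normal to the template's
#' reflection axis, left and right vertices are swapped, and the two copies
#' are averaged. The result is centered and exactly invariant under
#' reflect-and-relabel.
#'
#' @param config `p x 3` coordinate matrix.
#' @param topo a [template_topology()].
#' @return centered symmetric `p x 3` configuration.
#' @export
symmetrize <- function(config, topo) {
  xc <- center_config(check_config(config, topo))
  (xc + reflect_relabel(xc, topo)) / 2
}

# weighted ordinary Procrustes fit of source onto target.
# Returns the aligned source and the (rotation, scale, translation) used.
procrustes_fit <- function(source, target, weights = NULL, allow_scale = FALSE) {
  if (nrow(source) != nrow(target))
    stopf("source and target must have the same vertex count")
  p <- nrow(source)
  w <- if (is.null(weights)) rep(1, p) else weights
  sw <- sum(w)
  if (sw <= 0) stopf("total weight must be positive")
  cs <- colSums(w * source) / sw
  ct <- colSums(w * target) / sw
  xs <- sweep(source, 2L, cs, "-")
  xt <- sweep(target, 2L, ct, "-")
  denom <- sum(w * rowSums(xs^2))
  if (denom < .Machine$double.eps)
    stopf("degenerate configuration: all weighted vertices coincide")
  M <- crossprod(xs, w * xt)
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  s <- if (allow_scale) sum(diag(crossprod(R, M))) / denom else 1
  aligned <- s * (xs %*% R)
  aligned <- sweep(aligned, 2L, ct, "+")
  list(aligned = aligned, rotation = R, scale = s,
       translation = ct - s * as.vector(cs %*% R))
}

#' Robust Procrustes alignment of one configuration onto another
#'
#' Superimposes `source` onto `target` by a similarity (or rigid) transform
#' fitted by iteratively reweighted least squares. Vertex weights are flat
#' at 1 inside the residual bulk and decline with a Gaussian tail beyond
#' it: \eqn{w_v = \exp(-(r_v - c\sigma)_+^2 / 2\sigma^2)} with
#' \eqn{\sigma = 1.4826 \times \mathrm{median}(r)} and cutoff `c = 3`, so
#' grossly displaced vertices do not drag the fit while ordinary residuals
#' keep full weight. On outlier-free data every weight is 1 and the result
#' coincides with the ordinary least-squares Procrustes fit.
#'
#' @param source,target `p x 3` coordinate matrices with matching vertex
#'   order.
#' @param allow_scale include a scale factor in the transform?
#' @param iterations number of IRLS iterations.
#' @param cutoff residuals within `cutoff` robust sd keep full weight.
#' @return list with `aligned` coordinates, transform parameters
#'   (`rotation`, `scale`, `translation`) and final vertex `weights`.
#' @export
robust_align <- function(source, target, allow_scale = FALSE, iterations = 10L,
                         cutoff = 3) {
  check_config(source, arg = "source")
  check_config(target, arg = "target")
  w <- rep(1, nrow(source))
  fit <- procrustes_fit(source, target, w, allow_scale)
  for (it in seq_len(iterations)) {
    r <- row_norms(fit$aligned - target)
    sigma <- 1.4826 * stats::median(r)
    if (sigma < 1e-12) break # already an essentially exact fit
    w <- exp(-pmax(0, r - cutoff * sigma)^2 / (2 * sigma^2))
    fit <- procrustes_fit(source, target, w, allow_scale)
  }
  fit$weights <- w
  fit
}

#' Procrustes (shape-space) distance between two aligned configurations
#'
#' The Euclidean (Frobenius) norm of the coordinate difference. All
#' configurations are assumed to sit in one common Procrustes frame, so no
#' re-superimposition is performed; this is the usual tangent-space
#' approximation for small shape variation.
#'
#' @param a,b `p x 3` coordinate matrices in the same frame.
#' @return non-negative scalar distance.
#' @export
shape_distance <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stopf("configurations must have identical dimensions")
  sqrt(sum((a - b)^2))
}

#' Generalized Procrustes alignment of a cohort
#'
#' Iteratively superimposes every configuration on an evolving consensus
#' until the consensus stabilizes. Configurations are centered first; with
#' `scale = TRUE` each is divided by its centroid size ([centroid_size()]),
#' placing the sample in shape space, while `scale = FALSE` retains size
#' (size-and-shape space). Rotations are fitted by ordinary or robust
#' ([robust_align()]) Procrustes fits.
#'
#' After convergence the whole sample is rotated so that the consensus lies
#' in its principal-axes frame with a deterministic sign convention (no
#' reflections). This makes the aligned coordinates invariant, up to
#' numerical tolerance, to arbitrary similarity transforms applied to the
#' input configurations.
#'
#' @param x a [cohort()].
#' @param scale scale configurations to unit centroid size?
#' @param robust use robust Procrustes fits?
#' @param tol convergence tolerance on the Frobenius change of the
#'   consensus.
#' @param max_iter maximum number of alignment sweeps; non-convergence
#'   raises a warning and returns the current state (`converged = FALSE`).
#' @return the aligned cohort, with `consensus` (a `p x 3` matrix),
#'   `aligned`/`scaled` flags set, recorded physical `sizes` untouched, and
#'   attribute-like fields `gpa_iterations` and `converged`.
#' @export
gpa <- function(x, scale = TRUE, robust = TRUE, tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(x, "cohort"))
  n <- length(x)
  if (n < 2L) stopf("gpa needs at least 2 configurations")
  p <- dim(x$coords)[1L]

  base <- array(0, dim(x$coords))
  for (i in seq_len(n)) {
    xi <- center_config(x$coords[, , i])
    if (scale) xi <- xi / centroid_size(xi)
    base[, , i] <- xi
  }

  consensus <- base[, , 1L]
  aligned <- base
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    for (i in seq_len(n)) {
      fit <- if (robust)
        robust_align(base[, , i], consensus, allow_scale = FALSE)
      else
        procrustes_fit(base[, , i], consensus, allow_scale = FALSE)
      aligned[, , i] <- center_config(fit$aligned)
    }
    new_consensus <- center_config(apply(aligned, c(1L, 2L), mean))
    if (scale) new_consensus <- new_consensus / centroid_size(new_consensus)
    # anchor the frame: per-config robust weights exert a small net torque on
    # the mean, which would otherwise rotate the whole frame indefinitely
    new_consensus <- procrustes_fit(new_consensus, consensus,
                                    allow_scale = FALSE)$aligned
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warnf("gpa did not converge within %d iterations (last change %.3g)",
          max_iter, delta)

  rot <- canonical_rotation(consensus)
  consensus <- consensus %*% rot
  for (i in seq_len(n)) aligned[, , i] <- aligned[, , i] %*% rot

  out <- x
  out$coords <- aligned
  out$aligned <- TRUE
  out$scaled <- isTRUE(scale)
  out$consensus <- consensus
  out$gpa_iterations <- iter
  out$converged <- converged
  validate_cohort(out)
  out
}

# rotation taking a centered configuration to its principal-axes frame with
# deterministic axis signs; paired column flips keep det = +1 (no mirror)
canonical_rotation <- function(consensus) {
  sv <- svd(consensus)
  R <- sv$v
  if (det(R) < 0) R[, 3L] <- -R[, 3L]
  y <- consensus %*% R
  f <- as.vector(crossprod(y, seq_len(nrow(y)))) # fixed linear functional per axis
  neg <- f < 0
  if (neg[1L] && neg[2L]) R[, c(1L, 2L)] <- -R[, c(1L, 2L)]
  else if (neg[1L]) R[, c(1L, 3L)] <- -R[, c(1L, 3L)]
  else if (neg[2L]) R[, c(2L, 3L)] <- -R[, c(2L, 3L)]
  R
}

#' Per-vertex outward unit normals
#'
#' Area-weighted average of incident face normals (the unnormalized cross
#' product of a triangle's edges has magnitude twice its area, so summing
#' raw cross products is the area weighting), normalized to unit length.
#' Faces are assumed to be wound counter-clockwise seen from outside, as
#' produced by [make_template()].
#'
#' @param config `p x 3` coordinate matrix.
#' @param topo a [template_topology()] supplying the triangulation.
#' @return `p x 3` matrix of unit normals; vertices with no incident face
#'   get a zero row with a warning.
#' @export
vertex_normals <- function(config, topo) {
  check_config(config, topo)
  f <- topo$faces
  e1 <- config[f[, 2L], , drop = FALSE] - config[f[, 1L], , drop = FALSE]
  e2 <- config[f[, 3L], , drop = FALSE] - config[f[, 1L], , drop = FALSE]
  fn <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  idx <- c(f[, 1L], f[, 2L], f[, 3L])
  acc <- rowsum(rbind(fn, fn, fn), group = idx)
  normals <- matrix(0, topo$n_vertices, 3L)
  normals[as.integer(rownames(acc)), ] <- acc
  nr <- row_norms(normals)
  if (any(nr == 0))
    warnf("%d isolated vertices have no incident face; zero normals returned",
          sum(nr == 0))
  ok <- nr > 0
  normals[ok, ] <- normals[ok, , drop = FALSE] / nr[ok]
  normals
}
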