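#' Template topology for dense corresponded configurations
#'
#' A template topology fixes the correspondence scheme shared by every
#' configuration in a study: the number of vertices, the triangulation used
#' for surface normals, and the bilateral symmetry structure (left--right
#' vertex pairing plus the set of midline vertices) together with the
#' coordinate axis across which the template is mirror-symmetric.
#'
#' All vertex indices are 1-based inside R; file interfaces
#' ([read_symmetry_pairs()]) use 0-based indices.
#'
#' @param n_vertices number of template vertices (positive integer).
#' @param faces integer matrix with three columns, one row per triangle
#'   (1-based vertex indices).
#' @param symmetry_pairs two-column integer matrix; each row is a
#'   (left, right) vertex pair swapped by the template's mirror symmetry.
#' @param midline_vertices integer vector of vertices fixed by the mirror
#'   symmetry.
#' @param reflection_axis one of `"x"`, `"y"`, `"z"`: the coordinate axis
#'   flipped by the template's mirror symmetry.
#' @return an object of class `template_topology`.
#' @examples
#' tpl <- make_template(1)
#' tpl$topology
#' @export
template_topology <- function(n_vertices, faces, symmetry_pairs, midline_vertices,
                              reflection_axis = c("x", "y", "z")) {
  reflection_axis <- match.arg(reflection_axis)
  n_vertices <- as.integer(n_vertices)
  if (n_vertices < 1L) stopf("n_vertices must be a positive integer")
  faces <- matrix(as.integer(faces), ncol = 3L)
  symmetry_pairs <- matrix(as.integer(symmetry_pairs), ncol = 2L)
  midline_vertices <- as.integer(midline_vertices)

  if (any(faces < 1L) || any(faces > n_vertices))
    stopf("face indices must lie in 1..n_vertices")
  if (any(faces[, 1L] == faces[, 2L] | faces[, 1L] == faces[, 3L] |
            faces[, 2L] == faces[, 3L]))
    stopf("degenerate faces (repeated vertex index) are not allowed")

  seen <- c(symmetry_pairs[, 1L], symmetry_pairs[, 2L], midline_vertices)
  if (length(seen) != n_vertices || anyDuplicated(seen) ||
        !setequal(seen, seq_len(n_vertices)))
    stopf("every vertex must appear in exactly one symmetry pair or in midline_vertices")

  structure(
    list(n_vertices = n_vertices, faces = faces,
         symmetry_pairs = symmetry_pairs, midline_vertices = midline_vertices,
         reflection_axis = reflection_axis),
    class = "template_topology"
  )
}

#' @export
print.template_topology <- function(x, ...) {
  cat(sprintf(
    "Template topology: %d vertices, %d faces, %d symmetry pairs, %d midline vertices (mirror axis %s)\n",
    x$n_vertices, nrow(x$faces), nrow(x$symmetry_pairs),
    length(x$midline_vertices), x$reflection_axis))
  invisible(x)
}

# permutation that swaps left<->right vertices and fixes the midline
symmetry_permutation <- function(topo) {
  perm <- seq_len(topo$n_vertices)
  perm[topo$symmetry_pairs[, 1L]] <- topo$symmetry_pairs[, 2L]
  perm[topo$symmetry_pairs[, 2L]] <- topo$symmetry_pairs[, 1L]
  perm
}

axis_index <- function(axis) match(axis, c("x", "y", "z"))

check_config <- function(config, topo = NULL, arg = "config") {
  if (!is.matrix(config) || ncol(config) != 3L)
    stopf("%s must be an n x 3 coordinate matrix", arg)
  if (!all(is.finite(config)))
    stopf("%s contains non-finite coordinates", arg)
  if (!is.null(topo) && nrow(config) != topo$n_vertices)
    stopf("%s has %d vertices but the template has %d",
          arg, nrow(config), topo$n_vertices)
  invisible(config)
}
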