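#' Toy head template: a triangulated ellipsoid with exact mirror symmetry
#'
#' Builds a watertight latitude--longitude triangulation of an ellipsoid
#' ("toy head") whose vertex layout is exactly mirror-symmetric across the
#' `x = 0` plane, together with the matching [template_topology()]
#' (left--right vertex pairing and midline set). The x axis is lateral, y
#' anterior--posterior, z vertical. Vertex count grows with `resolution`.
#'
#' @param resolution positive integer; the mesh has `2 + (2r+1) * 4(r+1)`
#'   vertices.
#' @param radii ellipsoid semi-axes (x, y, z) in mm; the defaults give a
#'   head-sized template with centroid size around 85 mm.
#' @return list with `topology` (a [template_topology()]) and `base`
#'   (centered `p x 3` coordinates, mm).
#' @export
make_template <- function(resolution = 2L, radii = c(75, 95, 85)) {
  r <- as.integer(resolution)
  if (r < 1L) stopf("resolution must be >= 1")
  nlat <- 2L * r + 1L            # interior latitude rings
  m <- 4L * (r + 1L)             # longitudes per ring, divisible by 4

  theta <- pi * seq_len(nlat) / (nlat + 1L)
  phi <- 2 * pi * (seq_len(m) - 1L) / m
  ring <- function(i) {
    cbind(radii[1L] * sin(theta[i]) * cos(phi),
          radii[2L] * sin(theta[i]) * sin(phi),
          radii[3L] * cos(theta[i]))
  }
  verts <- rbind(c(0, 0, radii[3L]),
                 do.call(rbind, lapply(seq_len(nlat), ring)),
                 c(0, 0, -radii[3L]))
  p <- nrow(verts)
  # vertex ids: 1 = north pole, rings row-major, p = south pole
  vid <- function(i, j) 1L + (i - 1L) * m + ((j - 1L) %% m) + 1L

  faces <- list()
  for (j in seq_len(m)) # north fan
    faces[[length(faces) + 1L]] <- c(1L, vid(1L, j), vid(1L, j + 1L))
  for (i in seq_len(nlat - 1L)) for (j in seq_len(m)) { # quad strips
    a <- vid(i, j); b <- vid(i, j + 1L)
    c2 <- vid(i + 1L, j); d <- vid(i + 1L, j + 1L)
    faces[[length(faces) + 1L]] <- c(a, c2, b)
    faces[[length(faces) + 1L]] <- c(b, c2, d)
  }
  for (j in seq_len(m)) # south fan
    faces[[length(faces) + 1L]] <- c(p, vid(nlat, j + 1L), vid(nlat, j))
  faces <- do.call(rbind, faces)

  # enforce outward winding (centered convex-ish mesh: normal . centroid > 0)
  v1 <- verts[faces[, 1L], ]; v2 <- verts[faces[, 2L], ]; v3 <- verts[faces[, 3L], ]
  e1 <- v2 - v1; e2 <- v3 - v1
  fn <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  flip <- rowSums(fn * (v1 + v2 + v3) / 3) < 0
  faces[flip, c(2L, 3L)] <- faces[flip, c(3L, 2L)]

  # mirror x -> -x maps longitude j to (m/2 - j + 1) mod m + 1 in 1-based ids
  midline <- c(1L, p)
  pairs <- list()
  for (i in seq_len(nlat)) for (j in seq_len(m)) {
    xj <- verts[vid(i, j), 1L]
    if (abs(xj) < 1e-9) midline <- c(midline, vid(i, j))
    else if (xj > 0) {
      jr <- ((m / 2L - (j - 1L)) %% m) + 1L
      pairs[[length(pairs) + 1L]] <- c(vid(i, j), vid(i, jr))
    }
  }
  topo <- template_topology(p, faces, do.call(rbind, pairs), midline, "x")
  list(topology = topo, base = verts)
}

#' Synthetic growth scenario specification
#'
#' Defines a two-group cross-sectional study with known ground truth on a
#' toy template. Both groups follow smooth per-vertex mean trajectories
#' built from a baseline growth field `V` (radial directions whose
#' magnitude varies smoothly over the surface, mean length about
#' 1 mm/year):
#'
#' * `"null"` — both groups share the trajectory `X0 + a V`.
#' * `"rate"` — group B grows along the same directions at 1.5 times the
#'   rate (`X0 + 1.5 a V`): a pure growth-rate difference.
#' * `"direction"` — group B's growth vectors are rotated by 45 degrees
#'   about the local radial axis: a pure growth-direction difference.
#' * `"pubertal"` — identical until age 12, after which group B gains an
#'   extra `0.5 V (a - 12)` component: a difference emerging at puberty.
#' * `"separated"` — group B's trajectory is offset by a fixed shape-space
#'   vector of norm `separation` times the noise sd: a constant, fully
#'   age-stable group difference used for classifier power checks.
#'
#' Cases get i.i.d. isotropic Gaussian vertex noise and, optionally, random
#' nuisance similarity transforms (rotation/translation/scale) that a GPA
#' must remove.
#'
#' @param template a [make_template()] result.
#' @param type scenario name (see Details).
#' @param noise_sd per-coordinate noise sd in mm; default 2% of the
#'   template's centroid size.
#' @param rate_factor group-B rate multiplier for `"rate"` (default 1.5).
#' @param angle group-B direction rotation in degrees for `"direction"`
#'   (default 45).
#' @param onset_age emergence age for `"pubertal"` (default 12).
#' @param separation offset norm in noise-sd units for `"separated"`
#'   (default 10).
#' @param nuisance list with `rotation` (max angle, degrees), `translation`
#'   (max abs per axis, mm) and `scale` (c(lo, hi) factor range); `NULL`
#'   disables nuisance transforms.
#' @param age_range ages are drawn uniformly on this interval (years).
#' @return object of class `trajectory_spec` with callable `mean_fn(group,
#'   a)` and `field_fn(group, a)` (both centered).
#' @export
growth_scenario <- function(template,
                            type = c("null", "rate", "direction", "pubertal",
                                     "separated"),
                            noise_sd = NULL, rate_factor = 1.5, angle = 45,
                            onset_age = 12, separation = 10,
                            nuisance = list(rotation = 20, translation = 20,
                                            scale = NULL),
                            age_range = c(0.5, 18.5)) {
  type <- match.arg(type)
  base <- center_config(template$base)
  p <- nrow(base)
  if (is.null(noise_sd)) noise_sd <- 0.02 * centroid_size(base)

  # baseline field: radial directions, magnitude graded along z (mean ~1 mm/y).
  # Fields are kept exactly as constructed; mean configurations are centered
  # per age, so the centered-frame truth field is the field minus its column
  # means (see true_growth_field(frame = "centered")).
  u <- base / row_norms(base)
  g <- 0.6 + 0.8 * (base[, 3L] - min(base[, 3L])) /
    (max(base[, 3L]) - min(base[, 3L]))
  V <- u * g

  VB <- switch(type,
    null = V,
    rate = rate_factor * V,
    direction = {
      # tilt each (radial) growth vector about a local tangent axis: the
      # groups' vectors differ in direction by exactly `angle`, with equal
      # magnitudes
      t(vapply(seq_len(p), function(i) {
        t_ax <- c(u[i, 2L], -u[i, 1L], 0)
        if (sum(t_ax^2) < 1e-12) t_ax <- c(1, 0, 0) # poles: any tangent works
        as.vector(rotation_about_axis(t_ax, angle * pi / 180) %*% V[i, ])
      }, numeric(3L)))
    },
    pubertal = V,   # handled in mean_fn via onset
    separated = V)
  offset <- if (type == "separated") {
    # constant centered group offset, orthogonalized against the centered
    # growth field so the group contrast is not confounded with age
    d0 <- u * sin(2 * pi * (base[, 3L] - min(base[, 3L])) /
                    (max(base[, 3L]) - min(base[, 3L])))
    d0 <- sweep(d0, 2L, colMeans(d0), "-")
    pv <- sweep(V, 2L, colMeans(V), "-")
    d0 <- d0 - pv * sum(d0 * pv) / sum(pv * pv)
    d0 / sqrt(sum(d0^2)) * separation * noise_sd
  } else matrix(0, p, 3L)
  extra <- if (type == "pubertal") 0.5 * V else matrix(0, p, 3L)

  mean_fn <- function(group, a) {
    if (group == "A") center_config(base + a * V)
    else center_config(base + a * VB + offset + max(0, a - onset_age) * extra)
  }
  field_fn <- function(group, a) {
    if (group == "A") V
    else VB + (a > onset_age) * extra
  }
  structure(
    list(type = type, template = template, noise_sd = noise_sd,
         nuisance = nuisance, age_range = age_range, mean_fn = mean_fn,
         field_fn = field_fn, rate_factor = rate_factor, angle = angle,
         onset_age = onset_age, separation = separation),
    class = "trajectory_spec")
}

#' Simulate a cross-sectional two-group cohort
#'
#' Draws ages, evaluates the scenario's group mean trajectory, adds
#' isotropic per-vertex Gaussian noise and applies per-case nuisance
#' similarity transforms. Cohorts generated without nuisance transforms are
#' marked `aligned` (the generating means are centered and share one
#' frame); cohorts with nuisance transforms must be aligned with [gpa()].
#'
#' @param spec a [growth_scenario()].
#' @param n_per_group cases per group.
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @return a [cohort()] with groups `"A"`/`"B"` and attribute `"truth"`: a
#'   list with the spec and the drawn ages/groups (the exact generating
#'   means and analytic growth fields are recoverable through
#'   `spec$mean_fn` / [true_growth_field()]).
#' @export
simulate_cohort <- function(spec, n_per_group, seed = 1L) {
  stopifnot(inherits(spec, "trajectory_spec"))
  if (n_per_group < 1L) stopf("n_per_group must be >= 1")
  set.seed(seed)
  p <- nrow(spec$template$base)
  n <- 2L * n_per_group
  ages <- stats::runif(n, spec$age_range[1L], spec$age_range[2L])
  groups <- rep(c("A", "B"), each = n_per_group)
  has_nuisance <- !is.null(spec$nuisance) &&
    (!is.null(spec$nuisance$rotation) || !is.null(spec$nuisance$translation) ||
       !is.null(spec$nuisance$scale))
  coords <- array(0, c(p, 3L, n))
  for (i in seq_len(n)) {
    xi <- spec$mean_fn(groups[i], ages[i]) +
      matrix(stats::rnorm(3L * p, sd = spec$noise_sd), p, 3L)
    if (has_nuisance) {
      nu <- spec$nuisance
      if (!is.null(nu$rotation) && nu$rotation > 0)
        xi <- xi %*% random_rotation(nu$rotation * pi / 180)
      if (!is.null(nu$scale))
        xi <- xi * stats::runif(1L, nu$scale[1L], nu$scale[2L])
      if (!is.null(nu$translation) && nu$translation > 0)
        xi <- sweep(xi, 2L, stats::runif(3L, -nu$translation, nu$translation), "+")
    }
    coords[, , i] <- xi
  }
  out <- cohort(coords, ages, groups,
                ids = sprintf("%s%04d", groups, seq_len(n)),
                aligned = !has_nuisance, scaled = FALSE,
                template = spec$template$topology)
  attr(out, "truth") <- list(spec = spec, ages = ages, groups = groups,
                             seed = seed)
  out
}

#' Analytic growth field of a scenario
#'
#' The exact derivative of the scenario's group mean trajectory at age
#' `a` — the ground-truth growth vector field against which estimated
#' fields can be checked. `frame = "analytic"` returns the raw per-vertex
#' construction (exact rates, angles and ratios); `frame = "centered"`
#' removes the field's mean vector, i.e. the derivative of the *centered*
#' mean trajectory, which is what models fitted to centered configurations
#' estimate.
#'
#' @param spec a [growth_scenario()].
#' @param group `"A"` or `"B"`.
#' @param a age in years (inside the scenario's age range).
#' @param frame `"analytic"` or `"centered"` (see Description).
#' @return `p x 3` matrix of class `growth_field`.
#' @export
true_growth_field <- function(spec, group, a,
                              frame = c("analytic", "centered")) {
  stopifnot(inherits(spec, "trajectory_spec"))
  frame <- match.arg(frame)
  if (a < spec$age_range[1L] || a > spec$age_range[2L])
    stopf("age %.3g outside the scenario age range", a)
  f <- spec$field_fn(group, a)
  if (frame == "centered") f <- sweep(f, 2L, colMeans(f), "-")
  structure(f, age = a, class = c("growth_field", "matrix", "array"))
}
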