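# shared fixtures: all built in code at test time

tpl1 <- make_template(1L)                      # 26-vertex toy head
tpl_sphere <- make_template(2L, radii = c(80, 80, 80))

# minimal 2-vertex template: one symmetry pair, no faces
tiny_pair_topo <- template_topology(
  2L, matrix(integer(), ncol = 3L), symmetry_pairs = rbind(c(1L, 2L)),
  midline_vertices = integer(), reflection_axis = "x")

random_config <- function(p = 10L, scale = 10) {
  matrix(stats::rnorm(3L * p, sd = scale), p, 3L)
}

# similarity-transformed copy of a configuration
transform_config <- function(x, rotate = TRUE, translate = TRUE, scale = 1) {
  y <- x * scale
  if (rotate) y <- y %*% morphotraj:::random_rotation(pi)
  if (translate) y <- sweep(y, 2L, stats::runif(3L, -20, 20), "+")
  y
}

# small aligned two-group cohort on tpl1 (no nuisance transforms)
small_cohort <- function(type = "null", n_per_group = 40L, seed = 1L, ...) {
  spec <- growth_scenario(tpl1, type, nuisance = NULL, ...)
  simulate_cohort(spec, n_per_group, seed = seed)
}
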