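#' Read a cohort from a metadata CSV and mesh files
#'
#' The metadata CSV must have the header `id,age,group,path` (age in
#' decimal years; group one of exactly two strings; path to a PLY/OBJ mesh,
#' relative paths resolved against the CSV's directory). Every mesh must
#' match the template's vertex count; the physical centroid size of each
#' case is recorded before any scaling.
#'
#' @param meta_csv path to the metadata CSV.
#' @param template a [template_topology()].
#' @param base_dir directory against which relative mesh paths are
#'   resolved; defaults to the CSV's directory.
#' @return an unaligned [cohort()].
#' @export
read_cohort <- function(meta_csv, template, base_dir = dirname(meta_csv)) {
  meta <- utils::read.csv(meta_csv, stringsAsFactors = FALSE)
  need <- c("id", "age", "group", "path")
  if (!all(need %in% names(meta)))
    stopf("metadata CSV must have columns %s", paste(need, collapse = ", "))
  ages <- suppressWarnings(as.numeric(meta$age))
  bad <- which(!is.finite(ages) | ages <= 0)
  if (length(bad))
    stopf("row %d (id '%s'): unparseable or non-positive age '%s'",
          bad[1L], meta$id[bad[1L]], meta$age[bad[1L]])
  if (anyDuplicated(meta$id))
    stopf("duplicate id '%s'", meta$id[duplicated(meta$id)][1L])
  groups <- unique(meta$group)
  if (length(groups) != 2L)
    stopf("metadata must contain exactly two group labels (found %d: %s)",
          length(groups), paste(groups, collapse = ", "))

  n <- nrow(meta)
  coords <- array(NA_real_, c(template$n_vertices, 3L, n))
  for (i in seq_len(n)) {
    path <- meta$path[i]
    if (!file.exists(path)) path <- file.path(base_dir, meta$path[i])
    if (!file.exists(path))
      stopf("row %d (id '%s'): mesh file '%s' not found", i, meta$id[i],
            meta$path[i])
    mesh <- read_mesh(path)
    if (nrow(mesh$vertices) != template$n_vertices)
      stopf("row %d (id '%s'): mesh '%s' has %d vertices, template expects %d",
            i, meta$id[i], meta$path[i], nrow(mesh$vertices),
            template$n_vertices)
    coords[, , i] <- mesh$vertices
  }
  cohort(coords, ages, meta$group, ids = meta$id, aligned = FALSE,
         scaled = FALSE, template = template)
}

#' Write analysis outputs with a checksum manifest
#'
#' Writes each element of a named results list under `out_dir` —
#' data.frames/matrices as CSV, other lists as JSON — and a
#' `manifest.json` listing every artifact with its MD5 checksum. Output is
#' deterministic: rerunning with the same inputs reproduces identical
#' bytes.
#'
#' @param results named list of data.frames, matrices, or JSON-serializable
#'   lists; an empty list yields a manifest with zero artifacts.
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly (list of file/md5 records).
#' @export
write_outputs <- function(results, out_dir) {
  if (length(results) && (is.null(names(results)) || any(names(results) == "")))
    stopf("results must be a named list")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory '%s'", out_dir)
  files <- character()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x) || is.matrix(x)) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(as.data.frame(x), f, row.names = FALSE)
    } else {
      f <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    files <- c(files, f)
  }
  manifest <- lapply(files, function(f)
    list(file = basename(f), md5 = unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Resolved run configuration
#'
#' Collects every tunable of the pipeline with its standard default:
#' kernel widths 2.75 y (shape) and 0.75 y (size), 10,000 permutations and
#' bootstrap replicates, 10-fold cross-validation with 100 repetitions,
#' kernel support-balance threshold 0.4, age brackets 0/5/10/15/20, and
#' the age-grid step 0.01 y. Values can be overridden from a YAML file
#' and/or explicit arguments (arguments win). Every run should write the
#' resolved configuration beside its outputs (see [write_outputs()]).
#'
#' @param config_yaml optional YAML file of overrides.
#' @param ... explicit overrides of individual fields.
#' @return named list of class `run_config`.
#' @export
run_config <- function(config_yaml = NULL, ...) {
  defaults <- list(
    width_shape = 2.75, width_size = 0.75,
    n_perm = 10000L, n_boot = 10000L,
    k = 10L, repetitions = 100L,
    support_threshold = 0.4,
    brackets = c(0, 5, 10, 15, 20),
    grid_step = 0.01,
    seed = 1L,
    scale_in_gpa = TRUE)
  cfg <- defaults
  if (!is.null(config_yaml)) {
    over <- yaml::read_yaml(config_yaml)
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown))
      stopf("unknown config fields: %s", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown))
    stopf("unknown config fields: %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}
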