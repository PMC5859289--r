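#' Cross-sectional cohort of corresponded configurations
#'
#' A cohort bundles the corresponded landmark configurations of a
#' cross-sectional sample with per-case metadata: decimal age in years, a
#' binary group label, the physical centroid size (mm) recorded before any
#' scaling, and a case id. Flags record whether the configurations are in a
#' common Procrustes frame (`aligned`) and whether they were scaled to unit
#' centroid size (`scaled`).
#'
#' @param coords numeric array `p x 3 x n` of vertex coordinates.
#' @param ages numeric vector of positive decimal ages (years).
#' @param groups vector coercible to a factor with exactly two levels.
#' @param sizes physical centroid sizes in mm; computed from `coords` when
#'   omitted.
#' @param ids case identifiers (unique); generated when omitted.
#' @param aligned,scaled logical flags (see Description).
#' @param template optional [template_topology()].
#' @return an object of class `cohort`.
#' @seealso [gpa()], [simulate_cohort()], [read_cohort()]
#' @export
cohort <- function(coords, ages, groups, sizes = NULL, ids = NULL,
                   aligned = FALSE, scaled = FALSE, template = NULL) {
  if (length(dim(coords)) != 3L || dim(coords)[2L] != 3L)
    stopf("coords must be a p x 3 x n array")
  n <- dim(coords)[3L]
  ages <- as.numeric(ages)
  groups <- factor(groups)
  if (nlevels(groups) != 2L)
    stopf("groups must have exactly two distinct labels (found %d)", nlevels(groups))
  if (is.null(sizes))
    sizes <- apply(coords, 3L, centroid_size)
  if (is.null(ids))
    ids <- sprintf("case%04d", seq_len(n))
  ids <- as.character(ids)
  if (length(ages) != n || length(groups) != n || length(sizes) != n ||
        length(ids) != n)
    stopf("coords (n = %d), ages, groups, sizes and ids must agree in length", n)
  if (any(!is.finite(ages)) || any(ages <= 0))
    stopf("ages must be positive and finite")
  if (anyDuplicated(ids))
    stopf("duplicate case ids: %s", paste(ids[duplicated(ids)], collapse = ", "))
  if (!all(is.finite(coords)))
    stopf("coords contain non-finite values")
  obj <- structure(
    list(coords = coords, ages = ages, groups = groups, sizes = as.numeric(sizes),
         ids = ids, aligned = isTRUE(aligned), scaled = isTRUE(scaled),
         consensus = NULL, template = template),
    class = "cohort"
  )
  validate_cohort(obj)
  obj
}

validate_cohort <- function(x) {
  if (x$aligned && x$scaled) {
    cents <- apply(x$coords, 3L, function(m) max(abs(colMeans(m))))
    szs <- apply(x$coords, 3L, centroid_size)
    if (max(cents) > 1e-9 || max(abs(szs - 1)) > 1e-9)
      stopf("aligned+scaled cohort must have centered, unit-size configurations")
  }
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf(
    "Cohort: %d cases (%s), %d vertices, ages %.2f-%.2f y%s%s\n",
    length(x$ages),
    paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
    dim(x$coords)[1L], min(x$ages), max(x$ages),
    if (x$aligned) ", aligned" else "",
    if (x$scaled) ", unit-scaled" else ""))
  invisible(x)
}

#' Number of cases in a cohort
#' @param x a [cohort()].
#' @export
length.cohort <- function(x) dim(x$coords)[3L]

#' Flattened configuration matrix of a cohort
#'
#' Returns the `n x 3p` matrix whose rows are flattened configurations
#' (all x-, then y-, then z-coordinates), the representation used by the
#' trajectory regressions.
#'
#' @param x a [cohort()].
#' @param ... unused.
#' @export
as.matrix.cohort <- function(x, ...) {
  m <- flatten_configs(x$coords)
  rownames(m) <- x$ids
  m
}

#' Subset a cohort by case
#' @param x a [cohort()].
#' @param i index vector of cases to keep.
#' @export
`[.cohort` <- function(x, i) {
  idx <- seq_along(x$ages)[i]
  out <- x
  out$coords <- x$coords[, , idx, drop = FALSE]
  out$ages <- x$ages[idx]
  out$groups <- factor(x$groups[idx], levels = levels(x$groups))
  out$sizes <- x$sizes[idx]
  out$ids <- x$ids[idx]
  out
}
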