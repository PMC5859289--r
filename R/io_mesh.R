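#' Read a PLY mesh
#'
#' Reads ASCII and binary little-endian PLY files. Vertex order defines the
#' landmark correspondence, so it is preserved exactly. Additional per-vertex
#' scalar properties (e.g. difference maps written by [write_ply()]) are
#' returned alongside the coordinates. Binary support covers the common
#' layout: float32 vertex properties and uchar/int32 face lists.
#'
#' @param path file path.
#' @return list with `vertices` (`p x 3`), `faces` (`F x 3`, 1-based; `NULL`
#'   when absent) and `properties` (named list of extra per-vertex
#'   numeric vectors).
#' @export
read_ply <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  hdr_hit <- grepRaw("end_header", raw, fixed = TRUE)
  if (length(hdr_hit) == 0L) stopf("%s is not a PLY file (no header)", path)
  nl <- hdr_hit + 10L
  while (nl <= length(raw) && raw[nl] != as.raw(10L)) nl <- nl + 1L
  header <- strsplit(rawToChar(raw[seq_len(hdr_hit - 1L)]), "\r?\n")[[1L]]
  body <- raw[seq.int(nl + 1L, length(raw))]
  if (!identical(trimws(header[1L]), "ply")) stopf("%s is not a PLY file", path)

  fmt <- NULL
  elements <- list(); cur <- NULL
  for (line in header[-1L]) {
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(tok) == 0L || tok[1L] == "comment") next
    if (tok[1L] == "format") fmt <- tok[2L]
    else if (tok[1L] == "element") {
      cur <- tok[2L]
      elements[[cur]] <- list(count = as.integer(tok[3L]), props = list())
    } else if (tok[1L] == "property") {
      if (tok[2L] == "list")
        elements[[cur]]$props[[tok[5L]]] <- list(list = TRUE,
                                                 count_type = tok[3L],
                                                 item_type = tok[4L])
      else
        elements[[cur]]$props[[tok[3L]]] <- list(list = FALSE, type = tok[2L])
    }
  }
  if (is.null(elements$vertex)) stopf("PLY file %s has no vertex element", path)

  if (fmt == "ascii") {
    con <- textConnection(rawToChar(body))
    on.exit(close(con))
    out <- read_ply_ascii(con, elements)
  } else if (fmt == "binary_little_endian") {
    con <- rawConnection(body)
    on.exit(close(con))
    out <- read_ply_binary(con, elements, path)
  } else stopf("unsupported PLY format '%s' in %s", fmt, path)

  vp <- out$vertex
  need <- c("x", "y", "z")
  if (!all(need %in% names(vp))) stopf("PLY vertex element must have x, y, z")
  vertices <- cbind(vp$x, vp$y, vp$z)
  props <- vp[setdiff(names(vp), need)]
  faces <- out$faces
  list(vertices = vertices, faces = faces,
       properties = if (length(props)) props else list())
}

read_ply_ascii <- function(con, elements) {
  vertex <- elements$vertex
  nv <- vertex$count
  npr <- length(vertex$props)
  vals <- scan(con, what = numeric(), n = nv * npr, quiet = TRUE)
  vm <- matrix(vals, nrow = nv, ncol = npr, byrow = TRUE)
  vp <- stats::setNames(lapply(seq_len(npr), function(j) vm[, j]),
                        names(vertex$props))
  faces <- NULL
  if (!is.null(elements$face) && elements$face$count > 0L) {
    nf <- elements$face$count
    fv <- scan(con, what = integer(), n = 4L * nf, quiet = TRUE)
    fm <- matrix(fv, nrow = nf, ncol = 4L, byrow = TRUE)
    if (any(fm[, 1L] != 3L)) stopf("only triangular faces are supported")
    faces <- fm[, 2:4, drop = FALSE] + 1L
  }
  list(vertex = vp, faces = faces)
}

ply_type_size <- function(t) {
  switch(t, char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
         short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
         int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
         float = 4L, float32 = 4L, double = 8L, float64 = 8L,
         stopf("unknown PLY type '%s'", t))
}

read_ply_binary <- function(con, elements, path) {
  vertex <- elements$vertex
  types <- vapply(vertex$props, function(p) p$type, character(1L))
  if (!all(types %in% c("float", "float32")))
    stopf("binary PLY support in %s is limited to float32 vertex properties", path)
  nv <- vertex$count
  npr <- length(types)
  raw_vals <- readBin(con, what = "numeric", n = nv * npr, size = 4L,
                      endian = "little")
  vm <- matrix(raw_vals, nrow = nv, ncol = npr, byrow = TRUE)
  vp <- stats::setNames(lapply(seq_len(npr), function(j) vm[, j]),
                        names(vertex$props))
  faces <- NULL
  if (!is.null(elements$face) && elements$face$count > 0L) {
    lp <- elements$face$props[[1L]]
    if (!lp$list || ply_type_size(lp$count_type) != 1L ||
          ply_type_size(lp$item_type) != 4L)
      stopf("binary PLY face lists in %s must be uchar count + int32 indices", path)
    nf <- elements$face$count
    faces <- matrix(NA_integer_, nf, 3L)
    for (i in seq_len(nf)) {
      cnt <- readBin(con, "integer", 1L, size = 1L, signed = FALSE)
      idx <- readBin(con, "integer", cnt, size = 4L, endian = "little")
      if (cnt != 3L) stopf("only triangular faces are supported")
      faces[i, ] <- idx + 1L
    }
  }
  list(vertex = vp, faces = faces)
}

#' Write an ASCII PLY mesh
#'
#' Writes vertices (preserving order, i.e. correspondence), optional
#' triangular faces (0-based in the file) and optional named per-vertex
#' scalar properties, e.g. the difference maps `diff_normal`, `diff_x`,
#' `diff_y`, `diff_z`, `rate_diff`, `dir_angle`.
#'
#' @param vertices `p x 3` coordinate matrix.
#' @param path output file path.
#' @param faces optional `F x 3` 1-based triangle matrix.
#' @param properties optional named list of numeric vectors of length `p`.
#' @return `path`, invisibly.
#' @export
write_ply <- function(vertices, path, faces = NULL, properties = NULL) {
  check_config(vertices, arg = "vertices")
  p <- nrow(vertices)
  if (!is.null(properties)) {
    if (is.null(names(properties)) || any(names(properties) == ""))
      stopf("vertex properties must be named")
    for (nm in names(properties))
      if (length(properties[[nm]]) != p)
        stopf("property '%s' must have one value per vertex", nm)
  }
  lines <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", p),
             "property float x", "property float y", "property float z",
             sprintf("property double %s", names(properties)),
             if (!is.null(faces)) sprintf("element face %d", nrow(faces)),
             if (!is.null(faces)) "property list uchar int vertex_indices",
             "end_header")
  vm <- if (is.null(properties)) vertices
        else cbind(vertices, do.call(cbind, properties))
  vtxt <- apply(vm, 1L, function(r) paste(sprintf("%.9g", r), collapse = " "))
  ftxt <- if (!is.null(faces))
    paste("3", faces[, 1L] - 1L, faces[, 2L] - 1L, faces[, 3L] - 1L)
  writeLines(c(lines, vtxt, ftxt), path)
  invisible(path)
}

#' Read an OBJ mesh
#'
#' Parses `v` and `f` records (texture/normal indices after `/` are
#' ignored). Vertex order is preserved.
#'
#' @param path file path.
#' @return list with `vertices` and `faces` (1-based; `NULL` when absent).
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0L) stopf("%s has no vertices", path)
  vertices <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vlines)), "\\s+"),
                                    function(x) as.numeric(x[1:3])))
  faces <- NULL
  if (length(flines)) {
    faces <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", flines)), "\\s+"),
      function(x) {
        idx <- as.integer(vapply(strsplit(x, "/"), `[[`, character(1L), 1L))
        if (length(idx) != 3L) stopf("only triangular faces are supported")
        idx
      }))
  }
  list(vertices = vertices, faces = faces, properties = list())
}

#' Write an OBJ mesh
#' @param vertices `p x 3` coordinate matrix.
#' @param path output file path.
#' @param faces optional `F x 3` 1-based triangle matrix.
#' @return `path`, invisibly.
#' @export
write_obj <- function(vertices, path, faces = NULL) {
  check_config(vertices, arg = "vertices")
  vtxt <- apply(vertices, 1L, function(r)
    paste("v", paste(sprintf("%.9g", r), collapse = " ")))
  ftxt <- if (!is.null(faces))
    paste("f", faces[, 1L], faces[, 2L], faces[, 3L])
  writeLines(c(vtxt, ftxt), path)
  invisible(path)
}

#' Read a mesh by extension
#' @param path `.ply` or `.obj` file.
#' @return as [read_ply()] / [read_obj()].
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, ply = read_ply(path), obj = read_obj(path),
         stopf("unsupported mesh format '.%s' (%s)", ext, path))
}

#' Read a symmetry-pair table
#'
#' Two-column CSV of 0-based (left, right) vertex indices, as exchanged
#' with external tools; converted to 1-based on read.
#'
#' @param path CSV path.
#' @return two-column integer matrix, 1-based.
#' @export
read_symmetry_pairs <- function(path) {
  tab <- utils::read.csv(path, header = FALSE)
  as.matrix(tab[, 1:2]) + 1L
}

#' Read a midline-vertex list
#'
#' One-column CSV of 0-based vertex indices; converted to 1-based.
#'
#' @param path CSV path.
#' @return integer vector, 1-based.
#' @export
read_midline <- function(path) {
  as.integer(utils::read.csv(path, header = FALSE)[, 1L]) + 1L
}
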