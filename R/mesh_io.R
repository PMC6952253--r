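#' Read a tetrahedral mesh
#'
#' Supported dialects: TetGen ASCII node/element pairs (`format = "tetgen"`,
#' `path` is the `.node` file or the common stem; indices 1-based on disk)
#' and legacy ASCII VTK unstructured grids containing only tetrahedra
#' (`format = "vtk_legacy"`, cell type 10). Indices are converted to the
#' internal 1-based R convention and inverted tetrahedra are reordered to
#' positive volume.
#'
#' @param path file path (for TetGen, the `.node` file or the stem shared by
#'   `.node`/`.ele`).
#' @param format `"tetgen"` or `"vtk_legacy"`; guessed from the extension
#'   when `NULL`.
#' @param node_sets optional named list of node-index sets to attach.
#' @return A [tet_mesh()].
#' @export
load_tet_mesh <- function(path, format = NULL, node_sets = list()) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, node = , ele = "tetgen", vtk = "vtk_legacy",
                     stopf("cannot guess mesh format from extension '%s'", ext))
  }
  format <- match.arg(format, c("tetgen", "vtk_legacy"))
  switch(format,
         tetgen = read_tetgen(path, node_sets),
         vtk_legacy = read_vtk_legacy(path, node_sets))
}

split_fields <- function(line) strsplit(trimws(line), "[[:space:]]+")[[1]]

# drop blank lines and TetGen '#' comments, keeping original line numbers
content_lines <- function(path) {
  raw <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", raw)
  keep <- which(nzchar(trimws(txt)))
  list(text = txt[keep], lineno = keep)
}

parse_numeric_fields <- function(fields, path, lineno) {
  vals <- suppressWarnings(as.numeric(fields))
  if (anyNA(vals))
    stopf("parse error in '%s' at line %d: non-numeric field", path, lineno)
  vals
}

read_tetgen <- function(path, node_sets = list()) {
  stem <- sub("\\.(node|ele)$", "", path)
  node_path <- paste0(stem, ".node")
  ele_path <- paste0(stem, ".ele")
  if (!file.exists(node_path)) stopf("TetGen node file not found: %s", node_path)
  if (!file.exists(ele_path)) stopf("TetGen element file not found: %s", ele_path)

  nl <- content_lines(node_path)
  hdr <- parse_numeric_fields(split_fields(nl$text[1L]), node_path, nl$lineno[1L])
  n_nodes <- as.integer(hdr[1L])
  if (length(nl$text) < n_nodes + 1L)
    stopf("parse error in '%s': expected %d node lines", node_path, n_nodes)
  nodes <- matrix(0, n_nodes, 3L)
  ids <- integer(n_nodes)
  for (i in seq_len(n_nodes)) {
    f <- parse_numeric_fields(split_fields(nl$text[i + 1L]), node_path,
                              nl$lineno[i + 1L])
    if (length(f) < 4L)
      stopf("parse error in '%s' at line %d: expected index + 3 coordinates",
            node_path, nl$lineno[i + 1L])
    ids[i] <- as.integer(f[1L])
    nodes[i, ] <- f[2:4]
  }
  first_index <- min(ids)
  if (!first_index %in% c(0L, 1L))
    stopf("parse error in '%s': node numbering must start at 0 or 1", node_path)

  el <- content_lines(ele_path)
  ehdr <- parse_numeric_fields(split_fields(el$text[1L]), ele_path, el$lineno[1L])
  n_tets <- as.integer(ehdr[1L])
  npt <- if (length(ehdr) >= 2L) as.integer(ehdr[2L]) else 4L
  if (npt != 4L)
    stopf("parse error in '%s': only 4-node tetrahedra supported (got %d nodes/cell)",
          ele_path, npt)
  if (length(el$text) < n_tets + 1L)
    stopf("parse error in '%s': expected %d element lines", ele_path, n_tets)
  tets <- matrix(0L, n_tets, 4L)
  for (i in seq_len(n_tets)) {
    f <- parse_numeric_fields(split_fields(el$text[i + 1L]), ele_path,
                              el$lineno[i + 1L])
    if (length(f) < 5L)
      stopf("parse error in '%s' at line %d: expected index + 4 node ids",
            ele_path, el$lineno[i + 1L])
    ix <- as.integer(f[2:5]) - first_index + 1L
    if (any(ix < 1L) || any(ix > n_nodes))
      stopf("parse error in '%s' at line %d: node index out of range [%d, %d]",
            ele_path, el$lineno[i + 1L], first_index, first_index + n_nodes - 1L)
    tets[i, ] <- ix
  }
  tet_mesh(nodes, tets, node_sets)
}

read_vtk_legacy <- function(path, node_sets = list()) {
  if (!file.exists(path)) stopf("VTK file not found: %s", path)
  raw <- readLines(path, warn = FALSE)
  up <- toupper(raw)
  if (!any(grepl("DATASET\\s+UNSTRUCTURED_GRID", up)))
    stopf("parse error in '%s': not an ASCII unstructured grid", path)

  # token stream with line provenance
  toks <- character(0); tok_line <- integer(0)
  for (i in seq_along(raw)) {
    f <- split_fields(raw[i])
    if (length(f)) { toks <- c(toks, f); tok_line <- c(tok_line, rep(i, length(f))) }
  }
  tu <- toupper(toks)

  ipts <- match("POINTS", tu)
  if (is.na(ipts)) stopf("parse error in '%s': no POINTS section", path)
  n_nodes <- as.integer(toks[ipts + 1L])
  coords <- suppressWarnings(as.numeric(toks[(ipts + 3L):(ipts + 2L + 3L * n_nodes)]))
  if (anyNA(coords))
    stopf("parse error in '%s' at line %d: bad point coordinates",
          path, tok_line[ipts + 3L])
  nodes <- matrix(coords, n_nodes, 3L, byrow = TRUE)

  icel <- match("CELLS", tu)
  if (is.na(icel)) stopf("parse error in '%s': no CELLS section", path)
  n_cells <- as.integer(toks[icel + 1L])
  total <- as.integer(toks[icel + 2L])
  cell_data <- suppressWarnings(as.integer(toks[(icel + 3L):(icel + 2L + total)]))
  if (anyNA(cell_data))
    stopf("parse error in '%s' at line %d: bad cell connectivity",
          path, tok_line[icel + 3L])

  ityp <- match("CELL_TYPES", tu)
  if (is.na(ityp)) stopf("parse error in '%s': no CELL_TYPES section", path)
  types <- as.integer(toks[(ityp + 2L):(ityp + 1L + n_cells)])
  if (any(types != 10L))
    stopf("unsupported cell type(s) %s in '%s': only tetrahedra (type 10)",
          paste(unique(types[types != 10L]), collapse = ", "), path)

  tets <- matrix(0L, n_cells, 4L)
  pos <- 1L
  for (i in seq_len(n_cells)) {
    cnt <- cell_data[pos]
    if (cnt != 4L)
      stopf("parse error in '%s': cell %d has %d points, expected 4", path, i, cnt)
    ix <- cell_data[(pos + 1L):(pos + 4L)] + 1L  # VTK is 0-based
    if (any(ix < 1L) || any(ix > n_nodes))
      stopf("parse error in '%s': cell %d node index out of range", path, i)
    tets[i, ] <- ix
    pos <- pos + 5L
  }
  tet_mesh(nodes, tets, node_sets)
}

#' Write a tetrahedral mesh
#'
#' Writes TetGen `.node`/`.ele` pairs (1-based indices) or a legacy ASCII
#' VTK unstructured grid (0-based, cell type 10). Coordinates are written
#' with 17 significant digits so a write/read round trip is lossless.
#'
#' @param mesh a [tet_mesh()].
#' @param path output path; for TetGen, the stem or `.node` path.
#' @param format `"tetgen"` or `"vtk_legacy"`.
#' @return `path`, invisibly.
#' @export
write_tet_mesh <- function(mesh, path, format = c("tetgen", "vtk_legacy")) {
  stopifnot(inherits(mesh, "tet_mesh"))
  format <- match.arg(format)
  fmt <- function(x) sprintf("%.17g", x)
  if (format == "tetgen") {
    stem <- sub("\\.(node|ele)$", "", path)
    n <- nrow(mesh$nodes)
    node_lines <- c(sprintf("%d 3 0 0", n),
                    sprintf("%d %s %s %s", seq_len(n), fmt(mesh$nodes[, 1L]),
                            fmt(mesh$nodes[, 2L]), fmt(mesh$nodes[, 3L])))
    writeLines(node_lines, paste0(stem, ".node"))
    m <- nrow(mesh$tets)
    ele_lines <- c(sprintf("%d 4 0", m),
                   sprintf("%d %d %d %d %d", seq_len(m), mesh$tets[, 1L],
                           mesh$tets[, 2L], mesh$tets[, 3L], mesh$tets[, 4L]))
    writeLines(ele_lines, paste0(stem, ".ele"))
  } else {
    n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
    lines <- c("# vtk DataFile Version 3.0", "tet_mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n),
               sprintf("%s %s %s", fmt(mesh$nodes[, 1L]), fmt(mesh$nodes[, 2L]),
                       fmt(mesh$nodes[, 3L])),
               sprintf("CELLS %d %d", m, 5L * m),
               sprintf("4 %d %d %d %d", mesh$tets[, 1L] - 1L, mesh$tets[, 2L] - 1L,
                       mesh$tets[, 3L] - 1L, mesh$tets[, 4L] - 1L),
               sprintf("CELL_TYPES %d", m),
               rep("10", m))
    writeLines(lines, path)
  }
  invisible(path)
}
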