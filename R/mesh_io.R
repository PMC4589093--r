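#' Read / write meshes in Gmsh v2 ASCII format
#'
#' Supports 2-node lines, 3-node triangles and 4-node tetrahedra (element
#' types 1, 2, 4). On read, the highest-dimensional elements present define
#' the mesh; lower-dimensional elements are dropped (the boundary is
#' re-extracted). Node coordinates round-trip to full double precision.
#'
#' @param mesh an `fmt_mesh`.
#' @param path file path.
#' @return `read_gmsh` returns an `fmt_mesh`; `write_gmsh` returns `path`
#'   invisibly.
#' @export
write_gmsh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(mesh$N)), con)
  coords <- mesh$nodes
  if (mesh$dimension == 2L) coords <- cbind(coords, 0)
  writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(mesh$N),
                     coords[, 1L], coords[, 2L], coords[, 3L]), con)
  writeLines(c("$EndNodes", "$Elements", as.character(mesh$P)), con)
  etype <- if (mesh$dimension == 2L) 2L else 4L
  writeLines(paste(seq_len(mesh$P), etype, 2L, 0L, 0L,
                   apply(mesh$elements, 1L, paste, collapse = " ")), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' @rdname write_gmsh
#' @export
read_gmsh <- function(path) {
  ln <- readLines(path)
  sec <- function(name) {
    i0 <- which(ln == paste0("$", name)) + 1L
    i1 <- which(ln == paste0("$End", name)) - 1L
    ln[i0:i1]
  }
  nd <- sec("Nodes")
  nn <- as.integer(nd[1L])
  nodetab <- do.call(rbind, lapply(strsplit(nd[1L + seq_len(nn)], "\\s+"),
                                   as.numeric))
  ord <- order(nodetab[, 1L])
  coords <- nodetab[ord, 2:4, drop = FALSE]
  eld <- sec("Elements")
  ne <- as.integer(eld[1L])
  rows <- strsplit(eld[1L + seq_len(ne)], "\\s+")
  parsed <- lapply(rows, function(r) {
    r <- as.integer(r)
    type <- r[2L]; ntags <- r[3L]
    conn <- r[(4L + ntags):length(r)]
    list(type = type, conn = conn)
  })
  types <- vapply(parsed, function(p) p$type, integer(1L))
  if (any(types == 4L)) {
    conn <- do.call(rbind, lapply(parsed[types == 4L], function(p) p$conn))
    dim <- 3L
  } else if (any(types == 2L)) {
    conn <- do.call(rbind, lapply(parsed[types == 2L], function(p) p$conn))
    dim <- 2L
  } else stop("no triangle or tetrahedron elements in Gmsh file")
  if (dim == 2L) coords <- coords[, 1:2, drop = FALSE]
  # renumber in case node ids are not 1..N
  conn <- matrix(match(conn, nodetab[ord, 1L]), nrow = nrow(conn))
  fmt_mesh(coords, conn)
}

#' Read / write meshes as legacy ASCII VTK unstructured grids
#'
#' Cell types 5 (triangle) and 10 (tetrahedron). `point_data` optionally
#' attaches one named nodal scalar field, which `read_vtk` returns as the
#' `point_data` attribute.
#'
#' @param mesh an `fmt_mesh`.
#' @param path file path.
#' @param point_data optional named list with one numeric vector of length N.
#' @return `read_vtk` returns an `fmt_mesh`; `write_vtk` returns `path`
#'   invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "fmtrecon mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", mesh$N)), con)
  coords <- mesh$nodes
  if (mesh$dimension == 2L) coords <- cbind(coords, 0)
  writeLines(sprintf("%.17g %.17g %.17g",
                     coords[, 1L], coords[, 2L], coords[, 3L]), con)
  nv <- mesh$dimension + 1L
  writeLines(sprintf("CELLS %d %d", mesh$P, mesh$P * (nv + 1L)), con)
  writeLines(paste(nv, apply(mesh$elements - 1L, 1L, paste, collapse = " ")),
             con)
  writeLines(sprintf("CELL_TYPES %d", mesh$P), con)
  ct <- if (mesh$dimension == 2L) 5L else 10L
  writeLines(as.character(rep(ct, mesh$P)), con)
  if (!is.null(point_data)) {
    nm <- names(point_data)[1L]
    writeLines(c(sprintf("POINT_DATA %d", mesh$N),
                 sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(sprintf("%.17g", point_data[[1L]]), con)
  }
  invisible(path)
}

#' @rdname write_vtk
#' @export
read_vtk <- function(path) {
  ln <- readLines(path)
  ip <- grep("^POINTS", ln)[1L]
  np <- as.integer(strsplit(ln[ip], "\\s+")[[1L]][2L])
  pts <- scan(text = ln[(ip + 1L):(ip + np)], quiet = TRUE)
  coords <- matrix(pts, ncol = 3L, byrow = TRUE)
  ic <- grep("^CELLS", ln)[1L]
  nc <- as.integer(strsplit(ln[ic], "\\s+")[[1L]][2L])
  cells <- lapply(strsplit(trimws(ln[(ic + 1L):(ic + nc)]), "\\s+"),
                  as.integer)
  it <- grep("^CELL_TYPES", ln)[1L]
  types <- as.integer(ln[(it + 1L):(it + nc)])
  keep <- if (any(types == 10L)) 10L else if (any(types == 5L)) 5L else
    stop("no triangle or tetrahedron cells in VTK file")
  conn <- do.call(rbind, lapply(cells[types == keep],
                                function(cc) cc[-1L] + 1L))
  dim <- if (keep == 10L) 3L else 2L
  if (dim == 2L) coords <- coords[, 1:2, drop = FALSE]
  m <- fmt_mesh(coords, conn)
  isd <- grep("^SCALARS", ln)
  if (length(isd)) {
    nm <- strsplit(ln[isd[1L]], "\\s+")[[1L]][2L]
    vals <- scan(text = ln[(isd[1L] + 2L):(isd[1L] + 1L + np)], quiet = TRUE)
    attr(m, "point_data") <- stats::setNames(list(vals), nm)
  }
  m
}
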