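#' Read a surface or volume mesh
#'
#' Supported formats: STL (ASCII and binary), PLY (ASCII), VTK legacy ASCII
#' (`POLYDATA` and `UNSTRUCTURED_GRID`), VTK XML (`.vtp`, `.vtu`, ASCII
#' appended data not supported) and Gmsh MSH v2.2 ASCII. Units are assumed to
#' be millimetres and are never rescaled. Anatomical labels are recovered from
#' an integer cell-data array named `label` when present (see
#' [label_codes()]).
#'
#' @param path Path to the mesh file.
#' @param format_hint Optional format override: one of `"stl"`, `"ply"`,
#'   `"vtk"`, `"vtp"`, `"vtu"`, `"msh"`. Defaults to the file extension.
#' @return A [surface_mesh()] or, when the file holds tetrahedra, a
#'   [volume_mesh()].
#' @export
read_mesh <- function(path, format_hint = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fmt <- tolower(format_hint %||% tools::file_ext(path))
  switch(fmt,
         stl = read_stl(path),
         ply = read_ply(path),
         vtk = read_vtk_legacy(path),
         vtp = read_vtk_xml(path),
         vtu = read_vtk_xml(path),
         msh = read_msh(path),
         stop("unknown mesh format '", fmt, "'; supported: ",
              "stl, ply, vtk, vtp, vtu, msh", call. = FALSE))
}

#' Write a surface or volume mesh
#'
#' ASCII writers use fixed field order and fixed floating-point formatting so
#' identical input produces byte-identical files. STL cannot carry cell data:
#' labels are dropped with a warning.
#'
#' @param mesh A [surface_mesh()] or [volume_mesh()].
#' @param path Output path.
#' @param format One of `"stl"`, `"stl_binary"`, `"ply"`, `"vtk"`, `"vtp"`,
#'   `"vtu"`, `"msh"`; defaults to the file extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  fmt <- tolower(format %||% tools::file_ext(path))
  if (inherits(mesh, "surface_mesh")) validate_mesh(mesh)
  switch(fmt,
         stl = write_stl(mesh, path, binary = FALSE),
         stl_binary = write_stl(mesh, path, binary = TRUE),
         ply = write_ply(mesh, path),
         vtk = write_vtk_legacy(mesh, path),
         vtp = write_vtk_xml(mesh, path, "vtp"),
         vtu = write_vtk_xml(mesh, path, "vtu"),
         msh = write_msh(mesh, path),
         stop("unknown mesh format '", fmt, "'; supported: ",
              "stl, stl_binary, ply, vtk, vtp, vtu, msh", call. = FALSE))
  invisible(path)
}

## ---- STL -------------------------------------------------------------

read_stl <- function(path) {
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  sz <- file.info(path)$size
  close(con)
  is_binary <- length(ntri) == 1 && !is.na(ntri) &&
    sz == 84 + 50 * as.numeric(ntri)
  if (is_binary) read_stl_binary(path) else read_stl_ascii(path)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  raw <- readBin(con, "raw", 50 * ntri)
  if (length(raw) < 50 * ntri)
    stop("STL truncated at byte ", 84 + length(raw), " (expected ",
         84 + 50 * ntri, " bytes)", call. = FALSE)
  m <- matrix(raw, nrow = 50)
  tri_raw <- as.raw(m[1:48, ])
  vals <- readBin(tri_raw, "numeric", n = 12 * ntri, size = 4,
                  endian = "little")
  vals <- matrix(vals, nrow = 12)     # nx ny nz v1 v2 v3 per column
  verts <- matrix(as.vector(vals[4:12, , drop = FALSE]), ncol = 3,
                  byrow = TRUE)
  stl_soup_to_mesh(verts)
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (!length(vl))
    stop("ASCII STL parse failure near byte 0: no 'vertex' records",
         call. = FALSE)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  if (any(!is.finite(nums)))
    stop("ASCII STL has non-numeric vertex coordinates", call. = FALSE)
  stl_soup_to_mesh(nums)
}

# Triangle soup (3 rows per face) -> indexed mesh by exact coordinate match.
stl_soup_to_mesh <- function(verts) {
  if (nrow(verts) %% 3 != 0)
    stop("STL vertex count not a multiple of 3", call. = FALSE)
  key <- paste(verts[, 1], verts[, 2], verts[, 3])
  uid <- match(key, unique(key))
  uverts <- verts[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  surface_mesh(uverts, faces)
}

write_stl <- function(mesh, path, binary = FALSE) {
  if (!inherits(mesh, "surface_mesh"))
    stop("STL supports surface meshes only", call. = FALSE)
  if (any(mesh$face_labels != 0L))
    warning("STL cannot carry face labels; labels dropped on write")
  v <- mesh$vertices; f <- mesh$faces
  n <- face_normals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(c(charToRaw(sprintf("%-80s", "laaoplan binary STL"))[1:80]), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(n[i, ]), con, size = 4, endian = "little")
      writeBin(as.numeric(t(v[f[i, ], ])), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    lines <- character(2 + nrow(f) * 7)
    lines[1] <- "solid laaoplan"
    k <- 2
    for (i in seq_len(nrow(f))) {
      lines[k] <- paste("facet normal", paste(fmt_num(n[i, ]), collapse = " "))
      lines[k + 1] <- "  outer loop"
      lines[k + 2:4] <- paste("    vertex",
                              apply(v[f[i, ], , drop = FALSE], 1, function(r)
                                paste(fmt_num(r), collapse = " ")))
      lines[k + 5] <- "  endloop"
      lines[k + 6] <- "endfacet"
      k <- k + 7
    }
    lines[k] <- "endsolid laaoplan"
    writeLines(lines, path)
  }
  invisible(path)
}

## ---- PLY (ASCII) -----------------------------------------------------

read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (txt[1] != "ply") stop("not a PLY file (bad magic at byte 0)", call. = FALSE)
  hend <- match("end_header", txt)
  if (is.na(hend)) stop("PLY header not terminated", call. = FALSE)
  header <- txt[1:hend]
  if (!any(grepl("^format ascii", header)))
    stop("only ASCII PLY is supported", call. = FALSE)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", header, value = TRUE)))
  body <- txt[(hend + 1):length(txt)]
  vrows <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- do.call(rbind, lapply(vrows, function(p) as.numeric(p[1:3])))
  frows <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- do.call(rbind, lapply(frows, function(p) {
    if (as.integer(p[1]) != 3L)
      stop("unsupported element: non-triangular PLY face", call. = FALSE)
    as.integer(p[2:4]) + 1L
  }))
  # face label property, if declared, is the first scalar after the list
  face_props <- grep("^property ", header[seq(grep("^element face", header),
                                              hend)], value = TRUE)
  labels <- NULL
  if (any(grepl(" label$", face_props)))
    labels <- vapply(frows, function(p) as.integer(p[5]), integer(1))
  surface_mesh(verts, faces, labels)
}

write_ply <- function(mesh, path) {
  if (!inherits(mesh, "surface_mesh"))
    stop("PLY writer supports surface meshes only", call. = FALSE)
  v <- mesh$vertices; f <- mesh$faces
  header <- c("ply", "format ascii 1.0",
              "comment laaoplan labelled anatomy mesh",
              paste("element vertex", nrow(v)),
              "property float x", "property float y", "property float z",
              paste("element face", nrow(f)),
              "property list uchar int vertex_indices",
              "property int label",
              "end_header")
  vlines <- apply(v, 1, function(r) paste(fmt_num(r), collapse = " "))
  flines <- paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L, mesh$face_labels)
  writeLines(c(header, vlines, flines), path)
  invisible(path)
}

## ---- VTK legacy ASCII ------------------------------------------------

read_vtk_legacy <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (!grepl("^# vtk DataFile", txt[1]))
    stop("not a legacy VTK file (bad magic at byte 0)", call. = FALSE)
  toks <- scan_tokens(txt[-(1:2)])
  geti <- function(word) which(toks == word)[1]
  ip <- geti("POINTS")
  np <- as.integer(toks[ip + 1])
  verts <- matrix(as.numeric(toks[ip + 2 + seq_len(3 * np)]), ncol = 3,
                  byrow = TRUE)
  labels <- NULL
  lab_at <- which(toks == "label")
  if (length(lab_at)) {
    # tokens: label int 1 LOOKUP_TABLE default <values...>
    nlab <- length(toks) - (lab_at[1] + 4)
    labels <- as.integer(toks[lab_at[1] + 4 + seq_len(nlab)])
  }
  if (!is.na(geti("POLYGONS"))) {
    ig <- geti("POLYGONS")
    ncell <- as.integer(toks[ig + 1])
    faces <- matrix(0L, ncell, 3)
    k <- ig + 3
    for (i in seq_len(ncell)) {
      cnt <- as.integer(toks[k])
      if (cnt != 3L) stop("unsupported element: non-triangle polygon",
                          call. = FALSE)
      faces[i, ] <- as.integer(toks[k + 1:3]) + 1L
      k <- k + 4
    }
    return(surface_mesh(verts, faces, if (length(labels)) labels[seq_len(ncell)]))
  }
  ic <- geti("CELLS")
  if (is.na(ic)) stop("VTK file has neither POLYGONS nor CELLS", call. = FALSE)
  ncell <- as.integer(toks[ic + 1])
  it <- geti("CELL_TYPES")
  types <- as.integer(toks[it + 1 + seq_len(ncell)])
  cells <- vector("list", ncell)
  k <- ic + 3
  for (i in seq_len(ncell)) {
    cnt <- as.integer(toks[k])
    cells[[i]] <- as.integer(toks[k + seq_len(cnt)]) + 1L
    k <- k + cnt + 1
  }
  if (all(types == 10L)) {
    volume_mesh(verts, do.call(rbind, cells))
  } else if (all(types == 5L)) {
    surface_mesh(verts, do.call(rbind, cells),
                 if (length(labels)) labels[seq_len(ncell)])
  } else stop("unsupported element types in VTK file: ",
              paste(unique(types), collapse = ", "), call. = FALSE)
}

scan_tokens <- function(lines) unlist(strsplit(trimws(lines), "\\s+"))

write_vtk_legacy <- function(mesh, path) {
  if (inherits(mesh, "surface_mesh")) {
    v <- mesh$vertices; f <- mesh$faces
    lines <- c("# vtk DataFile Version 3.0", "laaoplan mesh", "ASCII",
               "DATASET POLYDATA",
               paste("POINTS", nrow(v), "float"),
               apply(v, 1, function(r) paste(fmt_num(r), collapse = " ")),
               paste("POLYGONS", nrow(f), 4 * nrow(f)),
               paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
               paste("CELL_DATA", nrow(f)),
               "SCALARS label int 1", "LOOKUP_TABLE default",
               as.character(mesh$face_labels))
  } else {
    v <- mesh$vertices; tt <- mesh$tets
    lines <- c("# vtk DataFile Version 3.0", "laaoplan mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", nrow(v), "float"),
               apply(v, 1, function(r) paste(fmt_num(r), collapse = " ")),
               paste("CELLS", nrow(tt), 5 * nrow(tt)),
               paste(4L, tt[, 1] - 1L, tt[, 2] - 1L, tt[, 3] - 1L, tt[, 4] - 1L),
               paste("CELL_TYPES", nrow(tt)),
               rep("10", nrow(tt)))
  }
  writeLines(lines, path)
  invisible(path)
}

## ---- VTK XML (vtp / vtu, inline ASCII) -------------------------------

read_vtk_xml <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, "//Piece")
  pts <- xml2::xml_find_first(piece, ".//Points/DataArray")
  verts <- matrix(as.numeric(scan_tokens(xml2::xml_text(pts))), ncol = 3,
                  byrow = TRUE)
  labels <- NULL
  lab <- xml2::xml_find_first(piece, ".//CellData/DataArray[@Name='label']")
  if (!inherits(lab, "xml_missing"))
    labels <- as.integer(scan_tokens(xml2::xml_text(lab)))
  root_name <- xml2::xml_attr(xml2::xml_root(doc), "type")
  if (identical(root_name, "PolyData") ||
      !inherits(xml2::xml_find_first(piece, ".//Polys"), "xml_missing")) {
    conn <- as.integer(scan_tokens(xml2::xml_text(xml2::xml_find_first(
      piece, ".//Polys/DataArray[@Name='connectivity']"))))
    offs <- as.integer(scan_tokens(xml2::xml_text(xml2::xml_find_first(
      piece, ".//Polys/DataArray[@Name='offsets']"))))
    if (any(diff(c(0L, offs)) != 3L))
      stop("unsupported element: non-triangle polys in VTP", call. = FALSE)
    faces <- matrix(conn, ncol = 3, byrow = TRUE) + 1L
    return(surface_mesh(verts, faces, labels))
  }
  conn <- as.integer(scan_tokens(xml2::xml_text(xml2::xml_find_first(
    piece, ".//Cells/DataArray[@Name='connectivity']"))))
  offs <- as.integer(scan_tokens(xml2::xml_text(xml2::xml_find_first(
    piece, ".//Cells/DataArray[@Name='offsets']"))))
  types <- as.integer(scan_tokens(xml2::xml_text(xml2::xml_find_first(
    piece, ".//Cells/DataArray[@Name='types']"))))
  sizes <- diff(c(0L, offs))
  if (all(types == 10L) && all(sizes == 4L)) {
    volume_mesh(verts, matrix(conn, ncol = 4, byrow = TRUE) + 1L)
  } else if (all(types == 5L) && all(sizes == 3L)) {
    surface_mesh(verts, matrix(conn, ncol = 3, byrow = TRUE) + 1L, labels)
  } else stop("mixed or unsupported element types in VTU", call. = FALSE)
}

xml_da <- function(name, type, ncomp, values) {
  c(sprintf('      <DataArray type="%s" Name="%s"%s format="ascii">',
            type, name,
            if (is.na(ncomp)) "" else sprintf(' NumberOfComponents="%d"', ncomp)),
    paste("       ", paste(values, collapse = " ")),
    "      </DataArray>")
}

write_vtk_xml <- function(mesh, path, flavour, point_data = NULL) {
  if (flavour == "vtp" && !inherits(mesh, "surface_mesh"))
    stop("VTP holds surface meshes; use vtu for volume meshes", call. = FALSE)
  v <- mesh$vertices
  vtxt <- as.vector(apply(v, 1, fmt_num))  # x1 y1 z1 x2 ...
  pd_lines <- character(0)
  if (!is.null(point_data)) {
    pd_lines <- c("    <PointData>",
                  unlist(lapply(names(point_data), function(nm)
                    xml_da(nm, "Float64", NA, fmt_num(point_data[[nm]])))),
                  "    </PointData>")
  }
  if (inherits(mesh, "surface_mesh")) {
    f <- mesh$faces
    ncell <- nrow(f)
    cell_block <- if (flavour == "vtp") {
      c("    <Polys>",
        xml_da("connectivity", "Int64", NA, as.vector(t(f)) - 1L),
        xml_da("offsets", "Int64", NA, seq_len(ncell) * 3L),
        "    </Polys>")
    } else {
      c("    <Cells>",
        xml_da("connectivity", "Int64", NA, as.vector(t(f)) - 1L),
        xml_da("offsets", "Int64", NA, seq_len(ncell) * 3L),
        xml_da("types", "UInt8", NA, rep(5L, ncell)),
        "    </Cells>")
    }
    cdata <- c("    <CellData>",
               xml_da("label", "Int32", NA, mesh$face_labels),
               "    </CellData>")
  } else {
    tt <- mesh$tets
    ncell <- nrow(tt)
    if (flavour != "vtu") stop("volume meshes must be written as VTU",
                               call. = FALSE)
    cell_block <- c("    <Cells>",
                    xml_da("connectivity", "Int64", NA, as.vector(t(tt)) - 1L),
                    xml_da("offsets", "Int64", NA, seq_len(ncell) * 4L),
                    xml_da("types", "UInt8", NA, rep(10L, ncell)),
                    "    </Cells>")
    cdata <- character(0)
  }
  tag <- if (flavour == "vtp") "PolyData" else "UnstructuredGrid"
  piece_attrs <- if (flavour == "vtp")
    sprintf('NumberOfPoints="%d" NumberOfVerts="0" NumberOfLines="0" NumberOfStrips="0" NumberOfPolys="%d"',
            nrow(v), ncell)
  else sprintf('NumberOfPoints="%d" NumberOfCells="%d"', nrow(v), ncell)
  lines <- c(sprintf('<VTKFile type="%s" version="0.1" byte_order="LittleEndian">', tag),
             sprintf("  <%s>", tag),
             sprintf("  <Piece %s>", piece_attrs),
             "    <Points>",
             xml_da("Points", "Float64", 3L, vtxt),
             "    </Points>",
             pd_lines, cell_block, cdata,
             "  </Piece>",
             sprintf("  </%s>", tag),
             "</VTKFile>")
  writeLines(lines, path)
  invisible(path)
}

## ---- Gmsh MSH v2.2 ASCII ---------------------------------------------

read_msh <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (!identical(txt[1], "$MeshFormat"))
    stop("not an MSH file (missing $MeshFormat at byte 0)", call. = FALSE)
  nstart <- match("$Nodes", txt)
  nn <- as.integer(txt[nstart + 1])
  nrows <- strsplit(trimws(txt[nstart + 1 + seq_len(nn)]), "\\s+")
  verts <- do.call(rbind, lapply(nrows, function(p) as.numeric(p[2:4])))
  estart <- match("$Elements", txt)
  ne <- as.integer(txt[estart + 1])
  erows <- strsplit(trimws(txt[estart + 1 + seq_len(ne)]), "\\s+")
  tris <- list(); tri_lab <- integer(0); tets <- list()
  for (p in erows) {
    type <- as.integer(p[2]); ntags <- as.integer(p[3])
    nodes <- as.integer(p[(4 + ntags):length(p)])
    if (type == 2L) {
      tris[[length(tris) + 1L]] <- nodes
      tri_lab <- c(tri_lab, if (ntags >= 1) as.integer(p[4]) else 0L)
    } else if (type == 4L) {
      tets[[length(tets) + 1L]] <- nodes
    } else stop("unsupported element type ", type, " in MSH", call. = FALSE)
  }
  if (length(tets)) {
    boundary <- if (length(tris))
      surface_mesh(verts, do.call(rbind, tris), tri_lab, validate = FALSE)
    volume_mesh(verts, do.call(rbind, tets), boundary = boundary)
  } else {
    surface_mesh(verts, do.call(rbind, tris), tri_lab)
  }
}

write_msh <- function(mesh, path) {
  v <- if (inherits(mesh, "surface_mesh")) mesh$vertices else mesh$vertices
  lines <- c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
             "$Nodes", as.character(nrow(v)),
             paste(seq_len(nrow(v)),
                   apply(v, 1, function(r) paste(fmt_num(r), collapse = " "))),
             "$EndNodes")
  if (inherits(mesh, "surface_mesh")) {
    f <- mesh$faces
    el <- paste(seq_len(nrow(f)), 2L, 2L, mesh$face_labels, mesh$face_labels,
                f[, 1], f[, 2], f[, 3])
    lines <- c(lines, "$Elements", as.character(nrow(f)), el, "$EndElements")
  } else {
    tt <- mesh$tets
    el_t <- paste(seq_len(nrow(tt)), 4L, 2L, 0L, 0L,
                  tt[, 1], tt[, 2], tt[, 3], tt[, 4])
    el_s <- character(0)
    if (!is.null(mesh$boundary)) {
      f <- mesh$boundary$faces
      el_s <- paste(nrow(tt) + seq_len(nrow(f)), 2L, 2L,
                    mesh$boundary$face_labels, mesh$boundary$face_labels,
                    f[, 1], f[, 2], f[, 3])
    }
    lines <- c(lines, "$Elements", as.character(nrow(tt) + length(el_s)),
               el_t, el_s, "$EndElements")
  }
  writeLines(lines, path)
  invisible(path)
}
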