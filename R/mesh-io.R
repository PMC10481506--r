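#' Labeled triangle mesh
#'
#' The container for one intra-oral scan: vertices in mm, triangular faces,
#' and an optional per-face instance annotation (0 = gingiva, k > 0 = tooth
#' instance k) plus a map from instance id to FDI code.
#'
#' @param vertices numeric matrix (V x 3), mm.
#' @param faces integer matrix (F x 3) of 1-based vertex indices.
#' @param face_labels integer vector of length F, or `NULL`/empty for an
#'   unannotated mesh.
#' @param fdi_map named integer vector mapping instance id (name) to FDI
#'   code, or `NULL`.
#' @return an object of class `labeled_mesh`.
#' @export
labeled_mesh <- function(vertices, faces, face_labels = NULL, fdi_map = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = list(NULL, c("x", "y", "z")))
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("labeled_mesh: face index out of range", call. = FALSE)
  if (!is.null(face_labels) && length(face_labels) > 0) {
    face_labels <- as.integer(face_labels)
    if (length(face_labels) != nrow(faces))
      stop("labeled_mesh: face_labels length (", length(face_labels),
           ") does not match face count (", nrow(faces), ")", call. = FALSE)
  } else {
    face_labels <- integer(0)
  }
  if (!is.null(fdi_map) && length(fdi_map) > 0) {
    ids <- as.integer(names(fdi_map))
    fdi_map <- stats::setNames(as.integer(fdi_map), names(fdi_map))
    if (!all(ids %in% face_labels))
      stop("labeled_mesh: fdi_map refers to instance ids absent from face_labels",
           call. = FALSE)
    if (!all(fdi_map %in% fdi_codes()))
      stop("labeled_mesh: fdi_map contains non-FDI codes", call. = FALSE)
  } else {
    fdi_map <- stats::setNames(integer(0), character(0))
  }
  structure(list(vertices = vertices, faces = faces,
                 face_labels = face_labels, fdi_map = fdi_map),
            class = "labeled_mesh")
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat("<labeled_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces", if (length(x$face_labels))
        paste0(", ", length(setdiff(unique(x$face_labels), 0L)),
               " tooth instances"), "\n", sep = "")
  invisible(x)
}

sidecar_path <- function(path) {
  sub("\\.[^.]+$", ".labels.json", path)
}

mesh_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(toupper(format), c("PLY", "OBJ", "STL")))
  ext <- toupper(sub(".*\\.", "", path))
  if (!ext %in% c("PLY", "OBJ", "STL"))
    stop("cannot infer mesh format from extension of ", path, call. = FALSE)
  ext
}

#' Read a dental mesh with optional annotation sidecar
#'
#' Reads PLY (ascii and binary little-endian), OBJ (`v`/`f` records) or STL
#' (ascii and binary). If a `<basename>.labels.json` sidecar exists next to
#' the file, per-face instance labels and the instance-to-FDI map are loaded
#' from it; otherwise the mesh is returned unannotated.
#'
#' @param path file path.
#' @param format `"PLY"`, `"OBJ"` or `"STL"`; inferred from the extension
#'   when omitted.
#' @return a [labeled_mesh()].
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- mesh_format(path, format)
  geom <- switch(format,
                 PLY = read_ply(path),
                 OBJ = read_obj(path),
                 STL = read_stl(path))
  face_labels <- NULL; fdi_map <- NULL
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    ann <- jsonlite::read_json(sc, simplifyVector = TRUE)
    face_labels <- ann$face_labels
    if (!is.null(ann$fdi_map) && length(ann$fdi_map))
      fdi_map <- unlist(ann$fdi_map)
    if (length(face_labels) != nrow(geom$faces))
      stop("annotation error: sidecar has ", length(face_labels),
           " labels for ", nrow(geom$faces), " faces", call. = FALSE)
  }
  labeled_mesh(geom$vertices, geom$faces, face_labels, fdi_map)
}

#' Write a dental mesh and its annotation sidecar
#'
#' Writes the mesh in the requested format and, when the mesh carries
#' face labels, a `<basename>.labels.json` sidecar with `face_labels` and
#' `fdi_map`. None of the supported geometry formats store instance labels
#' natively; a warning reminds of this for STL, whose triangle soup also
#' discards shared-vertex topology.
#'
#' @param mesh a [labeled_mesh()].
#' @param path output path.
#' @param format `"PLY"`, `"OBJ"` or `"STL"`; inferred from extension when
#'   omitted.
#' @param binary write binary PLY/STL instead of ascii (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  format <- mesh_format(path, format)
  switch(format,
         PLY = write_ply(mesh, path, binary),
         OBJ = write_obj(mesh, path),
         STL = write_stl(mesh, path, binary))
  if (length(mesh$face_labels)) {
    if (format == "STL")
      warning("STL stores no labels or shared vertices; labels written to sidecar only",
              call. = FALSE)
    jsonlite::write_json(
      list(face_labels = mesh$face_labels,
           fdi_map = as.list(mesh$fdi_map)),
      sidecar_path(path), auto_unbox = TRUE)
  }
  invisible(path)
}

# ---- PLY ---------------------------------------------------------------

ply_type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                   short = 2, ushort = 2, int16 = 2, uint16 = 2,
                   int = 4, uint = 4, int32 = 4, uint32 = 4,
                   float = 4, float32 = 4, double = 8, float64 = 8)

read_ply <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  # header ends at the newline after "end_header"; search raw bytes because
  # a binary body may contain nul characters
  hit <- grepRaw("end_header\n", bytes, fixed = TRUE)
  skip <- 11L
  if (length(hit) == 0) {
    hit <- grepRaw("end_header\r\n", bytes, fixed = TRUE)
    skip <- 12L
  }
  if (length(hit) == 0)
    stop("format error: PLY header not terminated", call. = FALSE)
  hdr_end <- hit[1]
  body_off <- hdr_end + skip
  hdr_lines <- strsplit(rawToChar(bytes[seq_len(hdr_end - 1)]), "\r?\n")[[1]]
  if (!identical(trimws(hdr_lines[1]), "ply"))
    stop("format error: missing 'ply' magic in ", path, call. = FALSE)
  fmt <- NULL; elements <- list(); cur <- NULL
  for (line in hdr_lines[-1]) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list")
        elements[[cur]]$props[[tok[5]]] <- list(list = TRUE, count_type = tok[3], type = tok[4])
      else
        elements[[cur]]$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
    }
  }
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("format error: PLY lacks vertex/face elements", call. = FALSE)
  body <- if (body_off > length(bytes)) raw(0)
          else bytes[seq.int(body_off, length(bytes))]
  if (identical(fmt, "ascii")) read_ply_ascii(body, elements)
  else if (identical(fmt, "binary_little_endian")) {
    con <- rawConnection(body)
    on.exit(close(con))
    read_ply_binary(con, elements)
  } else stop("format error: unsupported PLY format '", fmt, "'", call. = FALSE)
}

read_ply_ascii <- function(body, elements) {
  vn <- elements$vertex$count; fn <- elements$face$count
  vprops <- names(elements$vertex$props)
  lines <- strsplit(rawToChar(body), "\r?\n")[[1]]
  lines <- lines[trimws(lines) != ""]
  if (length(lines) < vn + fn)
    stop("format error: PLY body truncated", call. = FALSE)
  vert <- matrix(0, vn, 3)
  for (i in seq_len(vn)) {
    v <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
    vert[i, ] <- v[match(c("x", "y", "z"), vprops)]
  }
  faces <- matrix(0L, fn, 3)
  for (i in seq_len(fn)) {
    f <- as.integer(strsplit(trimws(lines[vn + i]), "\\s+")[[1]])
    if (f[1] != 3) stop("format error: non-triangular PLY face ", i, call. = FALSE)
    faces[i, ] <- f[2:4] + 1L
  }
  list(vertices = vert, faces = faces)
}

read_ply_binary <- function(con, elements) {
  vn <- elements$vertex$count; fn <- elements$face$count
  vprops <- elements$vertex$props
  vert <- matrix(0, vn, 3)
  for (i in seq_len(vn)) {
    for (p in names(vprops)) {
      ty <- vprops[[p]]$type
      val <- read_ply_scalar(con, ty)
      if (p %in% c("x", "y", "z"))
        vert[i, match(p, c("x", "y", "z"))] <- val
    }
  }
  fprop <- elements$face$props[[1]]
  faces <- matrix(0L, fn, 3)
  for (i in seq_len(fn)) {
    k <- read_ply_scalar(con, fprop$count_type)
    if (k != 3) stop("format error: non-triangular PLY face ", i, call. = FALSE)
    faces[i, ] <- vapply(1:3, function(j) as.integer(read_ply_scalar(con, fprop$type)), integer(1)) + 1L
  }
  list(vertices = vert, faces = faces)
}

read_ply_scalar <- function(con, type) {
  sz <- ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64"))
    readBin(con, "double", 1, size = sz, endian = "little")
  else
    readBin(con, "integer", 1, size = sz, endian = "little",
            signed = !(sz < 4 && grepl("^u", type)))
}

write_ply <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  hdr <- c("ply",
           paste("format", if (binary) "binary_little_endian" else "ascii", "1.0"),
           paste("element vertex", nrow(v)),
           "property double x", "property double y", "property double z",
           paste("element face", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
    for (i in seq_len(nrow(v)))
      writeBin(as.numeric(v[i, ]), con, size = 8, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    body_v <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
    body_f <- apply(f, 1, function(r) paste(c(3, r - 1L), collapse = " "))
    writeLines(c(hdr, body_v, body_f), path)
  }
}

# ---- OBJ ---------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  vert <- t(vapply(vl, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1]][2:4]))
    if (anyNA(v)) stop("format error: bad OBJ vertex record '", l, "'", call. = FALSE)
    v
  }, numeric(3), USE.NAMES = FALSE))
  faces <- t(vapply(fl, function(l) {
    tok <- strsplit(l, "\\s+")[[1]][-1]
    if (length(tok) != 3) stop("format error: non-triangular OBJ face '", l, "'", call. = FALSE)
    idx <- suppressWarnings(as.integer(sub("/.*", "", tok)))
    if (anyNA(idx)) stop("format error: bad OBJ face record '", l, "'", call. = FALSE)
    idx
  }, integer(3), USE.NAMES = FALSE))
  if (length(vl) == 0) vert <- matrix(0, 0, 3)
  if (length(fl) == 0) faces <- matrix(0L, 0, 3)
  list(vertices = vert, faces = faces)
}

write_obj <- function(mesh, path) {
  v <- apply(mesh$vertices, 1, function(r)
    paste("v", paste(sprintf("%.17g", r), collapse = " ")))
  f <- apply(mesh$faces, 1, function(r) paste("f", paste(r, collapse = " ")))
  writeLines(c(v, f), path)
}

# ---- STL ---------------------------------------------------------------

read_stl <- function(path) {
  # binary STL: 80-byte header + uint32 count + 50 bytes per triangle
  sz <- file.size(path)
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", 80)
  is_binary <- FALSE
  if (sz >= 84) {
    n <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (!is.na(n) && sz == 84 + 50 * n) is_binary <- TRUE
  }
  close(con)
  tris <- if (is_binary) read_stl_binary(path) else read_stl_ascii(path)
  if (nrow(tris) == 0)
    return(list(vertices = matrix(0, 0, 3), faces = matrix(0L, 0, 3)))
  # merge exactly coincident vertices back into shared topology
  key <- apply(tris, 1, function(r) paste(sprintf("%.9g", r), collapse = "_"))
  uid <- match(key, unique(key))
  vertices <- tris[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  list(vertices = vertices, faces = faces)
}

read_stl_ascii <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  if (length(lines) == 0 || !startsWith(lines[1], "solid"))
    stop("format error: STL missing 'solid' header", call. = FALSE)
  vl <- lines[startsWith(lines, "vertex")]
  if (length(vl) %% 3 != 0)
    stop("format error: STL vertex count not a multiple of 3", call. = FALSE)
  if (length(vl) == 0) return(matrix(0, 0, 3))
  t(vapply(vl, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1]][2:4]))
    if (anyNA(v)) stop("format error: bad STL vertex '", l, "'", call. = FALSE)
    v
  }, numeric(3), USE.NAMES = FALSE))
}

read_stl_binary <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", 80)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  tris <- matrix(0, 3 * n, 3)
  for (i in seq_len(n)) {
    vals <- readBin(con, "double", 12, size = 4, endian = "little")
    readBin(con, "raw", 2)  # attribute byte count
    tris[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  tris
}

write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(rep(0, 3), con, size = 4, endian = "little")  # normal
      writeBin(as.numeric(t(v[f[i, ], , drop = FALSE])), con, size = 4,
               endian = "little")
      writeBin(raw(2), con)
    }
  } else {
    out <- c("solid mesh")
    for (i in seq_len(nrow(f))) {
      tri <- v[f[i, ], , drop = FALSE]
      out <- c(out, "facet normal 0 0 0", "outer loop",
               apply(tri, 1, function(r)
                 paste("vertex", paste(sprintf("%.9g", r), collapse = " "))),
               "endloop", "endfacet")
    }
    writeLines(c(out, "endsolid mesh"), path)
  }
}

#' Uniform random downsampling of a mesh to a fixed vertex budget
#'
#' Selects `min(target, V)` vertices uniformly at random without
#' replacement, reproducibly under `seed`. Each selected vertex inherits a
#' tooth/gingiva class and instance id by majority vote over the labels of
#' its incident faces (ties broken toward the smaller label). The 30,000
#' default is the fixed budget the detection stage consumes.
#'
#' @param mesh a [labeled_mesh()].
#' @param target number of points to keep (default 30000).
#' @param seed integer seed.
#' @return a tibble with columns `x`, `y`, `z` and, when the mesh is
#'   annotated, `instance` (majority face label) and `class`
#'   (1 = tooth, 0 = gingiva).
#' @export
downsample_uniform <- function(mesh, target = 30000, seed = 1L) {
  stopifnot(inherits(mesh, "labeled_mesh"), target >= 1)
  vn <- nrow(mesh$vertices)
  keep <- withr::with_seed(seed, sample.int(vn, min(target, vn)))
  out <- tibble::as_tibble(mesh$vertices[keep, , drop = FALSE])
  if (length(mesh$face_labels)) {
    inst <- vertex_majority_label(mesh)[keep]
    out$instance <- inst
    out$class <- as.integer(inst > 0L)
  }
  out
}

vertex_majority_label <- function(mesh) {
  f <- as.vector(mesh$faces)
  lab <- rep(mesh$face_labels, 3)
  vapply(seq_len(nrow(mesh$vertices)), function(v) {
    ls <- lab[f == v]
    if (length(ls) == 0) return(0L)
    tb <- table(ls)
    as.integer(names(tb)[which.max(tb)])
  }, integer(1))
}
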