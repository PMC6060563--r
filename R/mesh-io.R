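#' Read a triangle mesh from disk
#'
#' Supports OFF, OBJ, PLY (ascii and binary little-endian) and STL (ascii
#' and binary). Vertices and faces are returned exactly as stored — vertex
#' order is preserved and no welding is performed unless requested (STL
#' stores a triangle soup, so welding is usually wanted there).
#'
#' @param path file path.
#' @param format one of `"auto"` (from the extension), `"ply"`, `"obj"`,
#'   `"off"`, `"stl"`.
#' @param weld if `TRUE`, merge coincident vertices after reading.
#' @param weld_tol welding tolerance (micrometres).
#' @return a [spine_mesh].
#' @export
read_mesh <- function(path, format = c("auto", "ply", "obj", "off", "stl"),
                      weld = FALSE, weld_tol = 1e-6) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read mesh: no such file: ", path)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("ply", "obj", "off", "stl"))
      stop("cannot infer mesh format from extension: ", path)
  }
  mesh <- switch(format,
    off = read_off(path), obj = read_obj(path),
    ply = read_ply(path), stl = read_stl(path))
  if (weld) mesh <- weld_vertices(mesh, weld_tol)
  mesh
}

#' Write a triangle mesh to disk
#'
#' @param mesh a [spine_mesh].
#' @param path output path.
#' @param format output format; `"auto"` uses the extension. PLY and STL
#'   are written as ascii.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path,
                       format = c("auto", "ply", "obj", "off", "stl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("ply", "obj", "off", "stl"))
      stop("cannot infer mesh format from extension: ", path)
  }
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  fmtv <- function(m) apply(m, 1, function(r) paste(sprintf("%.9g", r),
                                                    collapse = " "))
  switch(format,
    off = {
      writeLines("OFF", con)
      writeLines(sprintf("%d %d 0", nrow(v), nrow(f)), con)
      writeLines(fmtv(v), con)
      writeLines(paste("3", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
    },
    obj = {
      writeLines(paste("v", fmtv(v)), con)
      writeLines(paste("f", f[, 1], f[, 2], f[, 3]), con)
    },
    ply = {
      writeLines(c("ply", "format ascii 1.0",
                   sprintf("element vertex %d", nrow(v)),
                   "property float x", "property float y", "property float z",
                   sprintf("element face %d", nrow(f)),
                   "property list uchar int vertex_indices", "end_header"),
                 con)
      writeLines(fmtv(v), con)
      writeLines(paste("3", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
    },
    stl = {
      writeLines("solid spinemorph", con)
      for (i in seq_len(nrow(f))) {
        tri <- v[f[i, ], , drop = FALSE]
        n <- c(0, 0, 0)
        e1 <- tri[2, ] - tri[1, ]; e2 <- tri[3, ] - tri[1, ]
        n <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
               e1[1] * e2[2] - e1[2] * e2[1])
        nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
        writeLines(c(sprintf("facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                     "  outer loop",
                     sprintf("    vertex %.9g %.9g %.9g",
                             tri[, 1], tri[, 2], tri[, 3]),
                     "  endloop", "endfacet"), con)
      }
      writeLines("endsolid spinemorph", con)
    })
  invisible(path)
}

read_off <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (toupper(ln[1]) != "OFF") stop("not an OFF file: ", path)
  counts <- as.integer(strsplit(ln[2], "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vl <- ln[3:(2 + nv)]
  v <- matrix(as.numeric(unlist(strsplit(vl, "\\s+"))), ncol = 3,
              byrow = TRUE)
  fl <- ln[(3 + nv):(2 + nv + nf)]
  fp <- strsplit(fl, "\\s+")
  nvert <- vapply(fp, function(x) as.integer(x[1]), integer(1))
  if (any(nvert != 3L))
    stop("non-triangular face in OFF file at face ", which(nvert != 3L)[1])
  f <- t(vapply(fp, function(x) as.integer(x[2:4]), integer(3))) + 1L
  spine_mesh(v, f)
}

read_obj <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  v <- matrix(as.numeric(unlist(lapply(strsplit(trimws(vl), "\\s+"),
                                       function(x) x[2:4]))),
              ncol = 3, byrow = TRUE)
  fp <- strsplit(trimws(fl), "\\s+")
  nvert <- lengths(fp) - 1L
  if (any(nvert != 3L))
    stop("non-triangular face in OBJ file at face ", which(nvert != 3L)[1])
  ## "f a/b/c ..." -> leading vertex index before any slash.
  idx <- vapply(fp, function(x) {
    as.integer(sub("/.*$", "", x[2:4]))
  }, integer(3))
  spine_mesh(v, t(idx))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    l <- readLines(con, n = 1)
    hdr <- c(hdr, l)
    if (identical(trimws(l), "end_header")) break
    if (length(hdr) > 500) stop("malformed PLY header: ", path)
  }
  fmt_line <- grep("^format", hdr, value = TRUE)[1]
  binary <- grepl("binary_little_endian", fmt_line)
  if (!binary && !grepl("ascii", fmt_line))
    stop("unsupported PLY format (big-endian): ", path)
  elem <- grep("^element", hdr)
  get_count <- function(name) {
    l <- grep(paste0("^element ", name), hdr, value = TRUE)[1]
    as.integer(strsplit(trimws(l), "\\s+")[[1]][3])
  }
  nv <- get_count("vertex"); nf <- get_count("face")
  ## Vertex property layout.
  vstart <- grep("^element vertex", hdr)
  vend <- min(c(elem[elem > vstart], length(hdr)))
  vprops <- grep("^property", hdr[(vstart + 1):(vend - 1)], value = TRUE)
  vtypes <- vapply(strsplit(vprops, "\\s+"), `[`, "", 2)
  vnames <- vapply(strsplit(vprops, "\\s+"), `[`, "", 3)
  sizes <- c(float = 4L, float32 = 4L, double = 8L, float64 = 8L,
             uchar = 1L, uint8 = 1L, char = 1L, int8 = 1L,
             short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
             int = 4L, uint = 4L, int32 = 4L, uint32 = 4L)
  if (binary) {
    nbytes <- sizes[vtypes]
    if (anyNA(nbytes)) stop("unsupported PLY vertex property type")
    raw_v <- readBin(con, "raw", n = nv * sum(nbytes))
    offs <- cumsum(c(0L, nbytes))
    stride <- sum(nbytes)
    readcol <- function(j) {
      bytes <- outer(seq_len(nbytes[j]) + offs[j],
                     (seq_len(nv) - 1L) * stride, `+`)
      what <- if (vtypes[j] %in% c("float", "float32", "double", "float64"))
        "double" else "integer"
      readBin(raw_v[as.vector(bytes)], what, n = nv, size = nbytes[j],
              endian = "little")
    }
    xyz <- vapply(match(c("x", "y", "z"), vnames), readcol, numeric(nv))
    ## Face list property: assume uchar count + 4-byte ints (most common).
    fl_line <- grep("^property list", hdr, value = TRUE)[1]
    parts <- strsplit(trimws(fl_line), "\\s+")[[1]]
    csz <- sizes[parts[3]]; isz <- sizes[parts[4]]
    f <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- readBin(con, "integer", n = 1, size = csz, endian = "little",
                     signed = csz > 1)
      if (cnt != 3L) stop("non-triangular face in PLY file at face ", i)
      f[i, ] <- readBin(con, "integer", n = 3, size = isz, endian = "little")
    }
    spine_mesh(xyz, f + 1L)
  } else {
    ln <- readLines(con, warn = FALSE)
    ln <- trimws(ln); ln <- ln[nzchar(ln)]
    vl <- strsplit(ln[seq_len(nv)], "\\s+")
    xi <- match(c("x", "y", "z"), vnames)
    v <- t(vapply(vl, function(x) as.numeric(x[xi]), numeric(3)))
    fp <- strsplit(ln[nv + seq_len(nf)], "\\s+")
    nvert <- vapply(fp, function(x) as.integer(x[1]), integer(1))
    if (any(nvert != 3L))
      stop("non-triangular face in PLY file at face ", which(nvert != 3L)[1])
    f <- t(vapply(fp, function(x) as.integer(x[2:4]), integer(3))) + 1L
    spine_mesh(v, f)
  }
}

read_stl <- function(path) {
  ## Sniff ascii vs binary: ascii files start with "solid" AND contain
  ## "facet" early on; binary files have an 80-byte header + uint32 count.
  head_raw <- readBin(path, "raw", n = 512)
  head_txt <- rawToChar(head_raw[head_raw != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", head_txt) && grepl("facet", head_txt)
  if (is_ascii) {
    ln <- trimws(readLines(path, warn = FALSE))
    vl <- ln[startsWith(ln, "vertex")]
    v <- matrix(as.numeric(unlist(lapply(strsplit(vl, "\\s+"),
                                         function(x) x[2:4]))),
                ncol = 3, byrow = TRUE)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    rec <- readBin(con, "raw", n = nf * 50)
    idx <- rep((seq_len(nf) - 1L) * 50L, each = 36L) +
      rep(12L + seq_len(36L), times = nf)
    coords <- readBin(rec[idx], "double", n = nf * 9L, size = 4,
                      endian = "little")
    v <- matrix(coords, ncol = 3, byrow = TRUE)
  }
  if (nrow(v) %% 3 != 0) stop("malformed STL: vertex count not divisible by 3")
  spine_mesh(v, matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE))
}

#' Read spine insertion points
#'
#' Insertion points — the marked positions where each spine emerges from its
#' dendritic shaft — live in a sidecar CSV with header `spine_id,x,y,z`
#' (coordinates in micrometres).
#'
#' @param path CSV path.
#' @return a data.frame with columns `spine_id`, `x`, `y`, `z`.
#' @export
read_insertion_points <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("spine_id", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("insertion-point CSV must have header spine_id,x,y,z")
  if (anyDuplicated(df$spine_id))
    stop("duplicate spine_id in insertion-point table")
  df[need]
}

#' @rdname read_insertion_points
#' @param df data.frame with columns `spine_id`, `x`, `y`, `z`.
#' @export
write_insertion_points <- function(df, path) {
  write.csv(df[c("spine_id", "x", "y", "z")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read per-spine metadata
#'
#' Optional sidecar CSV with header `spine_id,compartment,age,distance_um`
#' (dendritic compartment apical/basal, age group, distance from soma).
#'
#' @param path CSV path.
#' @return a data.frame.
#' @export
read_spine_metadata <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"spine_id" %in% names(df))
    stop("metadata CSV must have a spine_id column")
  df
}

#' Assemble spine records from a mesh directory and sidecar tables
#'
#' Pairs each mesh file in `mesh_dir` (basename = spine_id) with its
#' insertion point and optional metadata row. Insertion points further than
#' `detach_tol` from the nearest mesh vertex are flagged `detached`.
#'
#' @param mesh_dir directory of mesh files.
#' @param insertions data.frame from [read_insertion_points()] or a CSV path.
#' @param metadata optional data.frame or CSV path.
#' @param detach_tol surface tolerance (micrometres) beyond which an
#'   insertion point counts as detached.
#' @return a list of records, each with `spine_id`, `mesh`, `insertion`
#'   (3-vector), `detached` flag and `metadata` row (or `NULL`).
#' @export
read_spine_records <- function(mesh_dir, insertions, metadata = NULL,
                               detach_tol = 0.15) {
  if (is.character(insertions)) insertions <- read_insertion_points(insertions)
  if (is.character(metadata)) metadata <- read_spine_metadata(metadata)
  files <- list.files(mesh_dir, "\\.(ply|obj|off|stl)$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0) stop("no mesh files found in ", mesh_dir)
  ids <- tools::file_path_sans_ext(basename(files))
  if (anyDuplicated(ids)) stop("duplicate spine_id among mesh files")
  lapply(seq_along(files), function(i) {
    mesh <- read_mesh(files[i])
    row <- insertions[insertions$spine_id == ids[i], , drop = FALSE]
    if (nrow(row) == 0) stop("no insertion point for spine ", ids[i])
    ins <- as.numeric(row[1, c("x", "y", "z")])
    d2 <- colSums((t(mesh$vertices) - ins)^2)
    md <- if (!is.null(metadata))
      metadata[metadata$spine_id == ids[i], , drop = FALSE] else NULL
    list(spine_id = ids[i], mesh = mesh, insertion = ins,
         detached = sqrt(min(d2)) > detach_tol,
         metadata = if (!is.null(md) && nrow(md)) md else NULL)
  })
}
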