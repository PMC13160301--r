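# Mesh and point-cloud file I/O. STL (binary and ASCII) is the canonical
# mesh format; ASCII PLY is canonical for clouds (it preserves labels);
# CSV (x,y,z[,label]) is accepted for small fixtures.

#' Write a triangle mesh to STL
#'
#' @param mesh A `triangle_mesh`.
#' @param path Output path.
#' @param ascii Write ASCII STL instead of binary (default `FALSE`).
#' @export
write_mesh <- function(mesh, path, ascii = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  V <- mesh$vertices; Fm <- mesh$faces
  nrm <- face_normals(mesh)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid pednav", con)
    for (f in seq_len(nrow(Fm))) {
      writeLines(sprintf("  facet normal %.9e %.9e %.9e", nrm[f, 1], nrm[f, 2], nrm[f, 3]), con)
      writeLines("    outer loop", con)
      for (k in 1:3) {
        v <- V[Fm[f, k], ]
        writeLines(sprintf("      vertex %.9e %.9e %.9e", v[1], v[2], v[3]), con)
      }
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid pednav", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(formatC("pednav binary STL", width = -80))
    writeBin(header[1:80], con)
    writeBin(as.integer(nrow(Fm)), con, size = 4, endian = "little")
    for (f in seq_len(nrow(Fm))) {
      writeBin(as.numeric(nrm[f, ]), con, size = 4, endian = "little")
      for (k in 1:3)
        writeBin(as.numeric(V[Fm[f, k], ]), con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}

#' Read a triangle mesh from STL (binary or ASCII)
#'
#' Duplicated facet corners are welded into shared vertices (exact
#' coordinate match), so a cube read back has 8 unique vertices.
#'
#' @param path Input path.
#' @return A `triangle_mesh`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stopf("mesh file not found: %s", path)
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = 80)
  close(con)
  txt <- rawToChar(head[head != as.raw(0)])
  tris <- if (grepl("^\\s*solid", txt) && is_ascii_stl(path))
    read_stl_ascii(path) else read_stl_binary(path)
  weld_vertices(tris)
}

# A file starting with "solid" may still be binary; check for "facet".
is_ascii_stl <- function(path) {
  lines <- tryCatch(readLines(path, n = 5L, warn = FALSE), error = function(e) character(0))
  any(grepl("facet", lines))
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (!length(nf) || nf < 0) stopf("malformed binary STL '%s': bad facet count", path)
  # each 50-byte record: normal (3 floats), 3 vertices (9 floats), 2 attribute bytes
  tri <- matrix(0, nf * 3, 3)
  for (f in seq_len(nf)) {
    vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    readBin(con, "raw", n = 2)
    if (length(vals) < 12) stopf("malformed binary STL '%s': truncated facet %d", path, f)
    tri[(f - 1) * 3 + 1:3, ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  tri
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines)
  if (!length(vl)) stopf("malformed ASCII STL '%s': no vertex records", path)
  parts <- strsplit(trimws(lines[vl]), "\\s+")
  bad <- which(vapply(parts, length, 1L) != 4L)
  if (length(bad))
    stopf("malformed ASCII STL '%s': bad vertex record at line %d", path, vl[bad[1]])
  tri <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (any(!is.finite(tri)))
    stopf("malformed ASCII STL '%s': non-numeric vertex coordinate", path)
  if (nrow(tri) %% 3 != 0) stopf("malformed ASCII STL '%s': vertex count not divisible by 3", path)
  tri
}

# Collapse exactly-repeated corner coordinates into shared vertices.
weld_vertices <- function(tri) {
  key <- apply(tri, 1, function(v) paste(format(v, digits = 17), collapse = ","))
  idx <- match(key, unique(key))
  V <- tri[!duplicated(key), , drop = FALSE]
  Fm <- matrix(idx, ncol = 3, byrow = TRUE)
  triangle_mesh(V, Fm)
}

#' Write a point cloud (ASCII PLY or CSV)
#'
#' Format chosen by extension: `.ply` or `.csv`. Labels are preserved in
#' both; PLY stores them as an integer property with the label dictionary
#' in header comments.
#'
#' @param cloud A `point_cloud`.
#' @param path Output path.
#' @export
write_cloud <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- as.data.frame(cloud$points)
    names(df) <- c("x", "y", "z")
    if (!is.null(cloud$labels)) df$label <- cloud$labels
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (ext == "ply") {
    n <- n_points(cloud)
    has_lab <- !is.null(cloud$labels)
    has_nrm <- !is.null(cloud$normals)
    lev <- if (has_lab) unique(cloud$labels) else character(0)
    hdr <- c("ply", "format ascii 1.0",
             if (has_lab) sprintf("comment label %d %s", seq_along(lev) - 1L, lev),
             sprintf("element vertex %d", n),
             "property double x", "property double y", "property double z",
             if (has_nrm) c("property double nx", "property double ny", "property double nz"),
             if (has_lab) "property int label",
             "end_header")
    body <- cloud$points
    if (has_nrm) body <- cbind(body, cloud$normals)
    lines <- if (n > 0) {
      rows <- apply(body, 1, function(r) paste(format(r, digits = 17, trim = TRUE, scientific = FALSE), collapse = " "))
      if (has_lab) paste(rows, match(cloud$labels, lev) - 1L) else rows
    } else character(0)
    writeLines(c(hdr, lines), path)
  } else stopf("unsupported cloud format '.%s' (use .ply or .csv)", ext)
  invisible(path)
}

#' Read a point cloud (ASCII PLY or CSV)
#' @param path Input path.
#' @return A `point_cloud`.
#' @export
read_cloud <- function(path) {
  if (!file.exists(path)) stopf("cloud file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- read.csv(path)
    need <- c("x", "y", "z")
    if (!all(need %in% names(df))) stopf("malformed cloud CSV '%s': need x,y,z columns", path)
    num <- suppressWarnings(vapply(df[need], function(v) as.numeric(as.character(v)),
                                   numeric(nrow(df))))
    num <- matrix(num, ncol = 3)
    bad <- which(rowSums(!is.finite(num)) > 0)
    if (length(bad)) stopf("malformed cloud CSV '%s': non-numeric row at line %d", path, bad[1] + 1L)
    point_cloud(num,
                labels = if ("label" %in% names(df)) as.character(df$label))
  } else if (ext == "ply") {
    lines <- readLines(path, warn = FALSE)
    end <- match("end_header", lines)
    if (is.na(end)) stopf("malformed PLY '%s': no end_header", path)
    hdr <- lines[seq_len(end)]
    nv <- as.integer(sub("element vertex\\s+", "", grep("^element vertex", hdr, value = TRUE)[1]))
    props <- sub("^property\\s+\\S+\\s+", "", grep("^property", hdr, value = TRUE))
    labmap <- grep("^comment label ", hdr, value = TRUE)
    lev <- if (length(labmap)) {
      parts <- strsplit(labmap, " ")
      stats::setNames(vapply(parts, `[`, "", 4L), vapply(parts, `[`, "", 3L))
    }
    body <- lines[seq(end + 1L, length.out = nv)]
    vals <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(vals, length, 1L) != length(props))
    if (length(bad)) stopf("malformed PLY '%s': bad row at line %d", path, end + bad[1])
    m <- t(vapply(vals, as.numeric, numeric(length(props))))
    if (nv == 1L) m <- matrix(m, 1L)
    col <- function(p) if (p %in% props) m[, match(p, props)] else NULL
    pts <- cbind(col("x"), col("y"), col("z"))
    nrm <- if ("nx" %in% props) cbind(col("nx"), col("ny"), col("nz"))
    labs <- if ("label" %in% props) unname(lev[as.character(as.integer(col("label")))])
    point_cloud(if (is.null(pts)) matrix(numeric(0), 0, 3) else pts,
                labels = labs, normals = nrm)
  } else stopf("unsupported cloud format '.%s' (use .ply or .csv)", ext)
}
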