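#' Read a colored triangle mesh from OBJ or PLY
#'
#' Supports Wavefront OBJ (with the common `v x y z r g b` per-vertex color
#' extension) and PLY in `ascii` or `binary_little_endian` form with
#' properties `x,y,z` (float or double) and optional `red,green,blue`
#' (uchar or float). Files without color default to mid-gray
#' `(0.5, 0.5, 0.5)`; the filler flag is initialized all-`FALSE`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"obj"` or `"ply"`.
#' @return a [colored_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "obj", "ply")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.obj$", path, ignore.case = TRUE)) "obj" else "ply"
  if (format == "obj") read_obj(path) else read_ply(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (!length(vlines)) stop("OBJ file has no vertices: ", path)
  vtok <- strsplit(trimws(sub("^v ", "", vlines)), "[[:space:]]+")
  nv <- lengths(vtok)
  verts <- t(vapply(vtok, function(t) as.numeric(t[1:3]), numeric(3)))
  color <- NULL
  if (all(nv >= 6))
    color <- t(vapply(vtok, function(t) as.numeric(t[4:6]), numeric(3)))
  faces <- NULL
  if (length(flines)) {
    ftok <- strsplit(trimws(sub("^f ", "", flines)), "[[:space:]]+")
    idx <- lapply(ftok, function(t) as.integer(sub("/.*$", "", t)))
    if (any(lengths(idx) != 3))
      stop("OBJ reader supports triangles only (face ",
           which(lengths(idx) != 3)[1], ")")
    faces <- do.call(rbind, idx)
    bad <- which(faces < 1L | faces > nrow(verts))
    if (length(bad))
      stop("OBJ face ", ((bad[1] - 1L) %% nrow(faces)) + 1L,
           " references a missing vertex")
  }
  colored_mesh(verts, faces %||% matrix(integer(0), 0, 3), color)
}

ply_prop_size <- function(type) {
  switch(type,
         char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
         short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
         int = 4L, uint = 4L, int32 = 4L, uint32 = 4L, float = 4L,
         float32 = 4L, double = 8L, float64 = 8L,
         stop("unsupported PLY property type: ", type))
}

ply_read_column <- function(raw, offsets, type) {
  size <- ply_prop_size(type)
  sel <- as.vector(outer(0:(size - 1L), offsets, `+`))
  bytes <- raw[sel]
  what <- if (type %in% c("float", "float32", "double", "float64"))
    "double" else "integer"
  signed <- !(type %in% c("uchar", "uint8", "ushort", "uint16", "uint", "uint32"))
  readBin(bytes, what, n = length(offsets), size = size,
          signed = if (size >= 4) TRUE else signed, endian = "little")
}

read_ply <- function(path) {
  allraw <- readBin(path, "raw", n = file.size(path))
  off <- grepRaw("end_header", allraw, fixed = TRUE)
  if (!length(off)) stop("PLY header not terminated: ", path)
  nl_rel <- which(allraw[off[1]:length(allraw)] == as.raw(10L))[1]
  if (is.na(nl_rel)) stop("PLY header not terminated: ", path)
  nl <- off[1] + nl_rel - 1L
  header <- strsplit(rawToChar(allraw[1:nl]), "\r?\n")[[1]]
  payload <- if (nl < length(allraw)) allraw[(nl + 1L):length(allraw)] else raw(0)
  if (!grepl("^ply", header[1])) stop("not a PLY file: ", path)
  fmt_line <- grep("^format ", header, value = TRUE)[1]
  binary <- grepl("binary_little_endian", fmt_line)
  if (!binary && !grepl("ascii", fmt_line))
    stop("unsupported PLY format: ", fmt_line)

  elements <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[tok[5]]] <- list(list = TRUE, count_type = tok[3],
                                    item_type = tok[4])
      } else {
        cur$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex)) stop("PLY file has no vertex element: ", path)

  parse_tables <- list()
  if (binary) {
    pos <- 1L
    for (el in elements) {
      pn <- names(el$props)
      if (!any(vapply(el$props, `[[`, TRUE, "list"))) {
        sizes <- vapply(pn, function(p) ply_prop_size(el$props[[p]]$type), 1L)
        stride <- sum(sizes)
        starts <- pos + stride * (seq_len(el$count) - 1L)
        cols <- list()
        off <- 0L
        for (p in pn) {
          cols[[p]] <- ply_read_column(payload, starts + off,
                                       el$props[[p]]$type)
          off <- off + ply_prop_size(el$props[[p]]$type)
        }
        parse_tables[[el$name]] <- cols
        pos <- pos + stride * el$count
      } else {
        # list element (faces)
        if (length(el$props) != 1)
          stop("PLY list elements with extra properties unsupported")
        p <- el$props[[1]]
        csize <- ply_prop_size(p$count_type)
        isize <- ply_prop_size(p$item_type)
        stride <- csize + 3L * isize
        uniform <- csize == 1L && el$count > 0 &&
          length(payload) - pos + 1L >= stride * el$count &&
          all(payload[pos + stride * (seq_len(el$count) - 1L)] == as.raw(3L))
        if (uniform) {
          starts <- pos + stride * (seq_len(el$count) - 1L) + 1L
          cols <- lapply(0:2, function(k)
            ply_read_column(payload, starts + k * isize, p$item_type))
          rows <- lapply(seq_len(el$count), function(i)
            c(cols[[1]][i], cols[[2]][i], cols[[3]][i]))
          pos <- pos + stride * el$count
        } else {
          rows <- vector("list", el$count)
          for (i in seq_len(el$count)) {
            cnt <- ply_read_column(payload, pos, p$count_type)
            pos <- pos + csize
            idx <- readBin(payload[pos:(pos + cnt * isize - 1L)],
                           if (p$item_type %in% c("float", "double")) "double"
                           else "integer",
                           n = cnt, size = isize, endian = "little")
            pos <- pos + cnt * isize
            rows[[i]] <- idx
          }
        }
        parse_tables[[el$name]] <- rows
      }
    }
  } else {
    body <- strsplit(rawToChar(payload), "\r?\n")[[1]]
    body <- body[nzchar(trimws(body))]
    at <- 1L
    for (el in elements) {
      chunk <- body[at:(at + el$count - 1L)]
      at <- at + el$count
      toks <- strsplit(trimws(chunk), "[[:space:]]+")
      if (!any(vapply(el$props, `[[`, TRUE, "list"))) {
        m <- do.call(rbind, lapply(toks, as.numeric))
        cols <- list()
        for (k in seq_along(el$props)) cols[[names(el$props)[k]]] <- m[, k]
        parse_tables[[el$name]] <- cols
      } else {
        parse_tables[[el$name]] <- lapply(toks, function(t)
          as.numeric(t[-1]))
      }
    }
  }

  vtab <- parse_tables$vertex
  verts <- cbind(vtab$x, vtab$y, vtab$z)
  color <- NULL
  if (all(c("red", "green", "blue") %in% names(vtab))) {
    color <- cbind(vtab$red, vtab$green, vtab$blue)
    rtype <- elements$vertex$props$red$type
    if (rtype %in% c("uchar", "uint8", "char", "int8")) color <- color / 255
  }
  faces <- matrix(integer(0), 0, 3)
  if (!is.null(parse_tables$face)) {
    rows <- parse_tables$face
    if (any(lengths(rows) != 3))
      stop("PLY reader supports triangles only (face ",
           which(lengths(rows) != 3)[1], ")")
    faces <- do.call(rbind, rows) + 1L  # PLY is 0-based
    bad <- which(faces < 1L | faces > nrow(verts))
    if (length(bad))
      stop("PLY face ", ((bad[1] - 1L) %% nrow(faces)) + 1L,
           " references a missing vertex")
  }
  colored_mesh(verts, faces, color)
}

#' Write a colored triangle mesh to OBJ or PLY
#'
#' PLY is written as `binary_little_endian` with double-precision
#' coordinates and uchar RGB (or `ascii` with full-precision coordinates),
#' so `read_mesh(write_mesh(m))` reproduces vertices and faces exactly and
#' colors within 1/255 per channel. OBJ uses the `v x y z r g b` color
#' extension.
#'
#' @param mesh a [colored_mesh()].
#' @param path output file path.
#' @param format `"auto"` (by extension), `"obj"` or `"ply"`.
#' @param binary logical; write binary PLY (default) or ascii.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "obj", "ply"),
                       binary = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.obj$", path, ignore.case = TRUE)) "obj" else "ply"
  ok <- tryCatch({
    if (format == "obj") write_obj(mesh, path) else
      write_ply(mesh, path, binary)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write mesh to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  col <- mesh$color
  writeLines(sprintf("v %.17g %.17g %.17g %.6f %.6f %.6f",
                     v[, 1], v[, 2], v[, 3], col[, 1], col[, 2], col[, 3]),
             con)
  if (nrow(mesh$faces))
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3]), con)
}

write_ply <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices
  col <- round(clamp(mesh$color, 0, 1) * 255)
  f0 <- mesh$faces - 1L
  header <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    sprintf("element vertex %d", nrow(v)),
    "property double x", "property double y", "property double z",
    "property uchar red", "property uchar green", "property uchar blue",
    sprintf("element face %d", nrow(f0)),
    "property list uchar int vertex_indices",
    "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0(paste(header, collapse = "\n"), "\n"), con,
              eos = NULL)
    if (nrow(v)) {
      dbytes <- matrix(writeBin(as.double(t(v)), raw(), size = 8,
                                endian = "little"), nrow = 24)
      cbytes <- matrix(as.raw(t(col)), nrow = 3)
      writeBin(as.vector(rbind(dbytes, cbytes)), con)
    }
    if (nrow(f0)) {
      ibytes <- matrix(writeBin(as.integer(t(f0)), raw(), size = 4,
                                endian = "little"), nrow = 12)
      cnt <- matrix(rep(as.raw(3L), ncol(ibytes)), nrow = 1)
      writeBin(as.vector(rbind(cnt, ibytes)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(sprintf("%.17g %.17g %.17g %d %d %d",
                       v[, 1], v[, 2], v[, 3], col[, 1], col[, 2], col[, 3]),
               con)
    if (nrow(f0))
      writeLines(sprintf("3 %d %d %d", f0[, 1], f0[, 2], f0[, 3]), con)
  }
}

#' Read or write a curve set (named polylines of vertex indices)
#'
#' Curve sets are stored as a JSON sidecar mapping curve names to arrays of
#' 1-based vertex indices on one mesh.
#'
#' @param path JSON file path.
#' @return named list of integer vectors, class `curve_set`.
#' @export
read_curves <- function(path) {
  if (!file.exists(path)) stop("cannot read curve file: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  curves <- lapply(raw, as.integer)
  validate_curves(curves)
  structure(curves, class = "curve_set")
}

#' @rdname read_curves
#' @param curves named list of integer vertex-index vectors.
#' @export
write_curves <- function(curves, path) {
  jsonlite::write_json(lapply(curves, as.integer), path)
  invisible(path)
}

validate_curves <- function(curves) {
  if (is.null(names(curves)) || anyDuplicated(names(curves)))
    stop("curve names must be present and unique")
  short <- vapply(curves, function(cv) length(unique(cv)) < 2, TRUE)
  if (any(short)) stop("curve '", names(curves)[short][1],
                       "' has fewer than 2 distinct vertices")
  invisible(curves)
}
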