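#' Read a PLY point cloud
#'
#' Supports ascii and binary-little-endian PLY with float32/float64 vertex
#' properties. Point order is preserved; optional `nx, ny, nz` normals and a
#' uchar `label` property are returned when present. Unknown elements are
#' skipped with a warning; a big-endian declaration is an explicit error
#' rather than a silent misread.
#'
#' @param path PLY file.
#' @return N x 3 matrix of points (mm), with attributes `normals` and
#'   `labels` when present.
#' @export
read_ply <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "ply")) stop("format error (line 1): not a PLY file")
  fmt <- NULL
  elements <- list()   # list of list(name, count, props = data.frame)
  cur <- NULL
  lineno <- 1L
  repeat {
    ln <- readLines(con, n = 1L)
    lineno <- lineno + 1L
    if (!length(ln)) stop("format error: header ended before end_header")
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!length(tok) || tok[1] == "comment") next
    if (tok[1] == "format") {
      if (tok[2] == "binary_big_endian") {
        stop("unsupported-dialect: binary_big_endian PLY is not supported")
      }
      if (!tok[2] %in% c("ascii", "binary_little_endian")) {
        stop(sprintf("format error (line %d): unknown format '%s'", lineno, tok[2]))
      }
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[length(elements) + 1L]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  types = character(0), names = character(0), list = logical(0))
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop(sprintf("format error (line %d): property before element", lineno))
      if (tok[2] == "list") {
        cur$list <- c(cur$list, TRUE)
        cur$types <- c(cur$types, paste(tok[3], tok[4]))
        cur$names <- c(cur$names, tok[5])
      } else {
        cur$list <- c(cur$list, FALSE)
        cur$types <- c(cur$types, tok[2])
        cur$names <- c(cur$names, tok[3])
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[length(elements) + 1L]] <- cur
      break
    } else {
      stop(sprintf("format error (line %d): unexpected header token '%s'",
                   lineno, tok[1]))
    }
  }
  if (is.null(fmt)) stop("format error: missing format declaration")
  type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                 short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                 int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                 float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  vertex <- NULL
  for (el in elements) {
    if (el$name != "vertex") {
      warning("skipping unknown PLY element '", el$name, "'")
      if (fmt == "ascii") {
        readLines(con, n = el$count)
      } else {
        if (any(el$list)) stop("format error: cannot skip binary list element")
        per_row <- sum(type_size[el$types])
        invisible(readBin(con, "raw", n = el$count * per_row))
      }
      next
    }
    np <- length(el$names)
    if (fmt == "ascii") {
      lines <- readLines(con, n = el$count)
      vals <- matrix(as.numeric(unlist(strsplit(trimws(lines), "\\s+"))),
                     ncol = np, byrow = TRUE)
    } else {
      sizes <- unname(type_size[el$types])
      per_row <- sum(sizes)
      raw_all <- readBin(con, "raw", n = el$count * per_row)
      if (length(raw_all) < el$count * per_row) {
        stop("format error: truncated binary vertex data")
      }
      offs <- cumsum(c(0L, sizes))
      vals <- matrix(0, nrow = el$count, ncol = np)
      row_starts <- seq(0L, by = per_row, length.out = el$count)
      for (j in seq_len(np)) {
        idx <- rep(row_starts, each = sizes[j]) + offs[j] +
          seq_len(sizes[j])
        col_raw <- raw_all[idx]
        tj <- el$types[j]
        vals[, j] <- if (tj %in% c("float", "float32")) {
          readBin(col_raw, "numeric", n = el$count, size = 4L,
                  endian = "little")
        } else if (tj %in% c("double", "float64")) {
          readBin(col_raw, "numeric", n = el$count, size = 8L,
                  endian = "little")
        } else if (sizes[j] == 1L) {
          readBin(col_raw, "integer", n = el$count, size = 1L,
                  signed = FALSE, endian = "little")
        } else {
          readBin(col_raw, "integer", n = el$count, size = sizes[j],
                  endian = "little")
        }
      }
    }
    colnames(vals) <- el$names
    vertex <- vals
  }
  if (is.null(vertex)) stop("format error: no vertex element")
  if (!all(c("x", "y", "z") %in% colnames(vertex))) {
    stop("format error: vertex element lacks x, y, z")
  }
  pts <- unname(vertex[, c("x", "y", "z"), drop = FALSE])
  if (all(c("nx", "ny", "nz") %in% colnames(vertex))) {
    attr(pts, "normals") <- unname(vertex[, c("nx", "ny", "nz"), drop = FALSE])
  }
  if ("label" %in% colnames(vertex)) {
    attr(pts, "labels") <- as.integer(vertex[, "label"])
  }
  pts
}

#' Write a PLY point cloud
#'
#' Binary-little-endian (default) stores coordinates as float64 so that a
#' write/read cycle is bit-exact; ascii uses full decimal precision.
#'
#' @param path output file.
#' @param points N x 3 matrix (mm).
#' @param normals optional N x 3 matrix.
#' @param labels optional integer vector (0..255), stored as uchar.
#' @param binary write binary (default) or ascii.
#' @return Invisibly, the path.
#' @export
write_ply <- function(path, points, normals = NULL, labels = NULL,
                      binary = TRUE) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  n <- nrow(points)
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", n),
           "property double x", "property double y", "property double z")
  if (!is.null(normals)) {
    hdr <- c(hdr, "property double nx", "property double ny",
             "property double nz")
  }
  if (!is.null(labels)) hdr <- c(hdr, "property uchar label")
  hdr <- c(hdr, "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  block <- points
  if (!is.null(normals)) block <- cbind(block, as.matrix(normals))
  if (binary) {
    if (is.null(labels)) {
      writeBin(as.numeric(t(block)), con, size = 8L, endian = "little")
    } else {
      for (i in seq_len(n)) {
        writeBin(as.numeric(block[i, ]), con, size = 8L, endian = "little")
        writeBin(as.raw(labels[i]), con)
      }
    }
  } else {
    for (i in seq_len(n)) {
      row <- sprintf("%.17g", block[i, ])
      if (!is.null(labels)) row <- c(row, sprintf("%d", labels[i]))
      writeLines(paste(row, collapse = " "), con)
    }
  }
  invisible(path)
}
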