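#' Point-cloud container
#'
#' A point cloud is an ordered collection of 3D points in metres, optionally
#' carrying a per-point label (\code{"pig"}, \code{"floor"}, \code{"railing"},
#' \code{"noise"}, or cube face names). All geometry operations in the package
#' take and return this container.
#'
#' @param xyz numeric matrix (or coercible) with three columns x, y, z in
#'   metres. The global convention is x = body axis (anterior to posterior),
#'   y = lateral, z = vertical up.
#' @param labels optional character vector, one label per point.
#' @return an object of class \code{point_cloud}: a list with elements
#'   \code{xyz} (n x 3 double matrix) and \code{labels} (character or NULL).
#' @export
point_cloud <- function(xyz, labels = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L)
    stop("invalid parameter: 'xyz' must have exactly three columns")
  storage.mode(xyz) <- "double"
  colnames(xyz) <- c("x", "y", "z")
  if (!is.null(labels)) {
    if (length(labels) != nrow(xyz))
      stop("invalid parameter: one label per point required")
    labels <- as.character(labels)
  }
  structure(list(xyz = xyz, labels = labels), class = "point_cloud")
}

#' @export
is_point_cloud <- function(x) inherits(x, "point_cloud")

#' Number of points in a cloud
#' @param cloud a \code{point_cloud}.
#' @export
n_points <- function(cloud) nrow(cloud$xyz)

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud with %d points", n_points(x)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

# coerce matrices transparently where convenient
as_point_cloud <- function(x) {
  if (is_point_cloud(x)) x else point_cloud(x)
}

#' Subset a point cloud by index, keeping labels aligned
#' @param cloud a \code{point_cloud}.
#' @param idx integer or logical index into the points.
#' @export
subset_points <- function(cloud, idx) {
  point_cloud(cloud$xyz[idx, , drop = FALSE],
              if (!is.null(cloud$labels)) cloud$labels[idx])
}

#' Concatenate point clouds
#'
#' Labels are kept only if every cloud carries them.
#' @param ... \code{point_cloud} objects.
#' @export
bind_clouds <- function(...) {
  clouds <- list(...)
  if (length(clouds) == 1L && is.list(clouds[[1]]) && !is_point_cloud(clouds[[1]]))
    clouds <- clouds[[1]]
  xyz <- do.call(rbind, lapply(clouds, function(cl) cl$xyz))
  labs <- lapply(clouds, function(cl) cl$labels)
  labels <- if (all(!vapply(labs, is.null, logical(1)))) unlist(labs) else NULL
  point_cloud(xyz, labels)
}

# ---- PLY and XYZ serialization --------------------------------------------

# Minimal PLY writer: vertex element with double x/y/z and an optional int
# label property (label dictionary kept in header comments). Supports the
# ascii and binary_little_endian dialects.

#' Write a point cloud to a PLY file
#'
#' @param cloud a \code{point_cloud}.
#' @param path output file path.
#' @param format \code{"ascii"} or \code{"binary_little_endian"}.
#' @export
write_ply <- function(cloud, path, format = c("ascii", "binary_little_endian")) {
  format <- match.arg(format)
  n <- n_points(cloud)
  has_lab <- !is.null(cloud$labels)
  header <- c("ply", sprintf("format %s 1.0", format),
              "comment written by porcimetry")
  codes <- NULL
  if (has_lab) {
    levs <- sort(unique(cloud$labels))
    codes <- match(cloud$labels, levs) - 1L
    header <- c(header,
                sprintf("comment label %d %s", seq_along(levs) - 1L, levs))
  }
  header <- c(header,
              sprintf("element vertex %d", n),
              "property double x", "property double y", "property double z",
              if (has_lab) "property int label",
              "end_header")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con)
  if (format == "ascii") {
    rows <- sprintf("%.17g %.17g %.17g",
                    cloud$xyz[, 1], cloud$xyz[, 2], cloud$xyz[, 3])
    if (has_lab) rows <- paste(rows, codes)
    writeLines(rows, con)
  } else {
    coord <- writeBin(as.vector(t(cloud$xyz)), raw(), size = 8L,
                      endian = "little")
    if (has_lab) {
      lab <- writeBin(codes, raw(), size = 4L, endian = "little")
      body <- as.vector(rbind(matrix(coord, nrow = 24L),
                              matrix(lab, nrow = 4L)))
    } else body <- coord
    writeBin(body, con)
  }
  invisible(path)
}

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

#' Read a point cloud from a PLY file
#'
#' Reads x/y/z (float or double) and an optional integer \code{label}
#' property from the vertex element; other properties are skipped.
#' @param path file path.
#' @export
read_ply <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("invalid PLY: missing end_header")
    header <- c(header, line)
    if (line == "end_header") break
  }
  if (header[1] != "ply") stop("not a PLY file")
  fmt <- sub("^format\\s+(\\S+).*$", "\\1", grep("^format", header, value = TRUE))
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", header, value = TRUE)))
  # properties of the vertex element (the only element this writer emits)
  vstart <- grep("^element vertex", header)
  vend <- c(grep("^element", header), grep("^end_header", header))
  vend <- min(vend[vend > vstart])
  props <- grep("^property", header[(vstart + 1):(vend - 1)], value = TRUE)
  parts <- strsplit(props, "\\s+")
  ptype <- vapply(parts, `[`, "", 2L)
  pname <- vapply(parts, `[`, "", 3L)
  lab_levels <- NULL
  labcom <- grep("^comment label ", header, value = TRUE)
  if (length(labcom)) {
    toks <- strsplit(labcom, "\\s+")
    lab_levels <- vapply(toks, `[`, "", 4L)[order(as.integer(vapply(toks, `[`, "", 3L)))]
  }
  cols <- c("x", "y", "z", if ("label" %in% pname) "label")
  if (fmt == "ascii") {
    tab <- matrix(scan(con, what = double(), n = nv * length(pname),
                       quiet = TRUE),
                  ncol = length(pname), byrow = TRUE)
    vals <- lapply(cols, function(cn) tab[, match(cn, pname)])
  } else if (fmt == "binary_little_endian") {
    sizes <- ply_type_size[ptype]
    if (anyNA(sizes)) stop("unsupported PLY property type")
    stride <- sum(sizes)
    offs <- cumsum(c(0L, sizes[-length(sizes)]))
    body <- readBin(con, "raw", n = nv * stride)
    vals <- lapply(cols, function(cn) {
      j <- match(cn, pname)
      byte_idx <- as.vector(outer(seq_len(sizes[j]),
                                  (seq_len(nv) - 1L) * stride + offs[j], `+`))
      what <- if (ptype[j] %in% c("float", "float32", "double", "float64"))
        "double" else "integer"
      readBin(body[byte_idx], what, n = nv, size = sizes[j], endian = "little")
    })
  } else stop("unsupported PLY format: ", fmt)
  xyz <- cbind(vals[[1]], vals[[2]], vals[[3]])
  labels <- NULL
  if ("label" %in% cols) {
    codes <- as.integer(vals[[4]])
    labels <- if (!is.null(lab_levels)) lab_levels[codes + 1L] else as.character(codes)
  }
  point_cloud(xyz, labels)
}

#' Write a cloud as 3-column XYZ text
#' @export
#' @rdname read_xyz
write_xyz <- function(cloud, path) {
  utils::write.table(cloud$xyz, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write plain 3-column XYZ text clouds
#' @param cloud a \code{point_cloud}.
#' @param path file path.
#' @export
read_xyz <- function(path) {
  point_cloud(as.matrix(utils::read.table(path, col.names = c("x", "y", "z"))))
}

# seeded evaluation that does not disturb the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
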