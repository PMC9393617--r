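#' Build a point cloud tibble
#'
#' The in-memory currency of the package: a tibble with numeric columns
#' `x`, `y`, `z` (scene units before calibration, centimetres after) and
#' optional color columns `r`, `g`, `b` with each channel in `[0, 1]`.
#' Any further columns (e.g. a `component` label from the synthetic scene
#' generator) are carried along untouched by every filter in the pipeline.
#' A `frame` attribute records whether the cloud is still in the arbitrary
#' reconstruction frame (`"raw"`) or in real-world units with the ground at
#' Z = 0 (`"calibrated"`).
#'
#' Rows containing non-finite coordinates are dropped with a message:
#' multi-view-stereo exports occasionally contain invalid vertices.
#'
#' @param positions N x 3 numeric matrix or a data frame with columns x, y, z.
#' @param colors Optional N x 3 matrix of RGB channels in `[0, 1]`.
#' @param frame Either `"raw"` or `"calibrated"`.
#' @param ... Additional equal-length columns to carry (e.g. `component`).
#' @return A `point_cloud` tibble.
#' @export
#' @examples
#' pc <- point_cloud(matrix(rnorm(30), ncol = 3))
#' cloud_frame(pc)
point_cloud <- function(positions, colors = NULL, frame = c("raw", "calibrated"), ...) {
  frame <- match.arg(frame)
  if (is.data.frame(positions)) {
    stopifnot(all(c("x", "y", "z") %in% names(positions)))
    extra <- positions[setdiff(names(positions), c("x", "y", "z", "r", "g", "b"))]
    if (is.null(colors) && all(c("r", "g", "b") %in% names(positions))) {
      colors <- as.matrix(positions[c("r", "g", "b")])
    }
    positions <- as.matrix(positions[c("x", "y", "z")])
  } else {
    extra <- NULL
  }
  positions <- matrix(as.numeric(positions), ncol = 3,
                      dimnames = list(NULL, c("x", "y", "z")))
  dots <- list(...)
  df <- tibble(x = positions[, 1], y = positions[, 2], z = positions[, 3])
  if (!is.null(colors)) {
    colors <- matrix(as.numeric(colors), ncol = 3)
    if (nrow(colors) != nrow(positions)) {
      abort("`colors` must have one row per point.")
    }
    if (nrow(colors) > 0 && (min(colors) < 0 || max(colors) > 1)) {
      abort("color channels must lie in [0, 1].")
    }
    df$r <- colors[, 1]; df$g <- colors[, 2]; df$b <- colors[, 3]
  }
  if (!is.null(extra) && ncol(extra) > 0) df <- dplyr::bind_cols(df, as_tibble(extra))
  if (length(dots)) df <- dplyr::bind_cols(df, tibble::as_tibble(dots))
  bad <- !stats::complete.cases(df[c("x", "y", "z")]) |
    !is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z)
  if (any(bad)) {
    inform(sprintf("Dropped %d point(s) with non-finite coordinates.", sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  new_point_cloud(df, frame)
}

new_point_cloud <- function(df, frame) {
  df <- as_tibble(df)
  class(df) <- c("point_cloud", class(tibble()))
  attr(df, "frame") <- frame
  df
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("# A point cloud: %d points, frame = %s, colors: %s\n",
              nrow(x), cloud_frame(x), if (has_colors(x)) "yes" else "no"))
  NextMethod()
}

#' Frame tag of a point cloud
#' @param cloud A `point_cloud`.
#' @return `"raw"` or `"calibrated"`.
#' @export
cloud_frame <- function(cloud) attr(cloud, "frame") %||% "raw"

#' @rdname cloud_frame
#' @export
has_colors <- function(cloud) all(c("r", "g", "b") %in% names(cloud))

cloud_positions <- function(cloud) {
  cbind(x = cloud$x, y = cloud$y, z = cloud$z)
}

cloud_colors <- function(cloud) {
  if (!has_colors(cloud)) return(NULL)
  cbind(cloud$r, cloud$g, cloud$b)
}

assert_cloud <- function(cloud) {
  if (!inherits(cloud, "point_cloud")) {
    if (is.data.frame(cloud) && all(c("x", "y", "z") %in% names(cloud))) {
      return(point_cloud(cloud))
    }
    if (is.matrix(cloud) && ncol(cloud) == 3) return(point_cloud(cloud))
    abort("expected a `point_cloud` (or an x/y/z table).")
  }
  cloud
}

## keep the class and frame attribute through row subsetting done internally
cloud_subset <- function(cloud, idx, frame = cloud_frame(cloud)) {
  out <- as_tibble(cloud)[idx, , drop = FALSE]
  new_point_cloud(out, frame)
}

with_positions <- function(cloud, positions, frame = cloud_frame(cloud)) {
  out <- as_tibble(cloud)
  out$x <- positions[, 1]; out$y <- positions[, 2]; out$z <- positions[, 3]
  new_point_cloud(out, frame)
}

# ---- similarity transforms ---------------------------------------------

#' Similarity transform (scale, rotation, translation)
#'
#' Represents `p' = scale * R %*% p + translation`. The rotation must be a
#' proper orthonormal matrix (determinant +1).
#'
#' @param scale Positive scalar.
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation Length-3 numeric vector.
#' @return A `similarity_transform` object.
#' @export
#' @examples
#' t1 <- similarity_transform(scale = 2)
#' apply_transform(point_cloud(rbind(c(0, 0, 0), c(1, 0, 0))), t1)
similarity_transform <- function(scale = 1, rotation = diag(3), translation = c(0, 0, 0)) {
  scale <- as.numeric(scale)
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (length(scale) != 1 || !is.finite(scale) || scale <= 0) abort("`scale` must be a positive number.")
  if (length(translation) != 3 || any(!is.finite(translation))) abort("`translation` must be a finite 3-vector.")
  check_rotation(rotation)
  structure(list(scale = scale, rotation = rotation, translation = translation),
            class = "similarity_transform")
}

check_rotation <- function(R, tol = 1e-6) {
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol) {
    abort("`rotation` must be orthonormal with determinant +1.")
  }
  invisible(R)
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("similarity transform: scale %.6g, translation (%.4g, %.4g, %.4g)\n",
              x$scale, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a similarity transform to a point cloud
#'
#' @param cloud A `point_cloud`.
#' @param transform A [similarity_transform()].
#' @param frame Frame tag for the result; defaults to the input's tag.
#' @return The transformed cloud; colors and extra columns untouched.
#' @export
apply_transform <- function(cloud, transform, frame = cloud_frame(cloud)) {
  cloud <- assert_cloud(cloud)
  stopifnot(inherits(transform, "similarity_transform"))
  check_rotation(transform$rotation)
  P <- cloud_positions(cloud)
  P2 <- transform$scale * (P %*% t(transform$rotation))
  P2 <- sweep(P2, 2, transform$translation, "+")
  with_positions(cloud, P2, frame = frame)
}

#' Compose and invert similarity transforms
#'
#' `compose_transforms(t2, t1)` is the transform that applies `t1` first and
#' then `t2`.
#'
#' @param t2,t1,transform [similarity_transform()] objects.
#' @return A `similarity_transform`.
#' @export
compose_transforms <- function(t2, t1) {
  similarity_transform(
    scale = t2$scale * t1$scale,
    rotation = t2$rotation %*% t1$rotation,
    translation = t2$scale * as.numeric(t2$rotation %*% t1$translation) + t2$translation
  )
}

#' @rdname compose_transforms
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  similarity_transform(
    scale = 1 / transform$scale,
    rotation = Rt,
    translation = -as.numeric(Rt %*% transform$translation) / transform$scale
  )
}

#' Rotation helpers
#'
#' `rotation_about_axis()` builds the Rodrigues rotation matrix;
#' `rotation_aligning()` returns the minimal rotation taking unit vector
#' `from` onto unit vector `to`; `random_rotation()` draws a uniformly
#' distributed rotation from the current RNG stream.
#'
#' @param axis Length-3 axis (need not be unit length).
#' @param angle_deg Rotation angle in degrees.
#' @return A 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' @rdname rotation_about_axis
#' @param from,to Unit 3-vectors.
#' @export
rotation_aligning <- function(from, to) {
  f <- from / sqrt(sum(from^2)); t2 <- to / sqrt(sum(to^2))
  c_ <- sum(f * t2)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # pick any axis orthogonal to `from`
    ref <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- ref - sum(ref * f) * f
    return(rotation_about_axis(ax, 180))
  }
  v <- c(f[2] * t2[3] - f[3] * t2[2], f[3] * t2[1] - f[1] * t2[3], f[1] * t2[2] - f[2] * t2[1])
  K <- rbind(c(0, -v[3], v[2]), c(v[3], 0, -v[1]), c(-v[2], v[1], 0))
  diag(3) + K + K %*% K * (1 / (1 + c_))
}

#' @rdname rotation_about_axis
#' @export
random_rotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# ---- file I/O -----------------------------------------------------------

#' Read a colored point cloud
#'
#' Supports ASCII and binary-little-endian PLY (vertex element with `x`,
#' `y`, `z` and optional 8-bit `red`, `green`, `blue`), and whitespace
#' delimited XYZRGB text with 3 or 6 columns. 8-bit colors are rescaled to
#' `[0, 1]`.
#'
#' @param path File path.
#' @param format `"ply"` or `"xyzrgb"`; guessed from the extension by default.
#' @return A [point_cloud()].
#' @export
load_point_cloud <- function(path, format = c("auto", "ply", "xyzrgb")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyzrgb"
  }
  switch(format, ply = read_ply(path), xyzrgb = read_xyzrgb(path))
}

#' Write a point cloud
#'
#' PLY is written as ASCII (diffable, text-only); colors are stored as 8-bit
#' `uchar` channels when present. The declared write precision for
#' coordinates is 6 significant digits.
#'
#' @param cloud A [point_cloud()].
#' @param path Destination path.
#' @param format `"ply"` or `"xyzrgb"`.
#' @return `path`, invisibly.
#' @export
save_point_cloud <- function(cloud, path, format = c("auto", "ply", "xyzrgb")) {
  cloud <- assert_cloud(cloud)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyzrgb"
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) abort(sprintf("Directory does not exist: %s", dir))
  switch(format, ply = write_ply(cloud, path), xyzrgb = write_xyzrgb(cloud, path))
  invisible(path)
}

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(trimws(magic), "ply")) abort(sprintf("Not a PLY file (bad magic line): %s", path))
  fmt <- NULL; elements <- list(); cur <- NULL; lineno <- 1
  repeat {
    ln <- readLines(con, n = 1)
    lineno <- lineno + 1
    if (length(ln) == 0) abort(sprintf("PLY header ended prematurely at line %d", lineno))
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(count = as.integer(tok[3]), props = character(), types = character())
    } else if (tok[1] == "property") {
      if (is.null(cur)) abort(sprintf("PLY property before any element (line %d)", lineno))
      if (tok[2] == "list") {
        elements[[cur]]$props <- c(elements[[cur]]$props, tok[5])
        elements[[cur]]$types <- c(elements[[cur]]$types, paste("list", tok[3], tok[4]))
      } else {
        elements[[cur]]$props <- c(elements[[cur]]$props, tok[3])
        elements[[cur]]$types <- c(elements[[cur]]$types, tok[2])
      }
    } else if (tok[1] == "end_header") break
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian")) {
    abort(sprintf("Unsupported PLY format '%s' (ascii and binary_little_endian are accepted)", fmt %||% "?"))
  }
  if (!"vertex" %in% names(elements)) abort("PLY file has no vertex element")
  v <- elements$vertex
  if (any(grepl("^list", v$types))) abort("list properties on the vertex element are not supported")
  if (!all(c("x", "y", "z") %in% v$props)) abort("PLY vertex element lacks x/y/z properties")
  n <- v$count
  if (fmt == "ascii") {
    if (n == 0) {
      vals <- matrix(numeric(0), nrow = 0, ncol = length(v$props))
    } else {
      lines <- readLines(con, n = n)
      if (length(lines) < n) abort(sprintf("PLY: expected %d vertex rows, found %d", n, length(lines)))
      parts <- strsplit(trimws(lines), "\\s+")
      nf <- lengths(parts)
      if (any(nf < length(v$props))) {
        bad <- which(nf < length(v$props))[1]
        abort(sprintf("Malformed PLY vertex row at data line %d: '%s'", bad, lines[bad]))
      }
      vals <- matrix(suppressWarnings(as.numeric(unlist(lapply(parts, `[`, seq_along(v$props))))),
                     ncol = length(v$props), byrow = TRUE)
      if (anyNA(vals)) {
        bad <- which(apply(is.na(vals), 1, any))[1]
        abort(sprintf("Non-numeric field in PLY vertex row %d: '%s'", bad, lines[bad]))
      }
    }
  } else {
    sizes <- ply_type_size[v$types]
    if (anyNA(sizes)) abort(sprintf("Unknown PLY property type '%s'", v$types[is.na(sizes)][1]))
    rec <- sum(sizes)
    raw <- readBin(con, "raw", n = n * rec)
    if (length(raw) < n * rec) abort("PLY binary payload shorter than header promises")
    offs <- cumsum(c(0L, sizes[-length(sizes)]))
    vals <- matrix(0, nrow = n, ncol = length(v$props))
    base <- rep((seq_len(n) - 1L) * rec, each = 1L)
    for (j in seq_along(v$props)) {
      sz <- sizes[j]
      idx <- as.vector(outer(seq_len(sz), base + offs[j], "+"))
      bytes <- raw[idx]
      vals[, j] <- switch(as.character(sz),
        "1" = as.numeric(readBin(bytes, "integer", n = n, size = 1, signed = FALSE)),
        "2" = as.numeric(readBin(bytes, "integer", n = n, size = 2, endian = "little")),
        "4" = if (v$types[j] %in% c("float", "float32")) {
          readBin(bytes, "numeric", n = n, size = 4, endian = "little")
        } else {
          as.numeric(readBin(bytes, "integer", n = n, size = 4, endian = "little"))
        },
        "8" = readBin(bytes, "numeric", n = n, size = 8, endian = "little"))
    }
  }
  colnames(vals) <- v$props
  pos <- vals[, c("x", "y", "z"), drop = FALSE]
  cols <- NULL
  if (all(c("red", "green", "blue") %in% v$props)) {
    cols <- vals[, c("red", "green", "blue"), drop = FALSE]
    ctypes <- v$types[match(c("red", "green", "blue"), v$props)]
    if (any(ctypes %in% c("uchar", "uint8", "char", "int8"))) cols <- cols / 255
    cols <- pmin(pmax(cols, 0), 1)
  }
  point_cloud(pos, colors = cols)
}

write_ply <- function(cloud, path) {
  P <- cloud_positions(cloud)
  C <- cloud_colors(cloud)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(P)),
           "property float x", "property float y", "property float z")
  if (!is.null(C)) hdr <- c(hdr, "property uchar red", "property uchar green", "property uchar blue")
  hdr <- c(hdr, "end_header")
  writeLines(hdr, con)
  if (nrow(P) > 0) {
    coords <- formatC(P, format = "g", digits = 6)
    if (!is.null(C)) {
      rows <- paste(coords[, 1], coords[, 2], coords[, 3],
                    as.integer(round(C[, 1] * 255)),
                    as.integer(round(C[, 2] * 255)),
                    as.integer(round(C[, 3] * 255)))
    } else {
      rows <- paste(coords[, 1], coords[, 2], coords[, 3])
    }
    writeLines(rows, con)
  }
  invisible(path)
}

read_xyzrgb <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(point_cloud(matrix(numeric(0), ncol = 3)))
  parts <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(parts)
  if (!all(nf %in% c(3L, 6L)) || length(unique(nf)) != 1) {
    bad <- which(!nf %in% c(3L, 6L))
    bad <- if (length(bad)) bad[1] else which(nf != nf[1])[1]
    abort(sprintf("Malformed XYZRGB row at line %d: '%s' (expect 3 or 6 columns)", bad, lines[bad]))
  }
  vals <- suppressWarnings(matrix(as.numeric(unlist(parts)), ncol = nf[1], byrow = TRUE))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1, any))[1]
    abort(sprintf("Non-numeric field in XYZRGB line %d: '%s'", bad, lines[bad]))
  }
  cols <- if (nf[1] == 6L) pmin(pmax(vals[, 4:6, drop = FALSE] / 255, 0), 1) else NULL
  point_cloud(vals[, 1:3, drop = FALSE], colors = cols)
}

write_xyzrgb <- function(cloud, path) {
  P <- cloud_positions(cloud)
  C <- cloud_colors(cloud)
  coords <- formatC(P, format = "g", digits = 6)
  rows <- if (!is.null(C)) {
    paste(coords[, 1], coords[, 2], coords[, 3],
          as.integer(round(C[, 1] * 255)), as.integer(round(C[, 2] * 255)),
          as.integer(round(C[, 3] * 255)))
  } else {
    paste(coords[, 1], coords[, 2], coords[, 3])
  }
  writeLines(rows, path)
  invisible(path)
}
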