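#' Point cloud objects
#'
#' A point cloud is a tibble with numeric columns `x`, `y`, `z` (coordinates in
#' meters), an optional integer `label` column (0 = stem, 1 = silique) and
#' optional 8-bit color columns `r`, `g`, `b`. All package functions that
#' consume clouds accept any data frame with these columns.
#'
#' @param x,y,z Numeric coordinate vectors of equal length.
#' @param label Optional integer labels (0 = stem, 1 = silique).
#' @param r,g,b Optional 8-bit color channels.
#' @return A `point_cloud` tibble.
#' @examples
#' point_cloud(x = runif(5), y = runif(5), z = runif(5), label = c(0, 0, 1, 1, 1))
#' @export
point_cloud <- function(x, y, z, label = NULL, r = NULL, g = NULL, b = NULL) {
  df <- tibble(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (!is.null(label)) df$label <- as.integer(label)
  if (!is.null(r)) {
    df$r <- as.integer(r); df$g <- as.integer(g); df$b <- as.integer(b)
  }
  as_point_cloud(df)
}

#' Coerce a data frame to a point cloud
#'
#' @param df A data frame with at least `x`, `y`, `z` columns.
#' @return A validated `point_cloud` tibble.
#' @export
as_point_cloud <- function(df) {
  if (!all(c("x", "y", "z") %in% names(df))) {
    abort("a point cloud needs `x`, `y` and `z` columns")
  }
  df <- as_tibble(df)
  if (nrow(df) < 1) abort("a point cloud must contain at least one point")
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    abort("point coordinates must be finite")
  }
  if ("label" %in% names(df)) {
    df$label <- as.integer(df$label)
    if (!all(df$label %in% c(0L, 1L))) {
      abort("labels must be 0 (stem) or 1 (silique)")
    }
  }
  class(df) <- unique(c("point_cloud", class(df)))
  df
}

cloud_coords <- function(cloud) {
  cbind(x = as.numeric(cloud$x), y = as.numeric(cloud$y), z = as.numeric(cloud$z))
}

is_labeled <- function(cloud) "label" %in% names(cloud)

#' Read a point cloud from PLY, PCD or labeled TXT
#'
#' TXT is whitespace-delimited `x y z [label] [r g b]` (the CloudCompare export
#' dialect used for stem/silique annotation). PLY supports ascii and
#' binary-little-endian vertex clouds; PCD supports ascii v0.7.
#'
#' @param path File path.
#' @param format One of `"auto"` (by extension), `"ply"`, `"pcd"`, `"txt"`.
#' @return A `point_cloud` tibble.
#' @export
read_cloud <- function(path, format = c("auto", "ply", "pcd", "txt")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("ply", "pcd", "txt", "xyz")) {
      abort(paste0("cannot infer point-cloud format from extension '.", ext, "'"))
    }
    format <- ifelse(ext == "xyz", "txt", ext)
  }
  switch(format,
    txt = read_cloud_txt(path),
    ply = read_cloud_ply(path),
    pcd = read_cloud_pcd(path)
  )
}

read_cloud_txt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0(path, ": no points"))
  parts <- strsplit(trimws(lines), "[ \t,;]+")
  ncols <- lengths(parts)
  if (any(ncols != ncols[1])) {
    bad <- which(ncols != ncols[1])[1]
    abort(paste0(path, ": line ", bad, " has ", ncols[bad],
                 " fields, expected ", ncols[1]))
  }
  m <- suppressWarnings(matrix(as.numeric(unlist(parts)), ncol = ncols[1],
                               byrow = TRUE))
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    abort(paste0(path, ": line ", bad, " is not numeric"))
  }
  if (ncols[1] < 3) abort(paste0(path, ": need at least x y z columns"))
  cl <- tibble(x = m[, 1], y = m[, 2], z = m[, 3])
  if (ncols[1] %in% c(4, 7)) cl$label <- as.integer(m[, 4])
  if (ncols[1] >= 6) {
    rgb0 <- if (ncols[1] == 7) 5L else 4L
    cl$r <- as.integer(m[, rgb0]); cl$g <- as.integer(m[, rgb0 + 1])
    cl$b <- as.integer(m[, rgb0 + 2])
  }
  as_point_cloud(cl)
}

read_cloud_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) abort(paste0(path, ": truncated PLY header"))
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
  }
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1) abort(paste0(path, ": missing PLY format line"))
  binary <- grepl("binary_little_endian", fmt_line)
  el <- grep("^element vertex ", header)
  if (length(el) == 0) abort(paste0(path, ": no vertex element"))
  nv <- as.integer(strsplit(trimws(header[el[1]]), " +")[[1]][3])
  if (is.na(nv) || nv < 1) abort(paste0(path, ": PLY has no vertices"))
  prop_lines <- header[seq_along(header) > el[1] &
                         grepl("^property ", trimws(header))]
  if (el[1] < length(header)) {
    nxt <- grep("^element ", trimws(header))
    nxt <- nxt[nxt > el[1]]
    if (length(nxt) > 0) {
      prop_lines <- header[(el[1] + 1):(nxt[1] - 1)]
      prop_lines <- prop_lines[grepl("^property ", trimws(prop_lines))]
    }
  }
  props <- do.call(rbind, strsplit(trimws(prop_lines), " +"))
  types <- props[, 2]
  pnames <- props[, 3]
  if (!all(c("x", "y", "z") %in% pnames)) abort(paste0(path, ": PLY lacks x/y/z"))
  sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L, short = 2L,
             ushort = 2L, int16 = 2L, uint16 = 2L, int = 4L, uint = 4L,
             int32 = 4L, uint32 = 4L, float = 4L, float32 = 4L, double = 8L,
             float64 = 8L)
  if (binary) {
    vals <- matrix(NA_real_, nrow = nv, ncol = length(pnames))
    for (i in seq_len(nv)) {
      for (j in seq_along(pnames)) {
        sz <- sizes[[types[j]]]
        if (is.null(sz)) abort(paste0(path, ": unsupported PLY type ", types[j]))
        what <- if (types[j] %in% c("float", "float32", "double", "float64"))
          "numeric" else "integer"
        vals[i, j] <- readBin(con, what, n = 1, size = sz, endian = "little",
                              signed = !grepl("^u", types[j]) || sz >= 4)
      }
    }
  } else {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    if (length(body) < nv) abort(paste0(path, ": PLY body shorter than header count"))
    vals <- matrix(as.numeric(unlist(strsplit(trimws(body[seq_len(nv)]), " +"))),
                   nrow = nv, byrow = TRUE)
  }
  colnames(vals) <- pnames
  cl <- tibble(x = vals[, "x"], y = vals[, "y"], z = vals[, "z"])
  if ("label" %in% pnames) cl$label <- as.integer(vals[, "label"])
  if (all(c("red", "green", "blue") %in% pnames)) {
    cl$r <- as.integer(vals[, "red"]); cl$g <- as.integer(vals[, "green"])
    cl$b <- as.integer(vals[, "blue"])
  }
  as_point_cloud(cl)
}

read_cloud_pcd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hend <- grep("^DATA ", lines)
  if (length(hend) == 0) abort(paste0(path, ": missing PCD DATA line"))
  if (!grepl("^DATA ascii", lines[hend[1]])) {
    abort(paste0(path, ": only ascii PCD is supported"))
  }
  fields <- strsplit(sub("^FIELDS ", "", grep("^FIELDS ", lines, value = TRUE)[1]),
                     " +")[[1]]
  body <- lines[(hend[1] + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) abort(paste0(path, ": PCD has no points"))
  m <- matrix(as.numeric(unlist(strsplit(trimws(body), " +"))),
              nrow = length(body), byrow = TRUE)
  colnames(m) <- fields[seq_len(ncol(m))]
  cl <- tibble(x = m[, "x"], y = m[, "y"], z = m[, "z"])
  if ("label" %in% colnames(m)) cl$label <- as.integer(m[, "label"])
  as_point_cloud(cl)
}

#' Write a point cloud to PLY, PCD or TXT
#'
#' TXT round-trips bit-exactly (full double precision); PLY is written as
#' ascii with `%.9g` coordinates, PCD as ascii v0.7.
#'
#' @param cloud A point cloud.
#' @param path Output path.
#' @param format One of `"auto"`, `"ply"`, `"pcd"`, `"txt"`.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, format = c("auto", "ply", "pcd", "txt")) {
  cloud <- as_point_cloud(cloud)
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  n <- nrow(cloud)
  if (format == "txt") {
    cols <- list(format(cloud$x, digits = 17), format(cloud$y, digits = 17),
                 format(cloud$z, digits = 17))
    if (is_labeled(cloud)) cols <- c(cols, list(cloud$label))
    if ("r" %in% names(cloud)) cols <- c(cols, list(cloud$r, cloud$g, cloud$b))
    writeLines(do.call(paste, cols), path)
  } else if (format == "ply") {
    props <- c("property double x", "property double y", "property double z")
    body <- sprintf("%.17g %.17g %.17g", cloud$x, cloud$y, cloud$z)
    if (is_labeled(cloud)) {
      props <- c(props, "property int label")
      body <- paste(body, cloud$label)
    }
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", n), props, "end_header", body), path)
  } else if (format == "pcd") {
    fields <- c("x", "y", "z")
    body <- sprintf("%.17g %.17g %.17g", cloud$x, cloud$y, cloud$z)
    if (is_labeled(cloud)) {
      fields <- c(fields, "label")
      body <- paste(body, cloud$label)
    }
    nf <- length(fields)
    writeLines(c("# .PCD v0.7 - Point Cloud Data file format",
                 "VERSION 0.7",
                 paste("FIELDS", paste(fields, collapse = " ")),
                 paste("SIZE", paste(rep(8, nf), collapse = " ")),
                 paste("TYPE", paste(rep("F", nf), collapse = " ")),
                 paste("COUNT", paste(rep(1, nf), collapse = " ")),
                 paste("WIDTH", n), "HEIGHT 1",
                 "VIEWPOINT 0 0 0 1 0 0 0",
                 paste("POINTS", n), "DATA ascii", body), path)
  } else {
    abort(paste0("unknown point-cloud format '", format, "'"))
  }
  invisible(path)
}

#' Passthrough background filter
#'
#' Retains the points whose coordinate along one axis lies in the closed
#' interval `[lo, hi]`; the standard background-removal step before
#' segmentation. Label and color columns subset consistently.
#'
#' @param cloud A point cloud.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param lo,hi Interval bounds, `lo < hi`.
#' @return The filtered `point_cloud`.
#' @export
passthrough <- function(cloud, axis = c("z", "x", "y"), lo, hi) {
  cloud <- as_point_cloud(cloud)
  axis <- match.arg(axis)
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    abort("passthrough range must satisfy lo < hi")
  }
  v <- cloud[[axis]]
  keep <- v >= lo & v <= hi
  if (!any(keep)) abort("passthrough filter removed every point")
  as_point_cloud(cloud[keep, , drop = FALSE])
}

#' Downsample a point cloud to a fixed size
#'
#' Farthest-point sampling (`"fps"`, the default: greedy max-min selection
#' preserving shape, seeded start index) or uniform random subsampling.
#' The result is always a subset of the input rows, so labels and colors map
#' through.
#'
#' @param cloud A point cloud.
#' @param target_n Number of points to keep (`<= nrow(cloud)`).
#' @param method `"fps"` or `"random"`.
#' @param seed Optional integer seed (start point for fps, subsample draw for
#'   random).
#' @param start Optional explicit fps start row (1-based); overrides the seeded
#'   draw.
#' @return A `point_cloud` of exactly `target_n` rows, with the retained input
#'   row numbers in attribute `"index"`.
#' @export
downsample <- function(cloud, target_n, method = c("fps", "random"), seed = NULL,
                       start = NULL) {
  cloud <- as_point_cloud(cloud)
  method <- match.arg(method)
  n <- nrow(cloud)
  if (target_n > n) abort("target_n exceeds the cloud size")
  idx <- with_seed_or_current(seed, {
    if (method == "fps") {
      start <- start %||% sample.int(n, 1)
      sort(cpp_fps(cloud_coords(cloud), as.integer(target_n), as.integer(start)))
    } else {
      sort(sample.int(n, target_n))
    }
  })
  out <- as_point_cloud(cloud[idx, , drop = FALSE])
  attr(out, "index") <- idx
  out
}
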