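#' Read and write point clouds as ASCII PLY or CSV
#'
#' Clouds are exchanged as ASCII PLY files with `float x`, `y`, `z` vertex
#' properties, or as plain CSV with columns `x,y,z`. The `source_id` column
#' is an in-memory tag assigned at merge time and is not serialized; clouds
#' read from disk get `source_id = 0`.
#'
#' @param cloud a [point_cloud()].
#' @param path file path.
#' @return `read_ply()`/`read_cloud_csv()` return a `point_cloud`; the
#'   writers return `path` invisibly.
#' @export
write_ply <- function(cloud, path) {
  if (!is_point_cloud(cloud)) stop("expected a point_cloud", call. = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- c(
    "ply",
    "format ascii 1.0",
    sprintf("element vertex %d", nrow(cloud)),
    "property float x",
    "property float y",
    "property float z",
    "end_header"
  )
  body <- sprintf("%.9g %.9g %.9g", cloud$x, cloud$y, cloud$z)
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L || lines[1] != "ply") {
    stop(sprintf("'%s' is not a PLY file", path), call. = FALSE)
  }
  end <- match("end_header", lines)
  if (is.na(end)) stop(sprintf("'%s': missing end_header", path), call. = FALSE)
  vline <- grep("^element vertex ", lines[seq_len(end)], value = TRUE)
  if (length(vline) != 1L) {
    stop(sprintf("'%s': missing vertex element", path), call. = FALSE)
  }
  n <- as.integer(sub("^element vertex ", "", vline))
  if (n == 0L) return(point_cloud())
  body <- lines[(end + 1L):(end + n)]
  vals <- utils::read.table(text = body, col.names = c("x", "y", "z"),
                            colClasses = "numeric")
  point_cloud(vals$x, vals$y, vals$z)
}

#' @rdname write_ply
#' @export
write_cloud_csv <- function(cloud, path) {
  if (!is_point_cloud(cloud)) stop("expected a point_cloud", call. = FALSE)
  utils::write.csv(data.frame(x = cloud$x, y = cloud$y, z = cloud$z),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_cloud_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!all(c("x", "y", "z") %in% names(df))) {
    stop(sprintf("'%s': expected columns x,y,z", path), call. = FALSE)
  }
  point_cloud(df$x, df$y, df$z)
}

#' Read and write per-frame robot poses as CSV
#'
#' One row per frame with columns `frame,x,y,z,rx,ry,rz` (`frame` 0-based,
#' positions in meters, orientations in radians). Reading validates every
#' row and names the first malformed one.
#'
#' @param poses list of [robot_pose()]s.
#' @param path file path.
#' @return `read_robot_poses()` returns a list of `robot_pose`s ordered by
#'   frame index; the writer returns `path` invisibly.
#' @export
write_robot_poses <- function(poses, path) {
  df <- do.call(rbind, lapply(seq_along(poses), function(i) {
    p <- poses[[i]]
    data.frame(frame = i - 1L, x = p$x, y = p$y, z = p$z,
               rx = p$rx, ry = p$ry, rz = p$rz)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_robot_poses
#' @export
read_robot_poses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "x", "y", "z", "rx", "ry", "rz")
  if (!all(need %in% names(df))) {
    stop(sprintf("'%s': expected columns %s", path,
                 paste(need, collapse = ",")), call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    row <- suppressWarnings(as.numeric(df[i, need]))
    if (any(is.na(row)) || !all(is.finite(row))) {
      stop(sprintf("'%s': malformed pose row %d", path, i), call. = FALSE)
    }
  }
  df <- df[order(df$frame), , drop = FALSE]
  lapply(seq_len(nrow(df)), function(i) {
    robot_pose(df$x[i], df$y[i], df$z[i], df$rx[i], df$ry[i], df$rz[i])
  })
}
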