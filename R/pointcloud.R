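#' Construct an indexed 3D point cloud
#'
#' A point cloud is a data frame with numeric columns `x`, `y`, `z` (meters)
#' and an integer `source_id` tagging the measurement each return came from.
#' Row order is the point index: every downstream transformation (axis swap,
#' sweep merge, image projection, proportional fit) preserves it, so a row
#' number always refers to the same physical LiDAR return. That stability is
#' what lets the pipeline recover the original 3D coordinates of the points
#' selected around each 2D keypoint.
#'
#' Axis convention after [swap_vertical_axes()]: `x` is the horizontal sweep
#' direction, `y` is depth (sensor toward subject), `z` is up. Raw sensor
#' clouds arrive with `y` up and `z` depth (the sensor is mounted rotated by
#' 90 degrees) and must be swapped once before any merging or projection.
#'
#' @param x,y,z numeric vectors of equal length, all values finite (meters).
#' @param source_id integer measurement index (>= 0), recycled to the number
#'   of points.
#' @return a `point_cloud` data frame.
#' @export
point_cloud <- function(x = numeric(), y = numeric(), z = numeric(),
                        source_id = 0L) {
  n <- length(x)
  if (length(y) != n || length(z) != n) {
    stop("x, y and z must have equal length", call. = FALSE)
  }
  if (n > 0 && !all(is.finite(x), is.finite(y), is.finite(z))) {
    stop("point coordinates must all be finite", call. = FALSE)
  }
  source_id <- as.integer(rep_len(source_id, n))
  if (n > 0 && any(source_id < 0L)) {
    stop("source_id must be >= 0", call. = FALSE)
  }
  structure(
    data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
               source_id = source_id),
    class = c("point_cloud", "data.frame")
  )
}

#' @export
#' @rdname point_cloud
is_point_cloud <- function(cloud) inherits(cloud, "point_cloud")

as_point_cloud <- function(df) {
  point_cloud(df$x, df$y, df$z, if (is.null(df$source_id)) 0L else df$source_id)
}

n_points <- function(cloud) nrow(cloud)

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("lidarom_degenerate", "error")))
}

#' Mounting-rotation correction: swap the two vertical-plane axes
#'
#' The LiDAR is mounted rotated by 90 degrees, so the raw sensor `y` and `z`
#' axes are exchanged relative to the scene: each point `(x, y, z)` becomes
#' `(x, z, y)`. Applied once per raw cloud; applying it twice restores the
#' input exactly. Point order and `source_id` tags are untouched.
#'
#' @param cloud a non-empty [point_cloud()].
#' @return the corrected `point_cloud`.
#' @export
swap_vertical_axes <- function(cloud) {
  if (!is_point_cloud(cloud)) stop("expected a point_cloud", call. = FALSE)
  if (n_points(cloud) == 0L) stop_degenerate("cannot axis-swap an empty cloud")
  point_cloud(cloud$x, cloud$z, cloud$y, cloud$source_id)
}

#' End-effector pose of the robot carrying the sensor rig
#'
#' @param x,y,z position in meters; `x` is the horizontal sweep coordinate.
#' @param rx,ry,rz end-effector orientation in radians. The sweep is a pure
#'   horizontal translation, so orientation is carried through but ignored
#'   by the fusion step.
#' @return a `robot_pose` list.
#' @export
robot_pose <- function(x, y = 0, z = 0, rx = 0, ry = 0, rz = 0) {
  vals <- c(x = x, y = y, z = z, rx = rx, ry = ry, rz = rz)
  if (!all(is.finite(vals))) stop("robot pose values must be finite", call. = FALSE)
  structure(as.list(vals), class = "robot_pose")
}

#' One synchronized acquisition
#'
#' A frame bundles the components that were captured simultaneously: the
#' camera image (or a reference to it), the raw LiDAR cloud, the robot pose,
#' and a timestamp, optionally with a reference angle and a cached keypoint
#' detection. Frames missing a mandatory component are never constructed;
#' session readers skip incomplete acquisitions instead.
#'
#' @param cloud a [point_cloud()] in the raw (pre-swap) sensor convention.
#' @param pose a [robot_pose()].
#' @param timestamp seconds since session start.
#' @param image optional image matrix/array or file path.
#' @param ground_truth_angle optional reference angle in degrees.
#' @param detection optional cached [joint_detection()].
#' @param pose_index 1-based index of the held pose this frame belongs to.
#' @return a `session_frame` list.
#' @export
session_frame <- function(cloud, pose, timestamp, image = NULL,
                          ground_truth_angle = NA_real_, detection = NULL,
                          pose_index = 1L) {
  if (!is_point_cloud(cloud)) stop("cloud must be a point_cloud", call. = FALSE)
  if (!inherits(pose, "robot_pose")) stop("pose must be a robot_pose", call. = FALSE)
  if (!is.finite(timestamp)) stop("timestamp must be finite", call. = FALSE)
  structure(
    list(cloud = cloud, robot_pose = pose, timestamp = as.numeric(timestamp),
         image = image, ground_truth_angle = as.numeric(ground_truth_angle),
         detection = detection, pose_index = as.integer(pose_index)),
    class = "session_frame"
  )
}

#' Merge a horizontal sweep of LiDAR measurements into one cloud
#'
#' Consecutive measurements of the same held pose are fused into a single
#' denser cloud. The first frame is the reference; every point of frame
#' \eqn{i} is shifted along `x` by the rig displacement
#' \eqn{x_i - x_0} reported by the robot, so a static world point lands at
#' the same merged coordinate regardless of which rig stop observed it.
#' A full sweep comprises `target_count` measurements (11 by default: the
#' rig collects 10 stops, occasionally 11). When fewer frames are supplied
#' the last one is replicated up to `target_count` -- replicated points
#' merely overlap and are harmless; when more are supplied the first
#' `target_count` are used.
#'
#' Clouds must already be axis-swapped. The merged `source_id` is the frame's
#' position (0-based) in the merged sequence.
#'
#' @param frames non-empty list of [session_frame()]s with swapped clouds.
#' @param target_count number of measurements one sweep should contribute.
#' @return a `point_cloud` with `sum(points per used frame)` rows.
#' @export
merge_sweep <- function(frames, target_count = 11L) {
  if (length(frames) == 0L) stop("frames must be non-empty", call. = FALSE)
  target_count <- as.integer(target_count)
  if (target_count < 1L) stop("target_count must be >= 1", call. = FALSE)
  ok_pose <- vapply(frames, function(f) inherits(f$robot_pose, "robot_pose"),
                    logical(1))
  if (!all(ok_pose)) {
    stop(sprintf("frame(s) %s missing a robot pose",
                 paste(which(!ok_pose), collapse = ", ")), call. = FALSE)
  }
  if (length(frames) >= target_count) {
    used <- frames[seq_len(target_count)]
  } else {
    used <- c(frames, rep(frames[length(frames)],
                          target_count - length(frames)))
  }
  ref_x <- used[[1]]$robot_pose$x
  parts <- lapply(seq_along(used), function(i) {
    f <- used[[i]]
    cl <- f$cloud
    point_cloud(cl$x + (f$robot_pose$x - ref_x), cl$y, cl$z,
                source_id = i - 1L)
  })
  merged <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(merged) <- NULL
  structure(merged, class = c("point_cloud", "data.frame"))
}
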