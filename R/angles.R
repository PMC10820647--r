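#' Keypoint-to-cloud association parameters
#'
#' Around each detected keypoint, the `k_max` fitted cloud points nearest in
#' pixel distance are selected, searching only within `radius` pixels. The
#' defaults (40 px radius, 10 points) are the empirical values the approach
#' was validated with; both are deliberately exposed for exploration.
#'
#' @param radius search radius in pixels (> 0).
#' @param k_max maximum number of points per joint (>= 1).
#' @return a `selection_params` list.
#' @export
selection_params <- function(radius = 40, k_max = 10L) {
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0", call. = FALSE)
  k_max <- as.integer(k_max)
  if (is.na(k_max) || k_max < 1L) stop("k_max must be >= 1", call. = FALSE)
  structure(list(radius = radius, k_max = k_max), class = "selection_params")
}

#' Select the fitted cloud points nearest a keypoint
#'
#' Euclidean pixel distances from each fitted point to the keypoint are
#' computed; points farther than `params$radius` are excluded, and the
#' `params$k_max` nearest of the remainder are returned (all of them if
#' fewer qualify). Distance ties are broken toward the smaller
#' `source_index` so replays are deterministic.
#'
#' @param fitted data frame from [apply_fit()] (columns `u`, `v`,
#'   `source_index`).
#' @param kp_u,kp_v keypoint pixel coordinates.
#' @param params a [selection_params()].
#' @return integer vector of selected `source_index` values; `integer(0)`
#'   when no point lies within the radius (the joint is unusable this
#'   iteration).
#' @export
select_joint_points <- function(fitted, kp_u, kp_v, params = selection_params()) {
  if (nrow(fitted) == 0L) stop_degenerate("fitted cloud is empty")
  d <- sqrt((fitted$u - kp_u)^2 + (fitted$v - kp_v)^2)
  inside <- which(d <= params$radius)
  if (length(inside) == 0L) return(integer(0))
  ord <- inside[order(d[inside], fitted$source_index[inside])]
  fitted$source_index[ord[seq_len(min(params$k_max, length(ord)))]]
}

#' Arithmetic mean of a set of 3D points
#'
#' @param points a [point_cloud()] or data frame with `x`, `y`, `z`, at
#'   least one row.
#' @return named numeric vector `c(x, y, z)`.
#' @export
centroid <- function(points) {
  if (nrow(points) == 0L) stop_degenerate("centroid of an empty point set")
  c(x = mean(points$x), y = mean(points$y), z = mean(points$z))
}

#' Angle at vertex B of the triple (A, B, C), in degrees
#'
#' Computes \eqn{\theta = \arccos\!\big(BA \cdot BC / (\lVert BA\rVert\,
#' \lVert BC\rVert)\big)} with \eqn{BA = A - B} and \eqn{BC = C - B}. The
#' cosine is clamped to `[-1, 1]` to absorb floating-point overshoot, so the
#' result is always in `[0, 180]`.
#'
#' @param A,B,C numeric `c(x, y, z)` vectors; `B` is the joint vertex.
#' @return the angle in degrees.
#' @export
joint_angle_deg <- function(A, B, C) {
  ba <- as.numeric(A) - as.numeric(B)
  bc <- as.numeric(C) - as.numeric(B)
  nba <- sqrt(sum(ba^2))
  nbc <- sqrt(sum(bc^2))
  if (nba == 0 || nbc == 0) {
    stop_degenerate("degenerate joint geometry: coincident centroids")
  }
  cosang <- sum(ba * bc) / (nba * nbc)
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Joint triple defining each exercise's angle
#'
#' The angle vertex `B` and endpoints `A`, `C` per exercise:
#' shoulder abduction (`RA`) and shoulder flexion (`RF`) use hip--shoulder--
#' wrist (vertex at the shoulder); elbow flexion (`R7`) uses shoulder--
#' elbow--wrist (vertex at the elbow). The right arm is the default side.
#' The mapping is configurable: pass a named list of `c(A=, B=, C=)`
#' keypoint-name triples to override.
#'
#' @param exercise one of `"RA"`, `"RF"`, `"R7"`.
#' @param side `"right"` (default) or `"left"`.
#' @return character vector `c(A=, B=, C=)` of COCO keypoint names.
#' @export
exercise_triple <- function(exercise = c("RA", "RF", "R7"), side = "right") {
  exercise <- match.arg(exercise)
  p <- function(j) paste0(side, "_", j)
  switch(exercise,
    RA = c(A = p("hip"), B = p("shoulder"), C = p("wrist")),
    RF = c(A = p("hip"), B = p("shoulder"), C = p("wrist")),
    R7 = c(A = p("shoulder"), B = p("elbow"), C = p("wrist"))
  )
}

stop_skip <- function(msg) {
  stop(errorCondition(msg, class = c("lidarom_skip", "error")))
}

#' Estimate one joint angle from one iteration's frames
#'
#' Runs the full per-iteration chain: axis-swap each raw cloud, merge the
#' sweep (method `"F"`) or take the single measurement (method `"S"`),
#' flatten to 2D, fit proportionally onto the detected person, select the
#' nearest cloud points around each keypoint of the exercise's joint triple,
#' lift them back to their original 3D coordinates, average per joint, and
#' evaluate the vertex angle.
#'
#' Any unusable stage -- a required keypoint missing or below the confidence
#' threshold, an empty selection around a joint, coincident centroids --
#' aborts the iteration with a condition of class `lidarom_skip` carrying
#' the reason; [estimate_session()] records these and carries on.
#'
#' @param frames list of [session_frame()]s with raw (pre-swap) clouds: one
#'   frame for method `"S"`, up to `target_count` for method `"F"`.
#' @param detection the person's [joint_detection()] for this iteration.
#' @param exercise `"RA"`, `"RF"` or `"R7"`.
#' @param method `"S"` (single measurement) or `"F"` (full merged sweep).
#' @param params a [selection_params()].
#' @param mirror_u horizontal mirroring flag, see
#'   [project_to_image_plane()].
#' @param min_confidence keypoints below this confidence are treated as
#'   missing.
#' @param triple joint-name triple, defaults to [exercise_triple()].
#' @param target_count sweep size for method `"F"`.
#' @param iteration iteration number recorded in the estimate.
#' @return an `angle_estimate` list: `exercise`, `theta_deg`, `method`,
#'   `iteration`, `timestamp`, and `n_points` (named count of selected
#'   points per triple role).
#' @export
estimate_angle <- function(frames, detection, exercise, method = c("F", "S"),
                           params = selection_params(), mirror_u = TRUE,
                           min_confidence = 0.25, triple = NULL,
                           target_count = 11L, iteration = 1L) {
  method <- match.arg(method)
  if (length(frames) == 0L) stop("frames must be non-empty", call. = FALSE)
  if (is.null(triple)) triple <- exercise_triple(exercise)
  swapped <- lapply(frames, function(f) {
    f$cloud <- swap_vertical_axes(f$cloud)
    f
  })
  cloud <- if (method == "F") {
    merge_sweep(swapped, target_count = target_count)
  } else {
    swapped[[1]]$cloud
  }
  if (n_points(cloud) == 0L) stop_skip("empty point cloud")
  p2d <- project_to_image_plane(cloud, mirror_u = mirror_u)
  fit <- tryCatch(compute_fit(p2d, detection$bbox),
                  lidarom_degenerate = function(e) stop_skip(conditionMessage(e)))
  fitted <- apply_fit(p2d, fit)
  kps <- detection$keypoints
  cents <- list()
  n_sel <- integer(0)
  for (role in c("A", "B", "C")) {
    jn <- triple[[role]]
    row <- kps[kps$joint == jn & kps$confidence >= min_confidence, , drop = FALSE]
    if (nrow(row) == 0L) stop_skip(sprintf("keypoint '%s' missing or low-confidence", jn))
    sel <- select_joint_points(fitted, row$u[1], row$v[1], params)
    if (length(sel) == 0L) stop_skip(sprintf("no cloud points near '%s'", jn))
    cents[[role]] <- centroid(cloud[sel, , drop = FALSE])
    n_sel[role] <- length(sel)
  }
  theta <- tryCatch(joint_angle_deg(cents$A, cents$B, cents$C),
                    lidarom_degenerate = function(e) stop_skip(conditionMessage(e)))
  structure(
    list(exercise = exercise, theta_deg = theta, method = method,
         iteration = as.integer(iteration),
         timestamp = frames[[1]]$timestamp, n_points = n_sel),
    class = "angle_estimate"
  )
}

#' Estimate an angle series over a whole session
#'
#' Method `"S"` produces one estimate per frame from its single measurement.
#' Method `"F"` chunks each held pose's frames into consecutive groups of
#' `target_count` (a short final group is completed by replication inside
#' [merge_sweep()]), producing `ceiling(frames_per_pose / target_count)`
#' estimates per pose. Skipped iterations are recorded, with reasons, in the
#' `"skips"` attribute of the result.
#'
#' @param session a session as produced by [generate_session()] or
#'   [read_session()].
#' @param method `"F"` or `"S"`.
#' @inheritParams estimate_angle
#' @param exercise override of the session's exercise label.
#' @return data frame (class `angle_series`) with columns `iteration`,
#'   `timestamp_s`, `exercise`, `method`, `theta_deg`, `n_points_a`,
#'   `n_points_b`, `n_points_c`; attribute `skips` is a data frame of
#'   `iteration`, `reason`.
#' @export
estimate_session <- function(session, method = c("F", "S"),
                             params = selection_params(), mirror_u = TRUE,
                             min_confidence = 0.25, triple = NULL,
                             target_count = 11L, exercise = NULL) {
  method <- match.arg(method)
  frames <- session$frames
  if (length(frames) == 0L) stop("session has no frames", call. = FALSE)
  if (is.null(exercise)) exercise <- session$meta$exercise
  groups <- if (method == "S") {
    lapply(seq_along(frames), function(i) i)
  } else {
    pose_of <- vapply(frames, function(f) f$pose_index, integer(1))
    unlist(lapply(split(seq_along(frames), pose_of), function(idx) {
      split(idx, ceiling(seq_along(idx) / target_count))
    }), recursive = FALSE, use.names = FALSE)
  }
  rows <- list()
  skips <- list()
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    det <- frames[[idx[1]]]$detection
    res <- tryCatch({
      if (is.null(det)) stop_skip("no detection available")
      estimate_angle(frames[idx], det, exercise, method = method,
                     params = params, mirror_u = mirror_u,
                     min_confidence = min_confidence, triple = triple,
                     target_count = target_count, iteration = g)
    },
    lidarom_skip = function(e) e,
    lidarom_detection_failure = function(e) e)
    if (inherits(res, "angle_estimate")) {
      rows[[length(rows) + 1L]] <- data.frame(
        iteration = g, timestamp_s = res$timestamp, exercise = exercise,
        method = method, theta_deg = res$theta_deg,
        n_points_a = res$n_points[["A"]], n_points_b = res$n_points[["B"]],
        n_points_c = res$n_points[["C"]], stringsAsFactors = FALSE)
    } else {
      skips[[length(skips) + 1L]] <- data.frame(
        iteration = g, reason = conditionMessage(res), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(iteration = integer(), timestamp_s = numeric(),
               exercise = character(), method = character(),
               theta_deg = numeric(), n_points_a = integer(),
               n_points_b = integer(), n_points_c = integer())
  attr(out, "skips") <- if (length(skips)) do.call(rbind, skips) else
    data.frame(iteration = integer(), reason = character())
  class(out) <- c("angle_series", "data.frame")
  out
}

#' Write / read an angle series
#'
#' CSV columns: `iteration, timestamp_s, exercise, method, theta_deg,
#' n_points_a, n_points_b, n_points_c`; angles carry 3 decimal places and
#' timestamps are seconds since session start. `write_angle_series()` also
#' accepts `format = "json"`.
#'
#' @param series an `angle_series` data frame.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return reader returns the series data frame; writer returns `path`
#'   invisibly.
#' @export
write_angle_series <- function(series, path, format = c("csv", "json")) {
  format <- match.arg(format)
  out <- series
  out$theta_deg <- sprintf("%.3f", out$theta_deg)
  out$timestamp_s <- sprintf("%.3f", out$timestamp_s)
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_angle_series
#' @export
read_angle_series <- function(path) {
  # method is "S"/"F"; an unquoted F must not be parsed as FALSE
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(exercise = "character",
                                       method = "character"))
  class(df) <- c("angle_series", "data.frame")
  df
}

#' Per-pose-step mean of a single-measurement series
#'
#' Optional post-hoc summary of a method-`S` series: the mean estimate over
#' each consecutive window of `step` iterations (one robot sweep / held
#' pose step), the single-measurement analogue of the merged-sweep
#' estimate.
#'
#' @param series an `angle_series`.
#' @param step window length in iterations (default 11, one sweep).
#' @return data frame with `pose_step`, `theta_deg_mean`, `n`.
#' @export
pose_step_means <- function(series, step = 11L) {
  grp <- ceiling(series$iteration / step)
  agg <- stats::aggregate(series$theta_deg, by = list(pose_step = grp),
                          FUN = mean)
  cnt <- stats::aggregate(series$theta_deg, by = list(pose_step = grp),
                          FUN = length)
  data.frame(pose_step = agg$pose_step, theta_deg_mean = agg$x, n = cnt$x)
}
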