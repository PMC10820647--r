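#' Drop depth: project a 3D cloud to the image plane
#'
#' The camera and LiDAR are co-mounted without extrinsic calibration, so the
#' cloud is flattened orthographically: the depth axis `y` is simply
#' discarded. Image `v` grows downward while scene `z` grows upward, so
#' `v = -z`. The horizontal sign depends on how the sensor's sweep axis
#' relates to the image's `u` axis; the default mirrors it (`u = -x`),
#' matching the virtual rig's convention, and is configurable for real rigs
#' mounted the other way. Each output row keeps `source_index`, the row
#' number of its 3D origin, so selected 2D points can be lifted back to 3D.
#'
#' @param cloud non-empty [point_cloud()] in the post-swap convention
#'   (`y` = depth).
#' @param mirror_u if `TRUE` (default), `u = -x`; otherwise `u = x`.
#' @return data frame with columns `u`, `v`, `source_index`.
#' @export
project_to_image_plane <- function(cloud, mirror_u = TRUE) {
  if (!is_point_cloud(cloud)) stop("expected a point_cloud", call. = FALSE)
  if (n_points(cloud) == 0L) stop_degenerate("cannot project an empty cloud")
  data.frame(
    u = if (mirror_u) -cloud$x else cloud$x,
    v = -cloud$z,
    source_index = seq_len(nrow(cloud))
  )
}

#' Proportional fit of the flattened cloud onto the detected person
#'
#' The 2D cloud is rescaled so its width and height equal the person's
#' pixel width and height (independent scales: the fit is anisotropic), and
#' translated so its bounding rectangle coincides with the person's box --
#' the top-left corner of the cloud's bounding rectangle maps onto the
#' box's top-left corner.
#'
#' @param points2d data frame from [project_to_image_plane()].
#' @param bbox the person's [bounding_box()].
#' @return a `fit_transform` list with `scale_u`, `scale_v` (pixels per
#'   cloud unit, both > 0) and `offset_u`, `offset_v` (pixels).
#' @export
compute_fit <- function(points2d, bbox) {
  if (!inherits(bbox, "bounding_box")) stop("expected a bounding_box", call. = FALSE)
  du <- max(points2d$u) - min(points2d$u)
  dv <- max(points2d$v) - min(points2d$v)
  if (du <= 0 || dv <= 0) {
    stop_degenerate("cloud spans zero width or height; cannot fit to person")
  }
  scale_u <- bbox_width(bbox) / du
  scale_v <- bbox_height(bbox) / dv
  structure(
    list(scale_u = scale_u, scale_v = scale_v,
         offset_u = bbox$u_min - scale_u * min(points2d$u),
         offset_v = bbox$v_min - scale_v * min(points2d$v)),
    class = "fit_transform"
  )
}

#' @rdname compute_fit
#' @param fit a `fit_transform`.
#' @return `apply_fit()` returns the transformed points (same columns,
#'   `source_index` preserved).
#' @export
apply_fit <- function(points2d, fit) {
  if (!inherits(fit, "fit_transform")) stop("expected a fit_transform", call. = FALSE)
  data.frame(
    u = points2d$u * fit$scale_u + fit$offset_u,
    v = points2d$v * fit$scale_v + fit$offset_v,
    source_index = points2d$source_index
  )
}
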