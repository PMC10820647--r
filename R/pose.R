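#' The 17 COCO keypoint names, in canonical order
#' @export
COCO_KEYPOINTS <- c(
  "nose", "left_eye", "right_eye", "left_ear", "right_ear",
  "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
  "left_wrist", "right_wrist", "left_hip", "right_hip",
  "left_knee", "right_knee", "left_ankle", "right_ankle"
)

#' Pixel-space bounding box
#'
#' Half-open box `[u_min, u_max) x [v_min, v_max)`, 0-based, origin at the
#' top-left of the image, `u` rightward, `v` downward.
#'
#' @param u_min,v_min,u_max,v_max box edges in pixels.
#' @return a `bounding_box` list.
#' @export
bounding_box <- function(u_min, v_min, u_max, v_max) {
  vals <- c(u_min, v_min, u_max, v_max)
  if (!all(is.finite(vals))) stop("box edges must be finite", call. = FALSE)
  if (u_min >= u_max || v_min >= v_max) {
    stop("bounding box must have positive width and height", call. = FALSE)
  }
  structure(list(u_min = u_min, v_min = v_min, u_max = u_max, v_max = v_max),
            class = "bounding_box")
}

bbox_width <- function(b) b$u_max - b$u_min
bbox_height <- function(b) b$v_max - b$v_min

#' Image region to blank before person detection
#'
#' Same convention as [bounding_box()] but a zero-area region is allowed
#' (it masks nothing). Used to hide the lower body so the detector only
#' considers the part of the person the LiDAR actually scanned.
#'
#' @param u_min,v_min,u_max,v_max region edges in pixels (half-open).
#' @return a `mask_region` list.
#' @export
mask_region <- function(u_min, v_min, u_max, v_max) {
  vals <- c(u_min, v_min, u_max, v_max)
  if (!all(is.finite(vals))) stop("region edges must be finite", call. = FALSE)
  if (u_min > u_max || v_min > v_max) {
    stop("mask region must not be inverted", call. = FALSE)
  }
  structure(list(u_min = u_min, v_min = v_min, u_max = u_max, v_max = v_max),
            class = "mask_region")
}

#' Blank a rectangular image region
#'
#' Sets every pixel inside `region` to zero intensity and leaves every other
#' pixel untouched. The caller keeps the original image: the mask exists only
#' for the detector's benefit and is conceptually removed afterwards (nothing
#' downstream reads the masked pixels).
#'
#' @param image numeric matrix (rows = `v`, cols = `u`) or H x W x C array.
#' @param region a [mask_region()], fully inside the image.
#' @return the masked image, same shape as the input.
#' @export
mask_lower_body <- function(image, region) {
  if (!inherits(region, "mask_region")) stop("expected a mask_region", call. = FALSE)
  d <- dim(image)
  h <- d[1]; w <- d[2]
  if (region$u_min < 0 || region$v_min < 0 ||
      region$u_max > w || region$v_max > h) {
    stop("mask region lies outside the image", call. = FALSE)
  }
  if (region$u_min == region$u_max || region$v_min == region$v_max) {
    return(image)
  }
  rows <- (floor(region$v_min) + 1L):ceiling(region$v_max)
  cols <- (floor(region$u_min) + 1L):ceiling(region$u_max)
  if (length(d) == 2L) {
    image[rows, cols] <- 0
  } else {
    image[rows, cols, ] <- 0
  }
  image
}

#' Keypoint table constructor
#'
#' @param joint character vector of COCO keypoint names.
#' @param u,v pixel coordinates.
#' @param confidence detector confidence in `[0, 1]`.
#' @return a data frame with columns `joint`, `u`, `v`, `confidence`.
#' @export
keypoint_table <- function(joint, u, v, confidence = 1) {
  bad <- setdiff(joint, COCO_KEYPOINTS)
  if (length(bad) > 0) {
    stop(sprintf("unknown keypoint name(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  confidence <- rep_len(confidence, length(joint))
  if (any(confidence < 0 | confidence > 1)) {
    stop("confidence must be in [0, 1]", call. = FALSE)
  }
  data.frame(joint = joint, u = as.numeric(u), v = as.numeric(v),
             confidence = as.numeric(confidence), stringsAsFactors = FALSE)
}

#' One person's detection: upper-body box plus named keypoints
#'
#' @param bbox a [bounding_box()] around the (visible, upper) body.
#' @param keypoints a [keypoint_table()].
#' @return a `joint_detection` list.
#' @export
joint_detection <- function(bbox, keypoints) {
  if (!inherits(bbox, "bounding_box")) stop("bbox must be a bounding_box", call. = FALSE)
  structure(list(bbox = bbox, keypoints = keypoints), class = "joint_detection")
}

stop_detection_failure <- function(msg) {
  stop(errorCondition(msg, class = c("lidarom_detection_failure", "error")))
}

#' Serialize / deserialize detections as JSON
#'
#' Detections (box + keypoints) round-trip through JSON so outputs of a real
#' pose network can be cached once and replayed offline.
#'
#' @param detection a [joint_detection()].
#' @param path JSON file path.
#' @return `read_detection_json()` returns a `joint_detection`; the writer
#'   returns `path` invisibly.
#' @export
write_detection_json <- function(detection, path) {
  obj <- list(
    bbox = detection$bbox[c("u_min", "v_min", "u_max", "v_max")],
    keypoints = detection$keypoints
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_detection_json
#' @export
read_detection_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bb <- obj$bbox
  kp <- obj$keypoints
  joint_detection(
    bounding_box(bb$u_min, bb$v_min, bb$u_max, bb$v_max),
    keypoint_table(kp$joint, kp$u, kp$v, kp$confidence)
  )
}

#' Detector contract
#'
#' `detect_joints()` is the single entry point the pipeline calls on a
#' (masked) image; implementations are interchangeable. The package ships
#' two: a synthetic detector that replays projected ground-truth keypoints
#' produced by the scene simulator, and a cache reader that replays
#' detections previously serialized to JSON. A real pose-network adapter can
#' implement the same generic. If a detector sees more than one person it
#' must return the highest-confidence one; if it finds none it signals a
#' detection failure (condition class `lidarom_detection_failure`) and the
#' caller skips the iteration.
#'
#' @param detector a detector object.
#' @param image the masked image handed to the detector (may be `NULL` for
#'   replay detectors).
#' @param frame_index 1-based frame number within the session, used by
#'   replay detectors to look up the stored detection.
#' @return a [joint_detection()].
#' @export
detect_joints <- function(detector, image = NULL, frame_index = 1L) {
  UseMethod("detect_joints")
}

#' Synthetic replay detector
#'
#' Holds one precomputed [joint_detection()] per frame (projected
#' ground-truth joints, optionally noised at generation time) and replays
#' them on demand. A blank (all-zero) image is treated as containing no
#' person and raises a detection failure, like a real detector would.
#'
#' @param detections list of `joint_detection`s, one per frame.
#' @return a `synthetic_detector`.
#' @export
synthetic_detector <- function(detections) {
  structure(list(detections = detections),
            class = c("synthetic_detector", "lidarom_detector"))
}

#' @export
detect_joints.synthetic_detector <- function(detector, image = NULL,
                                             frame_index = 1L) {
  if (!is.null(image) && all(image == 0)) {
    stop_detection_failure("no person found in image")
  }
  if (frame_index < 1L || frame_index > length(detector$detections)) {
    stop_detection_failure(sprintf("no detection for frame %d", frame_index))
  }
  det <- detector$detections[[frame_index]]
  if (is.null(det)) stop_detection_failure(sprintf("no person in frame %d", frame_index))
  det
}

#' Cached-JSON replay detector
#'
#' Replays detections from `detections/NNNN.json` files in a session
#' directory (as written by [write_session()] or by an external adapter).
#'
#' @param dir path to the `detections/` directory.
#' @return a `cached_detector`.
#' @export
cached_detector <- function(dir) {
  structure(list(dir = dir),
            class = c("cached_detector", "lidarom_detector"))
}

#' @export
detect_joints.cached_detector <- function(detector, image = NULL,
                                          frame_index = 1L) {
  path <- file.path(detector$dir, sprintf("%04d.json", frame_index))
  if (!file.exists(path)) {
    stop_detection_failure(sprintf("no cached detection for frame %d", frame_index))
  }
  read_detection_json(path)
}
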