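#' Write a session to a directory
#'
#' On-disk layout (open formats only; a normalization of the acquisition
#' software's mixed `.jpg`/`.bag`/`.txt` outputs):
#' \preformatted{
#'   meta.json            session manifest (config, seed, file inventory)
#'   frames/NNNN.png      camera images (schematic renders for synthetic)
#'   clouds/NNNN.ply      raw (pre-swap) LiDAR clouds, ASCII PLY
#'   robot_poses.csv      frame,x,y,z,rx,ry,rz
#'   frames.csv           frame,timestamp_s,pose_index,ground_truth_angle
#'   ground_truth.csv     timestamp_s,angle_deg  (reference trace)
#'   detections/NNNN.json cached keypoint detections (optional)
#' }
#' Frame numbering is 1-based in file names (`0001.png` is frame 1). All
#' writers are deterministic, so identical sessions produce byte-identical
#' directories.
#'
#' @param session a `rom_session` from [generate_session()] or
#'   [read_session()].
#' @param dir target directory (created; must not already contain a
#'   session unless `overwrite = TRUE`).
#' @param overwrite replace an existing session directory.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, overwrite = FALSE) {
  if (file.exists(file.path(dir, "meta.json")) && !overwrite) {
    stop(sprintf("'%s' already contains a session", dir), call. = FALSE)
  }
  for (d in c(dir, file.path(dir, "frames"), file.path(dir, "clouds"),
              file.path(dir, "detections"))) {
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
  }
  frames <- session$frames
  meta <- session$meta
  n <- length(frames)
  frame_rows <- list()
  for (i in seq_len(n)) {
    f <- frames[[i]]
    write_ply(f$cloud, file.path(dir, "clouds", sprintf("%04d.ply", i)))
    img <- f$image
    if (is.null(img) && !is.null(meta$scenes)) {
      scene <- meta$scenes[[f$pose_index]]
      surf <- body_surface(skeleton_from_scene(scene), scene$limb_radius,
                           scene$torso_radius, scene$head_radius)
      img <- render_scene_image(surf, meta$rig, f$robot_pose$x)
    }
    if (is.character(img)) img <- png::readPNG(img)
    if (is.null(img)) img <- matrix(0, 4, 4)
    png::writePNG(img, file.path(dir, "frames", sprintf("%04d.png", i)))
    if (!is.null(f$detection)) {
      write_detection_json(f$detection,
                           file.path(dir, "detections", sprintf("%04d.json", i)))
    }
    frame_rows[[i]] <- data.frame(frame = i - 1L,
                                  timestamp_s = f$timestamp,
                                  pose_index = f$pose_index,
                                  ground_truth_angle = f$ground_truth_angle)
  }
  write_robot_poses(lapply(frames, `[[`, "robot_pose"),
                    file.path(dir, "robot_poses.csv"))
  utils::write.csv(do.call(rbind, frame_rows), file.path(dir, "frames.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(session$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(
    session_id = if (is.null(meta$session_id)) basename(dir) else meta$session_id,
    exercise = meta$exercise, view = meta$view, distance = meta$distance,
    n_frames = n, frames_per_pose = meta$frames_per_pose,
    rate_hz = meta$rate_hz,
    theta_true = meta$theta_true,
    seed = if (is.null(meta$noise)) NA else meta$noise$seed,
    rig = meta$rig[setdiff(names(meta$rig), character(0))],
    noise = if (is.null(meta$noise)) NULL else unclass(meta$noise),
    inventory = list(
      images = sprintf("frames/%04d.png", seq_len(n)),
      clouds = sprintf("clouds/%04d.ply", seq_len(n)),
      robot_poses = "robot_poses.csv",
      ground_truth = "ground_truth.csv"
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a session directory
#'
#' Loads only fully synchronized frames: a frame missing its cloud or image
#' file is skipped with a warning (mirroring the acquisition rule that data
#' were only saved when every component was available). A malformed robot
#' pose row is an error naming the row; a missing manifest, or a manifest
#' whose inventory counts disagree with the files on disk, is an error.
#' Cached detections are attached when present. Images are loaded lazily:
#' `frames[[i]]$image` holds the PNG path.
#'
#' @param path session directory.
#' @return a `rom_session` (with `meta$skipped_frames` listing any skipped
#'   frame indices).
#' @export
read_session <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) {
    stop(sprintf("'%s': missing meta.json manifest", path), call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  n <- meta$n_frames
  pose_path <- file.path(path, "robot_poses.csv")
  if (!file.exists(pose_path)) {
    stop(sprintf("'%s': missing robot_poses.csv", path), call. = FALSE)
  }
  poses <- read_robot_poses(pose_path)
  if (length(poses) != n) {
    stop(sprintf("'%s': manifest says %d frames but robot_poses.csv has %d rows",
                 path, n, length(poses)), call. = FALSE)
  }
  ftab <- utils::read.csv(file.path(path, "frames.csv"))
  truth <- utils::read.csv(file.path(path, "ground_truth.csv"))
  frames <- list()
  skipped <- integer(0)
  for (i in seq_len(n)) {
    cloud_path <- file.path(path, "clouds", sprintf("%04d.ply", i))
    img_path <- file.path(path, "frames", sprintf("%04d.png", i))
    if (!file.exists(cloud_path) || !file.exists(img_path)) {
      warning(sprintf("frame %d incomplete (missing %s); skipped", i,
                      if (file.exists(cloud_path)) "image" else "cloud"),
              call. = FALSE)
      skipped <- c(skipped, i)
      next
    }
    det_path <- file.path(path, "detections", sprintf("%04d.json", i))
    det <- if (file.exists(det_path)) read_detection_json(det_path) else NULL
    frames[[length(frames) + 1L]] <- session_frame(
      cloud = read_ply(cloud_path),
      pose = poses[[i]],
      timestamp = ftab$timestamp_s[ftab$frame == i - 1L],
      image = img_path,
      ground_truth_angle = ftab$ground_truth_angle[ftab$frame == i - 1L],
      detection = det,
      pose_index = ftab$pose_index[ftab$frame == i - 1L]
    )
  }
  meta_out <- as.list(meta)
  meta_out$skipped_frames <- skipped
  structure(list(frames = frames, truth = truth, meta = meta_out),
            class = "rom_session")
}
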