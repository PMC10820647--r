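#' Virtual acquisition rig
#'
#' Models the physical rig: a 16-beam LiDAR mounted vertically (so its beam
#' fan spreads across the horizontal direction and its spin covers the
#' vertical), restricted to a +/-18 degree angular span with a 4.8 m maximum
#' detection range, swept horizontally by the robot between -0.3 m and
#' -0.1 m in 10 stops, with a pinhole camera co-mounted atop the sensor.
#' Sensor height and camera intrinsics are configuration defaults, not
#' measured values.
#'
#' World frame: `x` horizontal (sweep direction), `y` depth toward the
#' subject, `z` up; the rig sits at `(sweep stop, 0, sensor_height)`.
#'
#' @param n_beams number of LiDAR beams (16).
#' @param beam_fov_deg full fan angle across the beams, degrees (30, i.e.
#'   2-degree beam spacing).
#' @param azimuth_span_deg full usable spin span, degrees (36 = +/-18).
#' @param azimuth_step_deg spin angular resolution at the ~10 Hz scan rate.
#' @param max_range maximum detection distance, meters.
#' @param sweep_x robot sweep stops along `x`, meters.
#' @param sensor_height sensor optical center height, meters.
#' @param focal_px camera focal length in pixels.
#' @param image_width,image_height camera image size in pixels.
#' @return a `virtual_rig` list.
#' @export
virtual_rig <- function(n_beams = 16L, beam_fov_deg = 30,
                        azimuth_span_deg = 36, azimuth_step_deg = 0.2,
                        max_range = 4.8,
                        sweep_x = seq(-0.3, -0.1, length.out = 10),
                        sensor_height = 1.2, focal_px = 600,
                        image_width = 640L, image_height = 480L) {
  stopifnot(n_beams >= 1, beam_fov_deg > 0, azimuth_span_deg > 0,
            azimuth_step_deg > 0, max_range > 0, length(sweep_x) >= 1)
  structure(
    list(n_beams = as.integer(n_beams), beam_fov_deg = beam_fov_deg,
         azimuth_span_deg = azimuth_span_deg,
         azimuth_step_deg = azimuth_step_deg, max_range = max_range,
         sweep_x = sweep_x, sensor_height = sensor_height,
         focal_px = focal_px, image_width = as.integer(image_width),
         image_height = as.integer(image_height)),
    class = "virtual_rig"
  )
}

#' Measurement noise model
#'
#' @param range_sigma Gaussian LiDAR range noise, meters (0 = noiseless).
#' @param pixel_sigma Gaussian keypoint position noise, pixels.
#' @param seed RNG seed controlling every random draw of a generated
#'   session.
#' @return a `noise_model` list.
#' @export
noise_model <- function(range_sigma = 0, pixel_sigma = 0, seed = 1L) {
  stopifnot(range_sigma >= 0, pixel_sigma >= 0)
  structure(list(range_sigma = range_sigma, pixel_sigma = pixel_sigma,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Ground-truth arm configuration
#'
#' One held pose of the subject: exercise type, true joint angle, viewing
#' direction and stand-off distance, plus the body dimensions (plausible
#' adult defaults; only the relative geometry matters for recovery tests).
#'
#' @param exercise `"RA"` (shoulder abduction), `"RF"` (shoulder flexion)
#'   or `"R7"` (elbow flexion).
#' @param theta_true true angle of the exercise's joint triple, degrees in
#'   `[0, 180]`.
#' @param view `"frontal"`, `"oblique"` or `"lateral"` -- a whole-body yaw
#'   of 0, 45 or 90 degrees (oblique/lateral yaws configurable via
#'   `view_yaw_deg`).
#' @param distance subject stand-off along the depth axis, meters (3 or 4
#'   in the protocol).
#' @param upper_arm,forearm,torso_height,shoulder_width,hip_width,hip_height
#'   segment dimensions, meters. `shoulder_width` and `hip_width` are the
#'   distances between the left/right joint centers (where pose keypoints
#'   sit), not the body's outer silhouette widths -- hip keypoints in
#'   particular are medial of the pelvis edge.
#' @param limb_radius,torso_radius,head_radius capsule radii, meters.
#' @param view_yaw_deg explicit yaw override, degrees.
#' @return an `arm_scene` list.
#' @export
arm_scene <- function(exercise = c("RA", "RF", "R7"), theta_true,
                      view = c("frontal", "oblique", "lateral"),
                      distance = 3, upper_arm = 0.30, forearm = 0.27,
                      torso_height = 0.50, shoulder_width = 0.40,
                      hip_width = 0.22, hip_height = 0.95,
                      limb_radius = 0.045, torso_radius = 0.11,
                      head_radius = 0.09, view_yaw_deg = NULL) {
  exercise <- match.arg(exercise)
  view <- match.arg(view)
  if (!is.finite(theta_true) || theta_true < 0 || theta_true > 180) {
    stop("theta_true must be in [0, 180] degrees", call. = FALSE)
  }
  lens <- c(distance, upper_arm, forearm, torso_height, shoulder_width,
            hip_width, hip_height, limb_radius, torso_radius, head_radius)
  if (!all(is.finite(lens) & lens > 0)) {
    stop("all scene dimensions must be positive", call. = FALSE)
  }
  if (is.null(view_yaw_deg)) {
    view_yaw_deg <- switch(view, frontal = 0, oblique = 45, lateral = 90)
  }
  structure(
    list(exercise = exercise, theta_true = theta_true, view = view,
         distance = distance, upper_arm = upper_arm, forearm = forearm,
         torso_height = torso_height, shoulder_width = shoulder_width,
         hip_width = hip_width, hip_height = hip_height,
         limb_radius = limb_radius, torso_radius = torso_radius,
         head_radius = head_radius, view_yaw_deg = view_yaw_deg),
    class = "arm_scene"
  )
}

rot_y <- function(v, theta) {
  c(v[1] * cos(theta) + v[3] * sin(theta), v[2],
    -v[1] * sin(theta) + v[3] * cos(theta))
}

rot_x <- function(v, theta) {
  c(v[1], v[2] * cos(theta) - v[3] * sin(theta),
    v[2] * sin(theta) + v[3] * cos(theta))
}

#' 3D joint positions for a scene
#'
#' Places the subject facing the rig at the scene's distance and solves the
#' right-arm configuration so the exercise's joint triple subtends exactly
#' `theta_true`:
#' * `RA`: straight arm rotated in the frontal plane, from the hip
#'   direction outward (abduction);
#' * `RF`: straight arm rotated in the sagittal plane toward the camera
#'   (flexion);
#' * `R7`: upper arm hanging at the side, forearm flexed in the subject's
#'   frontal plane (the flexion plane the frontal camera can observe).
#' The whole body is then yawed about the vertical axis through its center
#' by the view angle (frontal 0, oblique 45, lateral 90 degrees). Yaw is a
#' rigid rotation, so the generated triple subtends `theta_true` in every
#' view.
#'
#' @param scene an [arm_scene()].
#' @return named list of `c(x, y, z)` joint positions (meters): `pelvis`,
#'   `neck`, `head_top`, `nose`, left/right `hip`, `shoulder`, `elbow`,
#'   `wrist`.
#' @export
skeleton_from_scene <- function(scene) {
  d <- scene$distance
  sh_z <- scene$hip_height + scene$torso_height
  j <- list(
    pelvis = c(0, d, scene$hip_height),
    neck = c(0, d, sh_z),
    head_top = c(0, d, sh_z + 0.23),
    nose = c(0, d - scene$head_radius, sh_z + 0.13),
    right_hip = c(-scene$hip_width / 2, d, scene$hip_height),
    left_hip = c(scene$hip_width / 2, d, scene$hip_height),
    right_shoulder = c(-scene$shoulder_width / 2, d, sh_z),
    left_shoulder = c(scene$shoulder_width / 2, d, sh_z)
  )
  th <- scene$theta_true * pi / 180
  if (scene$exercise %in% c("RA", "RF")) {
    ba <- j$right_hip - j$right_shoulder
    u <- ba / sqrt(sum(ba^2))
    if (scene$exercise == "RA") {
      # Abduction: rotate the trunk direction outward in the frontal plane;
      # the rotation is rigid, so the triple subtends theta exactly.
      dir <- rot_y(u, th)
    } else {
      # Flexion moves the straight arm in the sagittal plane through the
      # shoulder (constant lateral offset). The trunk direction u is tilted
      # off that plane by its lateral component a = |u_x|, so the in-plane
      # elevation phi solves cos(theta) = sqrt(1 - a^2) * cos(phi); theta
      # values with |cos(theta)| > sqrt(1 - a^2) would require the arm to
      # leave the sagittal plane and are rejected.
      b <- sqrt(1 - u[1]^2)
      if (abs(cos(th)) > b) {
        stop(sprintf(
          "RF theta_true = %g deg infeasible in the sagittal plane; need theta in [%.2f, %.2f] deg",
          scene$theta_true, acos(b) * 180 / pi, 180 - acos(b) * 180 / pi),
          call. = FALSE)
      }
      phi <- acos(cos(th) / b)
      dir <- c(0, -sin(phi), -cos(phi))
    }
    j$right_elbow <- j$right_shoulder + scene$upper_arm * dir
    j$right_wrist <- j$right_elbow + scene$forearm * dir
  } else {
    j$right_elbow <- j$right_shoulder + scene$upper_arm * c(0, 0, -1)
    dir <- rot_y(c(0, 0, 1), -th)
    j$right_wrist <- j$right_elbow + scene$forearm * dir
  }
  j$left_elbow <- j$left_shoulder + scene$upper_arm * c(0, 0, -1)
  j$left_wrist <- j$left_elbow + scene$forearm * c(0, 0, -1)
  psi <- scene$view_yaw_deg * pi / 180
  if (psi != 0) {
    center <- c(0, d, 0)
    j <- lapply(j, function(p) {
      q <- p - center
      center + c(q[1] * cos(psi) - q[2] * sin(psi),
                 q[1] * sin(psi) + q[2] * cos(psi), q[3])
    })
  }
  j
}

#' Capsule body surface
#'
#' Models the scanned body as capsules (cylinders with hemispherical caps):
#' torso, head, and both upper arms and forearms. Capsules are all the
#' sparse-beam sampling pattern needs and keep ray casting cheap.
#'
#' @param skeleton joint positions from [skeleton_from_scene()].
#' @param limb_radius,torso_radius,head_radius capsule radii, meters.
#' @return a `body_surface`: list of capsules `(p0, p1, r)`.
#' @export
body_surface <- function(skeleton, limb_radius = 0.045, torso_radius = 0.11,
                         head_radius = 0.09) {
  caps <- list(
    list(p0 = skeleton$pelvis, p1 = skeleton$neck, r = torso_radius),
    # shoulder and pelvic girdles: the joint keypoints sit on fleshed body
    # surface (deltoids, hips), not on bare limb tubes
    list(p0 = skeleton$left_shoulder, p1 = skeleton$right_shoulder,
         r = 0.07),
    list(p0 = skeleton$left_hip, p1 = skeleton$right_hip, r = 0.09),
    list(p0 = skeleton$neck, p1 = skeleton$head_top, r = head_radius),
    list(p0 = skeleton$right_shoulder, p1 = skeleton$right_elbow, r = limb_radius),
    list(p0 = skeleton$right_elbow, p1 = skeleton$right_wrist, r = limb_radius),
    list(p0 = skeleton$left_shoulder, p1 = skeleton$left_elbow, r = limb_radius),
    list(p0 = skeleton$left_elbow, p1 = skeleton$left_wrist, r = limb_radius)
  )
  structure(list(capsules = caps), class = "body_surface")
}

# Smallest positive ray parameter t where origin + t*dir meets one capsule.
# dirs must be unit rows; returns Inf for misses.
ray_capsule_t <- function(origin, dirs, p0, p1, r) {
  eps <- 1e-9
  n <- nrow(dirs)
  t_best <- rep(Inf, n)
  a <- p1 - p0
  L <- sqrt(sum(a^2))
  if (L > eps) {
    ah <- a / L
    m <- origin - p0
    d_par <- as.numeric(dirs %*% ah)
    m_par <- sum(m * ah)
    d_perp <- dirs - tcrossprod(d_par, ah)
    m_perp <- m - m_par * ah
    A <- rowSums(d_perp^2)
    B <- 2 * as.numeric(d_perp %*% m_perp)
    C <- sum(m_perp^2) - r^2
    disc <- B^2 - 4 * A * C
    ok <- disc >= 0 & A > eps
    t_cyl <- rep(Inf, n)
    t_cyl[ok] <- (-B[ok] - sqrt(disc[ok])) / (2 * A[ok])
    s <- m_par + t_cyl * d_par
    t_cyl[!(t_cyl > eps & s >= 0 & s <= L)] <- Inf
    t_best <- pmin(t_best, t_cyl)
  }
  for (cen in list(p0, p1)) {
    oc <- origin - cen
    b <- as.numeric(dirs %*% oc)
    cc <- sum(oc^2) - r^2
    disc <- b^2 - cc
    ok <- disc >= 0
    t_s <- rep(Inf, n)
    t_s[ok] <- -b[ok] - sqrt(disc[ok])
    t_s[t_s <= eps] <- Inf
    t_best <- pmin(t_best, t_s)
  }
  t_best
}

#' Cast rays against a body surface
#'
#' @param surface a [body_surface()].
#' @param origin `c(x, y, z)` ray origin.
#' @param dirs n x 3 matrix of unit ray directions.
#' @return numeric vector of first-hit ranges (`Inf` for misses): occlusion
#'   is intrinsic, each ray stops at its nearest capsule.
#' @export
ray_cast <- function(surface, origin, dirs) {
  t_all <- rep(Inf, nrow(dirs))
  for (cap in surface$capsules) {
    t_all <- pmin(t_all, ray_capsule_t(origin, dirs, cap$p0, cap$p1, cap$r))
  }
  t_all
}

#' Simulate one LiDAR measurement
#'
#' Casts a grid of rays from the sensor at the given sweep stop: the 16
#' beams fan across the horizontal direction (vertical mounting) and the
#' spin steps cover the vertical direction within the +/-18 degree span.
#' Only first hits with range at most `max_range` are returned, with
#' optional Gaussian range noise (draws come from the current RNG stream,
#' which [generate_session()] seeds). The cloud is delivered in the raw
#' sensor convention (`y` up, `z` depth) so the pipeline's
#' [swap_vertical_axes()] is genuinely exercised.
#'
#' @param surface a [body_surface()].
#' @param rig a [virtual_rig()].
#' @param rig_x sweep stop, meters.
#' @param noise a [noise_model()] or `NULL` for noiseless.
#' @return a pre-swap [point_cloud()] (possibly empty if the subject is out
#'   of range or view).
#' @export
lidar_scan <- function(surface, rig, rig_x, noise = NULL) {
  origin <- c(rig_x, 0, rig$sensor_height)
  half_fan <- rig$beam_fov_deg / 2 * pi / 180
  alpha <- seq(-half_fan, half_fan, length.out = rig$n_beams)
  half_span <- rig$azimuth_span_deg / 2
  phi <- seq(-half_span, half_span, by = rig$azimuth_step_deg) * pi / 180
  grid <- expand.grid(alpha = alpha, phi = phi)
  dirs <- cbind(tan(grid$alpha), 1, tan(grid$phi))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  t <- ray_cast(surface, origin, dirs)
  hit <- which(is.finite(t))
  if (length(hit) == 0L) return(point_cloud())
  t <- t[hit]
  if (!is.null(noise) && noise$range_sigma > 0) {
    t <- t + stats::rnorm(length(t), 0, noise$range_sigma)
  }
  keep <- t > 0 & t <= rig$max_range
  if (!any(keep)) return(point_cloud())
  t <- t[keep]
  d <- dirs[hit[keep], , drop = FALSE]
  w <- cbind(origin[1] + t * d[, 1], origin[2] + t * d[, 2],
             origin[3] + t * d[, 3])
  point_cloud(w[, 1] - rig_x, w[, 3] - rig$sensor_height, w[, 2])
}

#' Pinhole projection of 3D points
#'
#' Camera at the sweep stop, optical axis along depth, principal point at
#' the image center; `u` mirrors the world `x` axis (consistent with the
#' default `mirror_u` of [project_to_image_plane()]) and `v` grows
#' downward.
#'
#' @param pts n x 3 matrix of world points.
#' @param rig a [virtual_rig()].
#' @param rig_x camera `x` position.
#' @return n x 2 matrix of `(u, v)` pixels.
#' @export
camera_project <- function(pts, rig, rig_x) {
  pts <- rbind(pts)
  y <- pts[, 2]
  if (any(y <= 0)) stop("point behind camera", call. = FALSE)
  u <- rig$image_width / 2 - rig$focal_px * (pts[, 1] - rig_x) / y
  v <- rig$image_height / 2 - rig$focal_px * (pts[, 3] - rig$sensor_height) / y
  cbind(u = u, v = v)
}

#' Ground-truth camera view of a skeleton
#'
#' Projects the modeled joints to pixel coordinates and derives the
#' upper-body bounding box from the projected extent of the capsule
#' silhouettes (endpoint projections padded by the projected capsule
#' radius, clipped to the image).
#'
#' @param skeleton joints from [skeleton_from_scene()].
#' @param rig a [virtual_rig()].
#' @param rig_x camera position.
#' @param surface optional [body_surface()] for the silhouette box; built
#'   from the skeleton with default radii when omitted.
#' @return list with `keypoints` (a [keypoint_table()], confidence 1),
#'   `bbox` (a [bounding_box()]) and `joints_px` (named matrix).
#' @export
camera_view <- function(skeleton, rig, rig_x, surface = NULL) {
  coco <- c("nose", "right_shoulder", "left_shoulder", "right_elbow",
            "left_elbow", "right_wrist", "left_wrist", "right_hip",
            "left_hip")
  pts <- do.call(rbind, skeleton[coco])
  px <- camera_project(pts, rig, rig_x)
  rownames(px) <- coco
  if (is.null(surface)) surface <- body_surface(skeleton)
  u_lo <- Inf; u_hi <- -Inf; v_lo <- Inf; v_hi <- -Inf
  for (cap in surface$capsules) {
    for (p in list(cap$p0, cap$p1)) {
      q <- camera_project(rbind(p), rig, rig_x)
      r_px <- rig$focal_px * cap$r / p[2]
      u_lo <- min(u_lo, q[1] - r_px); u_hi <- max(u_hi, q[1] + r_px)
      v_lo <- min(v_lo, q[2] - r_px); v_hi <- max(v_hi, q[2] + r_px)
    }
  }
  bbox <- bounding_box(max(0, u_lo), max(0, v_lo),
                       min(rig$image_width, u_hi),
                       min(rig$image_height, v_hi))
  kps <- keypoint_table(coco, px[, "u"], px[, "v"], confidence = 1)
  list(keypoints = kps, bbox = bbox, joints_px = px)
}

#' Render a schematic scene image
#'
#' Grayscale silhouette rendering of the capsule body (body pixels at 0.85
#' intensity on a black background), sufficient for detector plumbing and
#' visual debugging; no photorealism intended.
#'
#' @param surface a [body_surface()].
#' @param rig a [virtual_rig()].
#' @param rig_x camera position.
#' @return numeric `image_height` x `image_width` matrix in `[0, 1]`.
#' @export
render_scene_image <- function(surface, rig, rig_x) {
  w <- rig$image_width; h <- rig$image_height
  img <- matrix(0, nrow = h, ncol = w)
  uu <- matrix(rep(seq_len(w) - 0.5, each = h), nrow = h)
  vv <- matrix(rep(seq_len(h) - 0.5, times = w), nrow = h)
  for (cap in surface$capsules) {
    e <- camera_project(rbind(cap$p0, cap$p1), rig, rig_x)
    r0 <- rig$focal_px * cap$r / cap$p0[2]
    r1 <- rig$focal_px * cap$r / cap$p1[2]
    du <- e[2, 1] - e[1, 1]; dv <- e[2, 2] - e[1, 2]
    len2 <- du^2 + dv^2
    tt <- if (len2 < 1e-12) {
      matrix(0, nrow = h, ncol = w)
    } else {
      pmin(1, pmax(0, ((uu - e[1, 1]) * du + (vv - e[1, 2]) * dv) / len2))
    }
    dist <- sqrt((uu - (e[1, 1] + tt * du))^2 + (vv - (e[1, 2] + tt * dv))^2)
    img[dist <= r0 + tt * (r1 - r0)] <- 0.85
  }
  img
}

#' Generate a fully synthetic session
#'
#' Emulates the acquisition protocol: for each held pose (one [arm_scene()]
#' per pose), the robot sweeps the rig through its stops at ~10 Hz, and
#' each stop yields one synchronized frame -- a raw LiDAR cloud, the robot
#' pose, a timestamp, the true angle, and a cached synthetic detection
#' (projected ground-truth keypoints with optional Gaussian pixel noise,
#' silhouette bounding box). A ground-truth trace emulating the wearable
#' reference device's text stream (`timestamp`, `angle_deg`, constant
#' within a pose) accompanies the frames. All randomness is drawn from
#' `noise$seed`, so identical seeds give bit-identical sessions.
#'
#' @param scenes one [arm_scene()] or a list of them (one per pose).
#' @param rig a [virtual_rig()].
#' @param noise a [noise_model()].
#' @param frames_per_pose frames collected per pose (default: one per sweep
#'   stop).
#' @param rate_hz nominal acquisition rate.
#' @return a `rom_session` list: `frames` (list of [session_frame()]),
#'   `truth` (data frame `timestamp_s`, `angle_deg`), `meta`.
#' @export
generate_session <- function(scenes, rig = virtual_rig(),
                             noise = noise_model(),
                             frames_per_pose = length(rig$sweep_x),
                             rate_hz = 10) {
  if (inherits(scenes, "arm_scene")) scenes <- list(scenes)
  if (length(scenes) == 0L) stop("need at least one pose", call. = FALSE)
  set.seed(noise$seed)
  frames <- list()
  truth <- list()
  k <- 0L
  for (j in seq_along(scenes)) {
    scene <- scenes[[j]]
    skel <- skeleton_from_scene(scene)
    surf <- body_surface(skel, scene$limb_radius, scene$torso_radius,
                         scene$head_radius)
    for (s in seq_len(frames_per_pose)) {
      rig_x <- rig$sweep_x[((s - 1L) %% length(rig$sweep_x)) + 1L]
      cloud <- lidar_scan(surf, rig, rig_x, noise)
      view <- camera_view(skel, rig, rig_x, surf)
      kps <- view$keypoints
      if (noise$pixel_sigma > 0) {
        kps$u <- kps$u + stats::rnorm(nrow(kps), 0, noise$pixel_sigma)
        kps$v <- kps$v + stats::rnorm(nrow(kps), 0, noise$pixel_sigma)
        kps$u <- pmin(pmax(kps$u, 0), rig$image_width - 1e-6)
        kps$v <- pmin(pmax(kps$v, 0), rig$image_height - 1e-6)
      }
      ts <- k / rate_hz
      frames[[k + 1L]] <- session_frame(
        cloud = cloud,
        pose = robot_pose(rig_x, 0, rig$sensor_height),
        timestamp = ts,
        ground_truth_angle = scene$theta_true,
        detection = joint_detection(view$bbox, kps),
        pose_index = j
      )
      truth[[k + 1L]] <- data.frame(timestamp_s = ts,
                                    angle_deg = scene$theta_true)
      k <- k + 1L
    }
  }
  structure(
    list(frames = frames, truth = do.call(rbind, truth),
         meta = list(exercise = scenes[[1]]$exercise,
                     view = scenes[[1]]$view,
                     distance = scenes[[1]]$distance,
                     theta_true = vapply(scenes, function(s) s$theta_true,
                                         numeric(1)),
                     n_frames = k, frames_per_pose = frames_per_pose,
                     rate_hz = rate_hz, rig = rig, noise = noise,
                     scenes = scenes)),
    class = "rom_session"
  )
}
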