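test_that("generated skeletons subtend exactly the requested angle", {
  for (ex in c("RA", "RF", "R7")) {
    for (view in c("frontal", "oblique", "lateral")) {
      for (th in c(15, 30, 47.3, 90, 120, 150, 165)) {
        sk <- skeleton_from_scene(arm_scene(ex, th, view, 3))
        tr <- exercise_triple(ex)
        got <- joint_angle_deg(sk[[tr[["A"]]]], sk[[tr[["B"]]]], sk[[tr[["C"]]]])
        expect_lt(abs(got - th), 1e-9)
      }
    }
  }
})

test_that("a fully extended elbow gives a collinear arm", {
  sk <- skeleton_from_scene(arm_scene("R7", 180, "frontal", 3))
  ba <- sk$right_shoulder - sk$right_elbow
  bc <- sk$right_wrist - sk$right_elbow
  cr <- c(ba[2] * bc[3] - ba[3] * bc[2], ba[3] * bc[1] - ba[1] * bc[3],
          ba[1] * bc[2] - ba[2] * bc[1])
  expect_lt(sqrt(sum(cr^2)), 1e-9)
})

test_that("shoulder flexion outside the sagittally reachable range is rejected", {
  expect_error(skeleton_from_scene(arm_scene("RF", 2, "frontal", 3)),
               "infeasible")
  expect_error(skeleton_from_scene(arm_scene("RF", 179, "frontal", 3)),
               "infeasible")
})

test_that("the lateral view compresses joint spread onto the depth axis", {
  frontal <- skeleton_from_scene(arm_scene("RA", 90, "frontal", 3))
  lateral <- skeleton_from_scene(arm_scene("RA", 90, "lateral", 3))
  spread <- function(sk) diff(range(vapply(sk, `[[`, numeric(1), 1)))
  expect_lt(spread(lateral), spread(frontal) / 2)
})

test_that("rays hit capsules at the expected ranges and miss cleanly", {
  surf <- structure(list(capsules = list(
    list(p0 = c(0, 5, 0), p1 = c(0, 6, 0), r = 0.5))), class = "body_surface")
  # straight down the axis: first contact is the near cap at 4.5 m
  t <- ray_cast(surf, c(0, 0, 0), rbind(c(0, 1, 0)))
  expect_equal(t, 4.5, tolerance = 1e-12)
  # clean miss
  expect_identical(ray_cast(surf, c(0, 0, 0), rbind(c(0, 0, 1))), Inf)
})

test_that("all simulated returns lie on some capsule surface", {
  scene <- arm_scene("RA", 120, "oblique", 3)
  sk <- skeleton_from_scene(scene)
  surf <- body_surface(sk, scene$limb_radius, scene$torso_radius,
                       scene$head_radius)
  rig <- virtual_rig()
  cl <- lidar_scan(surf, rig, -0.2)
  expect_gt(nrow(cl), 100)
  # undo the sensor-frame conversion: world = (x + rig_x, z, y + h)
  for (i in sample.int(nrow(cl), 200, replace = TRUE)) {
    p <- c(cl$x[i] - 0.2, cl$z[i], cl$y[i] + rig$sensor_height)
    dmin <- min(vapply(surf$capsules, function(cp) {
      dist_point_segment(p, cp$p0, cp$p1) - cp$r
    }, numeric(1)))
    expect_lt(abs(dmin), 1e-6)
  }
})

test_that("a subject beyond the maximum detection distance yields no returns", {
  scene <- arm_scene("RA", 90, "frontal", 5)
  surf <- body_surface(skeleton_from_scene(scene))
  cl <- lidar_scan(surf, virtual_rig(), -0.2)
  expect_equal(nrow(cl), 0L)
})

test_that("noiseless scans are bit-identical across calls", {
  surf <- body_surface(skeleton_from_scene(arm_scene("RF", 60, "frontal", 3)))
  rig <- virtual_rig()
  expect_identical(lidar_scan(surf, rig, -0.3), lidar_scan(surf, rig, -0.3))
})

test_that("merging every sweep stop widens coverage of a close-up subject", {
  # at 1.5 m the 30-degree beam fan clips the body, so each stop sees a
  # different stripe and the merged sweep genuinely extends the x-extent
  scene <- arm_scene("RA", 90, "frontal", 1.5)
  surf <- body_surface(skeleton_from_scene(scene))
  rig <- virtual_rig()
  frames <- lapply(rig$sweep_x, function(x) {
    session_frame(swap_vertical_axes(lidar_scan(surf, rig, x)),
                  robot_pose(x), timestamp = 0)
  })
  widths <- vapply(frames, function(f) diff(range(f$cloud$x)), numeric(1))
  counts <- vapply(frames, function(f) nrow(f$cloud), numeric(1))
  merged <- merge_sweep(frames, target_count = 11)
  expect_equal(nrow(merged), sum(counts) + counts[10])
  expect_gt(diff(range(merged$x)), max(widths))
})

test_that("perspective projection scales and centers as a pinhole should", {
  rig <- virtual_rig()
  # principal-axis point maps to the image center
  expect_equal(as.numeric(camera_project(c(-0.2, 3, rig$sensor_height),
                                         rig, -0.2)),
               c(rig$image_width / 2, rig$image_height / 2))
  # doubling the distance halves the projected arm length
  px3 <- camera_view(skeleton_from_scene(arm_scene("RA", 90, "frontal", 2)),
                     rig, -0.2)$joints_px
  px6 <- camera_view(skeleton_from_scene(arm_scene("RA", 90, "frontal", 4)),
                     rig, -0.2)$joints_px
  len <- function(px) sqrt(sum((px["right_wrist", ] - px["right_shoulder", ])^2))
  expect_lt(abs(len(px3) / 2 - len(px6)), 1)
  expect_error(camera_project(c(0, -1, 1), rig, 0), "behind")
})

test_that("frontal-plane angles survive projection to the image", {
  rig <- virtual_rig()
  for (th in c(45, 90, 135)) {
    sk <- skeleton_from_scene(arm_scene("RA", th, "frontal", 4))
    px <- camera_view(sk, rig, -0.2)$joints_px
    a2 <- px["right_hip", ]; b2 <- px["right_shoulder", ]
    c2 <- px["right_wrist", ]
    # image v points down, so flip to keep orientation; angle is 2D
    ang <- oracle_angle_deg(c(a2[1], -a2[2], 0), c(b2[1], -b2[2], 0),
                            c(c2[1], -c2[2], 0))
    expect_lt(abs(ang - th), 1)
  }
})

test_that("sessions have the protocol's shape and determinism", {
  scene <- arm_scene("RA", 90, "frontal", 3)
  s <- generate_session(scene, noise = noise_model(0.01, 1, seed = 9))
  expect_equal(length(s$frames), 10L)
  ts <- vapply(s$frames, `[[`, numeric(1), "timestamp")
  expect_true(all(diff(ts) > 0))
  expect_true(all(s$truth$angle_deg == 90))
  expect_equal(nrow(s$truth), 10L)

  s2 <- generate_session(scene, noise = noise_model(0.01, 1, seed = 9))
  expect_identical(s, s2)

  multi <- generate_session(list(arm_scene("RA", 30), arm_scene("RA", 60)),
                            noise = noise_model(seed = 1))
  expect_equal(length(multi$frames), 20L)
  expect_equal(unique(multi$truth$angle_deg), c(30, 60))
})

test_that("the schematic render puts body pixels inside the silhouette box", {
  scene <- arm_scene("R7", 90, "frontal", 3)
  sk <- skeleton_from_scene(scene)
  surf <- body_surface(sk, scene$limb_radius, scene$torso_radius,
                       scene$head_radius)
  rig <- virtual_rig()
  img <- render_scene_image(surf, rig, -0.2)
  expect_equal(dim(img), c(rig$image_height, rig$image_width))
  body <- which(img > 0, arr.ind = TRUE)
  expect_gt(nrow(body), 1000)
  bb <- camera_view(sk, rig, -0.2, surf)$bbox
  expect_true(all(body[, "row"] - 0.5 >= bb$v_min - 1 &
                  body[, "row"] - 0.5 <= bb$v_max + 1))
  expect_true(all(body[, "col"] - 0.5 >= bb$u_min - 1 &
                  body[, "col"] - 0.5 <= bb$u_max + 1))
})
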