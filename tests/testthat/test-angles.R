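test_that("vertex angle matches closed-form cases", {
  O <- c(0, 0, 0)
  expect_equal(joint_angle_deg(c(1, 0, 0), O, c(0, 1, 0)), 90)
  expect_equal(joint_angle_deg(c(1, 0, 0), O, c(-2, 0, 0)), 180)
  expect_equal(joint_angle_deg(c(1, 0, 0), O, c(-1, 1, 0)), 135)
  expect_error(joint_angle_deg(O, O, c(1, 1, 1)), class = "lidarom_degenerate")
})

test_that("vertex angle agrees with an independent oracle and its invariances", {
  set.seed(101)
  for (i in 1:1000) {
    tr <- random_triple()
    got <- joint_angle_deg(tr$A, tr$B, tr$C)
    expect_lt(abs(got - oracle_angle_deg(tr$A, tr$B, tr$C)), 1e-9)
    # symmetry in the endpoints
    expect_lt(abs(got - joint_angle_deg(tr$C, tr$B, tr$A)), 1e-9)
  }
  # scale invariance of the two arms, rotation invariance of the triple
  set.seed(202)
  for (i in 1:50) {
    tr <- random_triple()
    base <- joint_angle_deg(tr$A, tr$B, tr$C)
    s <- runif(2, 0.1, 10)
    expect_lt(abs(joint_angle_deg(tr$B + s[1] * (tr$A - tr$B), tr$B,
                                  tr$B + s[2] * (tr$C - tr$B)) - base), 1e-9)
    ang <- runif(3, 0, 2 * pi)
    Rz <- matrix(c(cos(ang[1]), sin(ang[1]), 0, -sin(ang[1]), cos(ang[1]), 0,
                   0, 0, 1), 3)
    Rx <- matrix(c(1, 0, 0, 0, cos(ang[2]), sin(ang[2]),
                   0, -sin(ang[2]), cos(ang[2])), 3)
    R <- Rz %*% Rx
    expect_lt(abs(joint_angle_deg(R %*% tr$A, R %*% tr$B, R %*% tr$C) - base),
              1e-9)
  }
})

test_that("centroid is the per-coordinate mean", {
  expect_equal(centroid(point_cloud(c(0, 2), c(0, 0), c(0, 0))),
               c(x = 1, y = 0, z = 0))
  single <- point_cloud(0.3, -1, 2)
  expect_equal(centroid(single), c(x = 0.3, y = -1, z = 2))
  set.seed(8)
  cl <- random_cloud(10)
  expect_equal(centroid(cl),
               c(x = sum(cl$x) / 10, y = sum(cl$y) / 10, z = sum(cl$z) / 10))
  expect_error(centroid(point_cloud()), class = "lidarom_degenerate")
})

test_that("selection respects the radius, cap and ties", {
  # distances 39 and 41 around a radius-40 search
  f <- data.frame(u = c(39, 41), v = c(0, 0), source_index = 1:2)
  expect_identical(select_joint_points(f, 0, 0), 1L)

  # 15 points inside: the 10 nearest win
  set.seed(30)
  ang <- runif(15, 0, 2 * pi)
  r <- seq(2, 30, length.out = 15)
  f <- data.frame(u = r * cos(ang), v = r * sin(ang), source_index = 1:15)
  expect_identical(sort(select_joint_points(f, 0, 0)), 1:10)

  # all outside: empty-selection signal
  far <- data.frame(u = c(100, 200), v = c(0, 0), source_index = 1:2)
  expect_identical(select_joint_points(far, 0, 0), integer(0))

  # exact distance ties resolved toward the smaller index
  tie <- data.frame(u = c(3, -3, 0, 0), v = c(0, 0, 3, -3),
                    source_index = c(7L, 2L, 9L, 4L))
  expect_identical(select_joint_points(tie, 0, 0, selection_params(40, 2)),
                   c(2L, 4L))
})

test_that("selection matches the exhaustive oracle on random instances", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(20:500, 1)
    f <- data.frame(u = runif(n, 0, 100), v = runif(n, 0, 100),
                    source_index = sample.int(n))
    kp <- runif(2, 0, 100)
    got <- select_joint_points(f, kp[1], kp[2], selection_params(40, 10))
    expect_identical(got, oracle_select(f, kp[1], kp[2], 40, 10))
  }
})

test_that("exercise triples name hip-shoulder-wrist and shoulder-elbow-wrist", {
  expect_equal(unname(exercise_triple("RA")),
               c("right_hip", "right_shoulder", "right_wrist"))
  expect_equal(exercise_triple("RF"), exercise_triple("RA"))
  expect_equal(unname(exercise_triple("R7")),
               c("right_shoulder", "right_elbow", "right_wrist"))
  expect_equal(unname(exercise_triple("R7", side = "left")[2]), "left_elbow")
})

test_that("a noiseless frontal elbow-flexion scene recovers 90 degrees", {
  session <- generate_session(arm_scene("R7", 90, "frontal", 3),
                              noise = noise_model(seed = 1))
  est <- estimate_angle(session$frames, session$frames[[1]]$detection,
                        "R7", method = "F")
  expect_lt(abs(est$theta_deg - 90), 5)
  # bit-identical on replay
  est2 <- estimate_angle(session$frames, session$frames[[1]]$detection,
                         "R7", method = "F")
  expect_identical(est$theta_deg, est2$theta_deg)
})

test_that("iterations without a person or without nearby points are skipped", {
  session <- generate_session(arm_scene("RA", 90, "frontal", 3),
                              noise = noise_model(seed = 1))
  session$frames[[1]]$detection <- NULL
  series <- estimate_session(session, "S")
  skips <- attr(series, "skips")
  expect_equal(nrow(series) + nrow(skips), length(session$frames))
  expect_true(1L %in% skips$iteration)
  expect_match(skips$reason[skips$iteration == 1L], "no detection")

  # a keypoint below the confidence threshold makes the joint unusable
  f1 <- session$frames[[2]]
  det <- f1$detection
  det$keypoints$confidence[det$keypoints$joint == "right_wrist"] <- 0.1
  expect_error(estimate_angle(list(f1), det, "RA", method = "S"),
               class = "lidarom_skip")
})

test_that("method F groups frames into sweeps of 11 with replication", {
  session <- generate_session(arm_scene("RA", 60, "frontal", 3),
                              noise = noise_model(seed = 3))
  expect_equal(length(session$frames), 10L)
  sF <- estimate_session(session, "F")
  expect_equal(nrow(sF) + nrow(attr(sF, "skips")), 1L)
  sS <- estimate_session(session, "S")
  expect_equal(nrow(sS) + nrow(attr(sS, "skips")), 10L)
})

test_that("per-pose-step means summarize a single-measurement series", {
  series <- data.frame(iteration = 1:22, theta_deg = rep(c(10, 20), each = 11))
  pm <- pose_step_means(series, step = 11)
  expect_equal(pm$theta_deg_mean, c(10, 20))
  expect_equal(pm$n, c(11, 11))
})
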