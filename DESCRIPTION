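Package: lidarom
Title: Markerless Joint-Angle Estimation from Fused LiDAR Sweeps and Camera Keypoints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates upper-limb rehabilitation joint angles (shoulder
    abduction, shoulder flexion, elbow flexion) by fusing horizontally swept
    sparse LiDAR point clouds with 2D person keypoints detected in a
    co-mounted camera image. Sweep measurements are merged by robot-reported
    horizontal offsets, projected to the image plane, proportionally fitted
    onto the detected person, and associated to body keypoints by
    nearest-pixel selection; per-joint centroids of the recovered 3D points
    yield the joint angle via the arccosine of normalized vectors. Includes
    a virtual scene simulator (articulated arm, capsule body surfaces,
    ray-cast 16-beam LiDAR, pinhole camera, robot sweep) with known ground
    truth, an evaluation metric suite (MAE, RMSE, MAPE, NRMSE, STD, R2),
    session directory readers/writers, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
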