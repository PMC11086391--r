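test_that("pose_3d places the wrist by closed-form rotation about the humeral axis", {
  sk <- skeleton_config()
  f <- sk$forearm_length_m

  p0 <- pose_3d(sk, 0)
  expect_equal(unname(p0["right_wrist", ] - p0["right_elbow", ]),
               c(0, 0, f), tolerance = 1e-12)      # neutral: toward camera

  p90 <- pose_3d(sk, 90)
  off90 <- p90["right_wrist", ] - p90["right_elbow", ]
  expect_equal(unname(abs(off90["x"])), f, tolerance = 1e-12)  # purely lateral
  expect_equal(unname(off90["z"]), 0, tolerance = 1e-12)       # no anterior part

  p30 <- pose_3d(sk, 30)
  off30 <- p30["right_wrist", ] - p30["right_elbow", ]
  expect_equal(unname(abs(off30["x"])), f * sin(30 * pi / 180),
               tolerance = 1e-12)
  ## external rotation swings the wrist laterally, away from the trunk:
  ## for the right arm that is toward smaller world x (non-mirrored view)
  expect_lt(off30["x"], 0)
  expect_error(pose_3d(sk, 95), "<= 90")
})

test_that("trunk and upper arm are vertical and elbow flexion is 90 degrees in 3D", {
  p <- pose_3d(skeleton_config(), 37)
  expect_equal(p["right_hip", c("x", "z")], p["right_shoulder", c("x", "z")])
  expect_equal(p["right_elbow", c("x", "z")], p["right_shoulder", c("x", "z")])
  ua <- p["right_elbow", ] - p["right_shoulder", ]
  fa <- p["right_wrist", ] - p["right_elbow", ]
  expect_equal(sum(ua * fa), 0, tolerance = 1e-12)
})

test_that("orthographic projection is invariant to depth translation", {
  cam <- camera_model(projection = "orthographic")
  p <- pose_3d(skeleton_config(), 25)
  shifted <- p
  shifted[, "z"] <- shifted[, "z"] + 0.7
  expect_equal(project(p, cam), project(shifted, cam), tolerance = 1e-12)
})

test_that("at neutral rotation the wrist projects onto the elbow (frontal orthographic)", {
  cam <- camera_model(projection = "orthographic")
  uv <- project(pose_3d(skeleton_config(), 0), cam)
  expect_equal(uv["right_wrist", ], uv["right_elbow", ], tolerance = 1e-12)
})

test_that("doubling pinhole distance halves the projected trunk length", {
  p <- pose_3d(skeleton_config(), 0)
  trunk_len <- function(cam) {
    uv <- project(p, cam)
    sqrt(sum((uv["right_shoulder", ] - uv["right_hip", ])^2))
  }
  l2 <- trunk_len(camera_model(distance_m = 2))
  l4 <- trunk_len(camera_model(distance_m = 4))
  expect_equal(l2 / l4, 2, tolerance = 0.02)
})

test_that("points outside the image frame raise an error naming the role", {
  cam <- camera_model(projection = "orthographic", ortho_window_m = 0.1)
  expect_error(project(pose_3d(skeleton_config(), 0), cam), "right_hip")
})

test_that("the default plan yields 10 x 11 x 96 = 10,560 frames", {
  run <- default_noisy_run()
  expect_equal(nrow(run$features), 10560L)
  expect_equal(length(unique(run$features$clip_id)), 110L)
})

test_that("with all noise sources at zero, every frame of a clip is identical", {
  tab <- simulate_landmarks(simulation_plan(
    n_subjects = 1L, angles_deg = c(-10, 20), frames_per_clip = 4L,
    landmark_noise_sd = 0, angle_hold_sd_deg = 0, anthropometric_cv = 0,
    seed = 5L))
  dt <- as.data.frame(tab)
  for (clip in unique(dt$clip_id)) {
    sub <- dt[dt$clip_id == clip, ]
    per_role <- split(sub[, c("x", "y", "true_angle_deg")], sub$landmark_role)
    for (g in per_role) {
      expect_equal(nrow(unique(g)), 1L)
    }
  }
})

test_that("the simulation is reproducible from its seed and varies across seeds", {
  a <- small_table(seed = 9L)
  b <- small_table(seed = 9L)
  c <- small_table(seed = 10L)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(isTRUE(all.equal(a$x, c$x)))
})

test_that("degenerate plans are rejected", {
  expect_error(simulation_plan(n_subjects = 0L), "degenerate")
  expect_error(simulation_plan(angles_deg = numeric(0)), "degenerate")
  expect_error(simulation_plan(angles_deg = c(10, -10)), "ascending")
})

test_that("projected elbow angle is 90 degrees for nonzero rotation (orthographic, no noise)", {
  cam <- camera_model(projection = "orthographic")
  sk <- skeleton_config()
  for (theta in c(-50, -10, 5, 30, 90)) {
    pts <- project(pose_3d(sk, theta), cam)
    f <- compute_features(pts)
    expect_equal(unname(f["elbow_angle"]), 90, tolerance = 1e-9)
  }
})

test_that("trunk normalization absorbs camera distance (pinhole, 1.5-3 m)", {
  ## The raw parallelogram area scales as 1/distance^2; dividing by the
  ## squared projected trunk cancels that scale. What remains is forearm
  ## parallax (the forearm points toward the camera), which is small
  ## relative to the feature's design range but not zero.
  sk <- skeleton_config()
  thetas <- seq(-50, 50, by = 5)
  ds <- c(1.5, 2, 2.5, 3)
  vals <- sapply(ds, function(d) {
    cam <- camera_model(distance_m = d)
    vapply(thetas, function(th) {
      pts <- project(pose_3d(sk, th), cam)
      f <- compute_features(pts)
      c(f[["norm_elbow_size"]],
        unname(cross2d(pts["right_elbow", ] - pts["right_shoulder", ],
                       pts["right_wrist", ] - pts["right_elbow", ])))
    }, numeric(2))
  })
  nes <- vals[seq(1, nrow(vals), 2), ]   # normalized
  raw <- vals[seq(2, nrow(vals), 2), ]   # unnormalized area
  rel_dev <- function(m) {
    max(abs(m - m[, 2])) / diff(range(m[, 2]))   # vs the 2 m reference
  }
  expect_lt(rel_dev(nes), 0.05)
  expect_gt(rel_dev(raw) / rel_dev(nes), 5)   # normalization buys >5x stability
})
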