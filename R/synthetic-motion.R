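#' Skeleton segment lengths for the simulated subject
#'
#' Segment lengths default to standard anthropometric proportions of
#' stature: trunk (shoulder to hip) 0.288, biacromial (shoulder) width
#' 0.245, upper arm 0.186, forearm 0.146 and shoulder height 0.818 times
#' body height. The default stature of 1.683 m matches the mean height of
#' the cohort the simulator emulates.
#'
#' @param stature_m body height in meters used to derive the defaults.
#' @param trunk_length_m,shoulder_width_m,upper_arm_length_m,forearm_length_m,shoulder_height_m
#'   explicit segment lengths in meters; override the stature-derived values.
#' @return a `skeleton_config` list.
#' @export
skeleton_config <- function(stature_m = 1.683,
                            trunk_length_m = 0.288 * stature_m,
                            shoulder_width_m = 0.245 * stature_m,
                            upper_arm_length_m = 0.186 * stature_m,
                            forearm_length_m = 0.146 * stature_m,
                            shoulder_height_m = 0.818 * stature_m) {
  cfg <- list(
    trunk_length_m = trunk_length_m,
    shoulder_width_m = shoulder_width_m,
    upper_arm_length_m = upper_arm_length_m,
    forearm_length_m = forearm_length_m,
    shoulder_height_m = shoulder_height_m
  )
  if (any(unlist(cfg) <= 0)) {
    stop("all skeleton segment lengths must be strictly positive", call. = FALSE)
  }
  structure(cfg, class = "skeleton_config")
}

#' Camera model for projecting 3D poses to normalized image coordinates
#'
#' The default emulates the recording setup: a portrait-orientation camera
#' 2 m in front of the subject at 1.5 m height. `pinhole` performs
#' perspective division with the given horizontal field of view;
#' `orthographic` drops the depth axis and maps a fixed metric window
#' (height `ortho_window_m`, width `ortho_window_m * image_aspect`,
#' centered at camera height) onto the unit image square. Image y
#' increases downward.
#'
#' @param distance_m camera distance from the subject's coronal plane (m).
#' @param height_m camera height above the floor (m).
#' @param projection `"pinhole"` or `"orthographic"`.
#' @param horizontal_fov_deg pinhole horizontal field of view, degrees.
#' @param image_aspect image width:height ratio (portrait 1080x1920 default).
#' @param ortho_window_m height in meters of the orthographic view window.
#' @return a `camera_model` list.
#' @export
camera_model <- function(distance_m = 2, height_m = 1.5,
                         projection = c("pinhole", "orthographic"),
                         horizontal_fov_deg = 65,
                         image_aspect = 1080 / 1920,
                         ortho_window_m = 2.2) {
  projection <- match.arg(projection)
  if (distance_m <= 0) stop("distance_m must be > 0", call. = FALSE)
  if (projection == "pinhole" &&
      (horizontal_fov_deg <= 0 || horizontal_fov_deg >= 180)) {
    stop("horizontal_fov_deg must be in (0, 180)", call. = FALSE)
  }
  structure(list(
    distance_m = distance_m, height_m = height_m, projection = projection,
    horizontal_fov_deg = horizontal_fov_deg, image_aspect = image_aspect,
    ortho_window_m = ortho_window_m
  ), class = "camera_model")
}

#' Simulation plan: subjects, target angles and noise levels
#'
#' The defaults emulate the study design: 10 subjects, 11 target angles
#' from -50 to +50 degrees in 10-degree steps (internal rotation
#' negative), 96 frames per clip (about 3 s at 30 fps, giving a 10,560
#' frame dataset), Gaussian landmark jitter of 0.002 normalized units,
#' 5% between-subject anthropometric variation and 1 degree of
#' within-clip wobble around the target angle.
#'
#' @param n_subjects number of simulated subjects.
#' @param angles_deg target rotation angles, degrees, ascending.
#' @param frames_per_clip frames per (subject, angle) clip.
#' @param landmark_noise_sd sd of per-coordinate Gaussian jitter,
#'   normalized image units.
#' @param anthropometric_cv coefficient of variation of per-subject segment
#'   lengths.
#' @param angle_hold_sd_deg sd in degrees of per-frame wobble around the
#'   clip's target angle.
#' @param seed integer RNG seed making the simulation reproducible.
#' @return a `simulation_plan` list.
#' @export
simulation_plan <- function(n_subjects = 10L,
                            angles_deg = seq(-50, 50, by = 10),
                            frames_per_clip = 96L,
                            landmark_noise_sd = 0.002,
                            anthropometric_cv = 0.05,
                            angle_hold_sd_deg = 1,
                            seed = 42L) {
  if (n_subjects < 1L || frames_per_clip < 1L || length(angles_deg) < 1L) {
    stop("simulation plan is degenerate: need at least one subject, angle and frame",
         call. = FALSE)
  }
  if (is.unsorted(angles_deg, strictly = TRUE)) {
    stop("angles_deg must be strictly ascending", call. = FALSE)
  }
  if (landmark_noise_sd < 0 || anthropometric_cv < 0 || angle_hold_sd_deg < 0) {
    stop("noise levels must be nonnegative", call. = FALSE)
  }
  structure(list(
    n_subjects = as.integer(n_subjects), angles_deg = as.numeric(angles_deg),
    frames_per_clip = as.integer(frames_per_clip),
    landmark_noise_sd = landmark_noise_sd,
    anthropometric_cv = anthropometric_cv,
    angle_hold_sd_deg = angle_hold_sd_deg, seed = as.integer(seed)
  ), class = "simulation_plan")
}

#' Forward kinematics of the standing pose at a given rotation angle
#'
#' World frame: x toward the camera's image-right, y up, z from the subject
#' toward the camera. The subject stands facing the camera, so their right
#' side lies at negative x (smaller image x: non-mirrored video). The trunk
#' is vertical, the right upper arm hangs vertically at the side, and the
#' forearm — elbow flexed 90 degrees — lies horizontal, rotated by
#' `theta_deg` about the vertical humeral axis. At theta = 0 the forearm
#' points straight at the camera; positive theta (external rotation) swings
#' the wrist laterally, away from the trunk.
#'
#' @param skeleton a [skeleton_config].
#' @param theta_deg rotation angle in degrees, |theta| <= 90.
#' @return 5 x 3 matrix of 3D points (meters), rows named by landmark role,
#'   columns `x`, `y`, `z`.
#' @export
pose_3d <- function(skeleton, theta_deg) {
  stopifnot(inherits(skeleton, "skeleton_config"))
  if (abs(theta_deg) > 90) stop("|theta_deg| must be <= 90", call. = FALSE)
  s <- skeleton
  th <- theta_deg * pi / 180
  rs <- c(-s$shoulder_width_m / 2, s$shoulder_height_m, 0)
  ls <- c(+s$shoulder_width_m / 2, s$shoulder_height_m, 0)
  rh <- rs - c(0, s$trunk_length_m, 0)
  re <- rs - c(0, s$upper_arm_length_m, 0)
  ## forearm horizontal; external rotation (+theta) sweeps toward -x (lateral)
  rw <- re + s$forearm_length_m * c(-sin(th), 0, cos(th))
  m <- rbind(left_shoulder = ls, right_shoulder = rs, right_elbow = re,
             right_wrist = rw, right_hip = rh)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Project 3D world points to normalized image coordinates
#'
#' @param points3d numeric matrix with columns x, y, z (meters) and rows
#'   named by landmark role, as from [pose_3d()].
#' @param camera a [camera_model].
#' @param check if `TRUE` (default), error when a point projects outside
#'   the unit image square, naming the offending role.
#' @return matrix with columns `x`, `y` in \[0, 1\] (y down), same rownames.
#' @export
project <- function(points3d, camera, check = TRUE) {
  stopifnot(inherits(camera, "camera_model"))
  uv <- project_xyz(points3d[, 1], points3d[, 2], points3d[, 3], camera)
  m <- cbind(x = uv$u, y = uv$v)
  rownames(m) <- rownames(points3d)
  if (check) {
    out <- m[, 1] < 0 | m[, 1] > 1 | m[, 2] < 0 | m[, 2] > 1
    if (any(out)) {
      stop("point(s) project outside the image frame: ",
           paste(rownames(m)[out], collapse = ", "), call. = FALSE)
    }
  }
  m
}

## Vectorized projection core shared by project() and simulate_landmarks().
project_xyz <- function(x, y, z, camera) {
  if (camera$projection == "orthographic") {
    w <- camera$ortho_window_m * camera$image_aspect
    u <- 0.5 + x / w
    v <- 0.5 - (y - camera$height_m) / camera$ortho_window_m
  } else {
    zc <- camera$distance_m - z           # depth along the optical axis
    if (any(zc <= 0)) stop("point(s) behind the pinhole camera", call. = FALSE)
    tan_h <- tan(camera$horizontal_fov_deg / 2 * pi / 180)
    tan_v <- tan_h / camera$image_aspect  # vertical half-window at unit depth
    u <- 0.5 + (x / zc) / (2 * tan_h)
    v <- 0.5 - ((y - camera$height_m) / zc) / (2 * tan_v)
  }
  list(u = u, v = v)
}

#' Simulate a landmark dataset with known ground-truth angles
#'
#' Renders `n_subjects x length(angles_deg)` clips of `frames_per_clip`
#' frames each. Per subject, segment lengths are drawn once from Gaussians
#' with coefficient of variation `anthropometric_cv` around the base
#' skeleton. Per frame, the realized angle is the clip target plus
#' Gaussian wobble (recorded as `true_angle_deg`), the pose is projected
#' through `camera`, and each landmark coordinate is jittered by iid
#' Gaussian noise then clamped to \[0, 1\]. Fully reproducible from
#' `plan$seed`.
#'
#' @param plan a [simulation_plan].
#' @param skeleton_base a [skeleton_config]; per-subject skeletons vary
#'   around it.
#' @param camera a [camera_model].
#' @return a [landmark_table] with `source = "synthetic"`.
#' @export
simulate_landmarks <- function(plan = simulation_plan(),
                               skeleton_base = skeleton_config(),
                               camera = camera_model()) {
  stopifnot(inherits(plan, "simulation_plan"),
            inherits(skeleton_base, "skeleton_config"),
            inherits(camera, "camera_model"))
  with_preserved_seed(plan$seed, {
    clips <- vector("list", plan$n_subjects * length(plan$angles_deg))
    k <- 0L
    for (subj in seq_len(plan$n_subjects)) {
      skel <- perturb_skeleton(skeleton_base, plan$anthropometric_cv)
      for (target in plan$angles_deg) {
        k <- k + 1L
        clips[[k]] <- simulate_clip(
          subject_id = sprintf("S%02d", subj),
          clip_id = sprintf("S%02d_a%+04.0f", subj, target),
          target = target, skel = skel, camera = camera, plan = plan
        )
      }
    }
    landmark_table(rbindlist(clips), source = "synthetic", on_range = "clamp")
  })
}

perturb_skeleton <- function(base, cv) {
  vals <- unlist(base, use.names = TRUE)
  drawn <- vals * (1 + rnorm(length(vals), 0, cv))
  drawn <- pmax(drawn, 0.05 * vals)   # guard against nonphysical draws
  do.call(skeleton_config, c(as.list(drawn), list(stature_m = 1)))
}

simulate_clip <- function(subject_id, clip_id, target, skel, camera, plan) {
  nf <- plan$frames_per_clip
  theta <- target + rnorm(nf, 0, plan$angle_hold_sd_deg)
  theta <- pmin(pmax(theta, -90), 90)
  th <- theta * pi / 180

  ## static landmarks (per clip); only the wrist moves with theta
  base <- pose_3d(skel, 0)
  roles <- LANDMARK_ROLES
  n_roles <- length(roles)
  x3 <- matrix(rep(base[roles, "x"], each = nf), nrow = nf)
  y3 <- matrix(rep(base[roles, "y"], each = nf), nrow = nf)
  z3 <- matrix(rep(base[roles, "z"], each = nf), nrow = nf)
  wi <- match("right_wrist", roles)
  re <- base["right_elbow", ]
  x3[, wi] <- re["x"] - skel$forearm_length_m * sin(th)
  z3[, wi] <- re["z"] + skel$forearm_length_m * cos(th)

  uv <- project_xyz(as.vector(x3), as.vector(y3), as.vector(z3), camera)
  u <- uv$u; v <- uv$v
  if (plan$landmark_noise_sd > 0) {
    u <- u + rnorm(length(u), 0, plan$landmark_noise_sd)
    v <- v + rnorm(length(v), 0, plan$landmark_noise_sd)
  }
  data.table(
    subject_id = subject_id, clip_id = clip_id,
    frame_index = rep(seq_len(nf) - 1L, times = n_roles),
    true_angle_deg = rep(theta, times = n_roles),
    landmark_role = rep(roles, each = nf),
    x = pmin(pmax(u, 0), 1), y = pmin(pmax(v, 0), 1)
  )
}

#' Nominal (clip-target) angles of a simulated table
#'
#' Recovers each clip's target angle from its clip id (`"S01_a-050"` form).
#' @param x a landmark or feature table with a `clip_id` column.
#' @return numeric vector of nominal angles, one per row.
#' @export
nominal_angle <- function(x) {
  as.numeric(sub("^.*_a", "", x$clip_id))
}
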