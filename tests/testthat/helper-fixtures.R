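## Hand-constructible landmark frame whose seven features are known in
## closed form: trunk vertical of length 0.30, upper arm vertical 0.15,
## forearm horizontal 0.12, shoulders horizontal 0.20 apart.
hand_points <- function() {
  m <- rbind(
    left_shoulder  = c(0.40, 0.40),
    right_shoulder = c(0.60, 0.40),
    right_elbow    = c(0.60, 0.55),
    right_wrist    = c(0.72, 0.55),
    right_hip      = c(0.60, 0.70)
  )
  colnames(m) <- c("x", "y")
  m
}

hand_frame_table <- function() {
  pts <- hand_points()
  landmark_table(data.frame(
    subject_id = "S01", clip_id = "c1", frame_index = 0L,
    true_angle_deg = 12.3,
    landmark_role = rownames(pts), x = pts[, 1], y = pts[, 2]
  ), source = "imported")
}

## Random valid point sets: five landmarks drawn in a central box so that
## translations/scalings in the property tests stay inside [0, 1].
random_points <- function() {
  m <- matrix(runif(10, 0.3, 0.7), ncol = 2,
              dimnames = list(rownames(hand_points()), c("x", "y")))
  m
}

## Small synthetic table for I/O and pipeline tests.
small_table <- function(seed = 1L, n_subjects = 2L, frames = 5L, ...) {
  simulate_landmarks(simulation_plan(
    n_subjects = n_subjects, frames_per_clip = frames, seed = seed, ...))
}

## Noiseless linear training data: true_angle_deg = 10 * norm_elbow_size,
## other features uninformative noise.
linear_feature_rows <- function(n = 50L, seed = 3L) {
  set.seed(seed)
  df <- as.data.frame(matrix(runif(n * 7, -1, 1), ncol = 7))
  names(df) <- FEATURE_NAMES
  df$true_angle_deg <- 10 * df$norm_elbow_size
  df$subject_id <- "S01"
  df$clip_id <- "c1"
  df$frame_index <- seq_len(n) - 1L
  df
}
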