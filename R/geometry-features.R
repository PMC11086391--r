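#' Signed 2D cross product
#'
#' `cross2d(u, v)` returns `u_x v_y - u_y v_x`, the z-component of the 3D
#' cross product of the two vectors embedded in the plane. Its magnitude is
#' the area of the parallelogram the vectors span; the sign encodes
#' orientation, which is what lets the downstream features distinguish
#' internal (negative) from external (positive) rotation.
#'
#' @param u,v numeric 2-vectors, or two-column matrices (rowwise).
#' @return signed scalar (or vector, for matrix input).
#' @export
cross2d <- function(u, v) {
  if (is.matrix(u) || is.matrix(v)) {
    u[, 1] * v[, 2] - u[, 2] * v[, 1]
  } else {
    u[1] * v[2] - u[2] * v[1]
  }
}

#' Interior angle at a vertex, in degrees
#'
#' Angle in \[0, 180\] between the rays `vertex -> p_end1` and
#' `vertex -> p_end2`.
#'
#' @param p_end1,vertex,p_end2 numeric 2-vectors (points).
#' @return degrees in \[0, 180\].
#' @export
angle_at_vertex <- function(p_end1, vertex, p_end2) {
  a <- p_end1 - vertex
  b <- p_end2 - vertex
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("degenerate geometry: zero-length arm at vertex", call. = FALSE)
  }
  acos(pmin(pmax(sum(a * b) / (na * nb), -1), 1)) * 180 / pi
}

#' Compute the seven geometric features of one frame
#'
#' Let a = right_shoulder -> right_elbow, b = right_elbow -> right_wrist,
#' c = right_shoulder -> right_hip and d = left_shoulder -> right_shoulder,
#' all in normalized image coordinates (y down). The features are
#' \describe{
#'   \item{norm_elbow_size}{`cross2d(a, b) / |c|^2` — signed upper-arm x
#'     forearm parallelogram area, trunk-normalized. The dominant angle
#'     cue: in frontal view it tracks sin(rotation angle).}
#'   \item{norm_shoulder_size}{`cross2d(a, d) / |c|^2`.}
#'   \item{norm_forearm_distance}{`|b| / |c|`.}
#'   \item{norm_uparm_distance}{`|a| / |c|`.}
#'   \item{elbow_angle}{angle right_shoulder - right_elbow - right_wrist.}
#'   \item{shoulder_angle}{angle right_elbow - right_shoulder - right_wrist.}
#'   \item{trunk_angle}{angle left_shoulder - right_shoulder - right_hip.}
#' }
#' All are invariant to translation and uniform scaling of the landmarks;
#' the two signed features flip sign under horizontal mirroring.
#'
#' @param frame a frame as returned by [landmark_frame()], or a two-column
#'   point matrix with rows named by landmark role.
#' @return named numeric vector of the seven features (see [FEATURE_NAMES]).
#' @export
compute_features <- function(frame) {
  pts <- if (is.matrix(frame)) frame else frame$points
  missing_roles <- setdiff(LANDMARK_ROLES, rownames(pts))
  if (length(missing_roles) > 0L) {
    stop("frame lacks landmark role(s): ",
         paste(missing_roles, collapse = ", "), call. = FALSE)
  }
  ls <- pts["left_shoulder", ]; rs <- pts["right_shoulder", ]
  re <- pts["right_elbow", ];  rw <- pts["right_wrist", ]
  rh <- pts["right_hip", ]
  a <- re - rs; b <- rw - re; cc <- rh - rs; d <- rs - ls
  c2 <- sum(cc^2)
  if (c2 == 0) {
    stop("degenerate geometry: zero trunk length (right shoulder == right hip)",
         call. = FALSE)
  }
  c(norm_elbow_size = unname(cross2d(a, b)) / c2,
    norm_shoulder_size = unname(cross2d(a, d)) / c2,
    norm_forearm_distance = sqrt(sum(b^2)) / sqrt(c2),
    norm_uparm_distance = sqrt(sum(a^2)) / sqrt(c2),
    elbow_angle = angle_at_vertex(rs, re, rw),
    shoulder_angle = angle_at_vertex(re, rs, rw),
    trunk_angle = angle_at_vertex(ls, rs, rh))
}

#' Extract the feature table from a landmark table
#'
#' Computes the seven features of [compute_features()] for every frame,
#' vectorized over the whole table. Frames with degenerate geometry (zero
#' trunk length, or a zero-length arm at an angle vertex) are skipped with
#' a message, or abort the extraction, per `on_degenerate`.
#'
#' @param table a [landmark_table].
#' @param on_degenerate `"skip"` (drop with a message) or `"error"`.
#' @return data.frame with columns `subject_id`, `clip_id`, `frame_index`,
#'   `true_angle_deg` and the seven feature columns, one row per frame in
#'   the original order.
#' @export
extract_feature_table <- function(table, on_degenerate = c("skip", "error")) {
  on_degenerate <- match.arg(on_degenerate)
  dt <- as.data.table(as.data.frame(table))
  if (nrow(dt) == 0L) {
    out <- data.table(subject_id = character(), clip_id = character(),
                      frame_index = integer(), true_angle_deg = numeric())
    for (f in FEATURE_NAMES) out[, (f) := numeric()]
    return(as.data.frame(out))
  }
  dt <- dt[landmark_role %in% LANDMARK_ROLES]
  dt[, landmark_role := factor(landmark_role, levels = LANDMARK_ROLES)]
  wide <- dcast(dt, subject_id + clip_id + frame_index + true_angle_deg ~
                  landmark_role, value.var = c("x", "y"), sep = "_")
  ## preserve the original frame order
  first_seen <- dt[, .I[1L], by = .(subject_id, clip_id, frame_index)]
  ord <- first_seen[order(V1)]
  wide <- wide[ord[, .(subject_id, clip_id, frame_index)],
               on = c("subject_id", "clip_id", "frame_index")]

  ax <- wide$x_right_elbow - wide$x_right_shoulder
  ay <- wide$y_right_elbow - wide$y_right_shoulder
  bx <- wide$x_right_wrist - wide$x_right_elbow
  by <- wide$y_right_wrist - wide$y_right_elbow
  cx <- wide$x_right_hip - wide$x_right_shoulder
  cy <- wide$y_right_hip - wide$y_right_shoulder
  dx <- wide$x_right_shoulder - wide$x_left_shoulder
  dy <- wide$y_right_shoulder - wide$y_left_shoulder
  wx <- wide$x_right_wrist - wide$x_right_shoulder   # shoulder -> wrist
  wy <- wide$y_right_wrist - wide$y_right_shoulder

  c2 <- cx^2 + cy^2
  na <- sqrt(ax^2 + ay^2); nb <- sqrt(bx^2 + by^2)
  nw <- sqrt(wx^2 + wy^2); nd <- sqrt(dx^2 + dy^2); nc <- sqrt(c2)

  degenerate <- c2 == 0 | na == 0 | nb == 0 | nw == 0 | nd == 0
  if (any(degenerate)) {
    if (on_degenerate == "error") {
      bad <- wide[which(degenerate)[1L]]
      stop(sprintf(
        "degenerate geometry at (subject %s, clip %s, frame %d)",
        bad$subject_id, bad$clip_id, bad$frame_index), call. = FALSE)
    }
    message(sum(degenerate), " degenerate frame(s) skipped")
  }

  ang <- function(ux, uy, vx, vy, nu, nv) {
    acos(pmin(pmax((ux * vx + uy * vy) / (nu * nv), -1), 1)) * 180 / pi
  }
  out <- wide[, .(subject_id, clip_id, frame_index, true_angle_deg)]
  out[, norm_elbow_size := (ax * by - ay * bx) / c2]
  out[, norm_shoulder_size := (ax * dy - ay * dx) / c2]
  out[, norm_forearm_distance := nb / nc]
  out[, norm_uparm_distance := na / nc]
  out[, elbow_angle := ang(-ax, -ay, bx, by, na, nb)]
  out[, shoulder_angle := ang(ax, ay, wx, wy, na, nw)]
  out[, trunk_angle := ang(-dx, -dy, cx, cy, nd, nc)]
  out <- out[!degenerate]
  if (nrow(out) == 0L) {
    stop("every frame was degenerate; no features extracted", call. = FALSE)
  }
  setDF(out)
  out
}
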