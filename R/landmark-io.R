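#' Construct a validated landmark table
#'
#' A landmark table is the package's container for per-frame 2D pose
#' landmarks: one row per (frame, landmark role), with coordinates in
#' normalized image fractions (x divided by image width, y by image height,
#' both in \[0, 1\], y increasing downward) and a ground-truth rotation
#' angle label per frame (internal rotation negative).
#'
#' @param frames data.frame with columns `subject_id`, `clip_id`,
#'   `frame_index`, `true_angle_deg`, `landmark_role`, `x`, `y` and
#'   optionally `visibility`. Roles beyond the five in [LANDMARK_ROLES] are
#'   allowed; they are preserved but ignored by feature extraction.
#' @param source provenance tag, `"synthetic"` or `"imported"`.
#' @param on_range what to do with coordinates outside \[0, 1\]:
#'   `"reject"` (error) or `"clamp"`.
#' @return a `landmark_table`: a data.frame with the columns above and a
#'   `source` attribute.
#' @export
landmark_table <- function(frames, source = c("imported", "synthetic"),
                           on_range = c("reject", "clamp")) {
  source <- match.arg(source)
  on_range <- match.arg(on_range)
  required <- c("subject_id", "clip_id", "frame_index", "true_angle_deg",
                "landmark_role", "x", "y")
  missing_cols <- setdiff(required, names(frames))
  if (length(missing_cols) > 0L) {
    stop("landmark table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dt <- as.data.table(frames)
  dt[, subject_id := as.character(subject_id)]
  dt[, clip_id := as.character(clip_id)]
  dt[, frame_index := as.integer(frame_index)]

  if (nrow(dt) > 0L) {
    if (anyNA(dt$x) || anyNA(dt$y) || any(!is.finite(dt$x)) || any(!is.finite(dt$y))) {
      stop("landmark coordinates must be finite", call. = FALSE)
    }
    if (any(dt$frame_index < 0L)) {
      stop("frame_index must be nonnegative", call. = FALSE)
    }
    if (any(!is.finite(dt$true_angle_deg))) {
      stop("true_angle_deg must be finite", call. = FALSE)
    }
    out <- dt$x < 0 | dt$x > 1 | dt$y < 0 | dt$y > 1
    if (any(out)) {
      if (on_range == "reject") {
        bad <- dt[which(out)[1L]]
        stop(sprintf(
          "coordinate outside [0, 1] for %s at (subject %s, clip %s, frame %d)",
          bad$landmark_role, bad$subject_id, bad$clip_id, bad$frame_index
        ), call. = FALSE)
      }
      dt[, x := pmin(pmax(x, 0), 1)]
      dt[, y := pmin(pmax(y, 0), 1)]
    }
    ## each frame must carry all five required roles
    have <- dt[landmark_role %in% LANDMARK_ROLES,
               .(n_roles = uniqueN(landmark_role)),
               by = .(subject_id, clip_id, frame_index)]
    short <- have[have$n_roles < length(LANDMARK_ROLES)]
    all_keys <- unique(dt[, .(subject_id, clip_id, frame_index)])
    absent <- all_keys[!have, on = c("subject_id", "clip_id", "frame_index")]
    if (nrow(absent) > 0L) short <- rbind(short, absent, fill = TRUE)
    if (nrow(short) > 0L) {
      bad <- short[1L]
      stop(sprintf(
        "frame (subject %s, clip %s, frame %d) lacks one of the required landmark roles [%s]",
        bad$subject_id, bad$clip_id, bad$frame_index,
        paste(LANDMARK_ROLES, collapse = ", ")
      ), call. = FALSE)
    }
    dup <- dt[, .N, by = .(subject_id, clip_id, frame_index, landmark_role)]
    if (any(dup$N > 1L)) {
      bad <- dup[dup$N > 1L][1L]
      stop(sprintf(
        "duplicate landmark %s in frame (subject %s, clip %s, frame %d)",
        bad$landmark_role, bad$subject_id, bad$clip_id, bad$frame_index
      ), call. = FALSE)
    }
  }
  out <- as.data.frame(dt)
  attr(out, "source") <- source
  class(out) <- c("landmark_table", "data.frame")
  out
}

#' @export
print.landmark_table <- function(x, ...) {
  keys <- unique(x[, c("subject_id", "clip_id", "frame_index")])
  cat(sprintf(
    "<landmark_table> %d frames, %d landmark rows, %d subject(s), source: %s\n",
    nrow(keys), nrow(x), length(unique(x$subject_id)),
    attr(x, "source") %||% "imported"
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of distinct frames in a landmark table
#' @param table a `landmark_table`.
#' @return integer frame count.
#' @export
n_frames <- function(table) {
  nrow(unique(table[, c("subject_id", "clip_id", "frame_index")]))
}

#' Extract one frame's landmarks as a named point set
#'
#' @param table a `landmark_table`.
#' @param subject_id,clip_id,frame_index frame key.
#' @return list with the frame key, `true_angle_deg`, and `points`: a
#'   two-column matrix (x, y) with one row per landmark role.
#' @export
landmark_frame <- function(table, subject_id, clip_id, frame_index) {
  rows <- table[table$subject_id == subject_id & table$clip_id == clip_id &
                  table$frame_index == frame_index, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop(sprintf("no frame (subject %s, clip %s, frame %d)",
                 subject_id, clip_id, frame_index), call. = FALSE)
  }
  pts <- as.matrix(rows[, c("x", "y")])
  rownames(pts) <- rows$landmark_role
  list(subject_id = subject_id, clip_id = clip_id,
       frame_index = as.integer(frame_index),
       true_angle_deg = rows$true_angle_deg[1L], points = pts)
}

#' Read a landmark table from disk
#'
#' Two dialects are supported. `long_csv` is the package's tidy format: one
#' row per (frame, landmark role) with columns `subject_id, clip_id,
#' frame_index, true_angle_deg, landmark_role, x, y`. `mediapipe_json` is a
#' JSON array of frame objects each carrying a 33-element `landmarks` array
#' of `{x, y, z, visibility}` in the standard full-body indexing; indices
#' 11/12/14/16/24 map to the five named roles, `z` is discarded, and
#' `visibility` is kept as optional metadata.
#'
#' @param path file to read.
#' @param dialect `"long_csv"` or `"mediapipe_json"`.
#' @param source provenance tag stored on the result.
#' @param on_range `"reject"` or `"clamp"` for out-of-range coordinates.
#' @return a validated [landmark_table].
#' @export
read_landmark_table <- function(path, dialect = c("long_csv", "mediapipe_json"),
                                source = c("imported", "synthetic"),
                                on_range = c("reject", "clamp")) {
  dialect <- match.arg(dialect)
  source <- match.arg(source)
  on_range <- match.arg(on_range)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "long_csv") {
    dt <- fread(path, colClasses = list(
      character = c("subject_id", "clip_id", "landmark_role")))
  } else {
    frames <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    dt <- rbindlist(lapply(frames, mediapipe_frame_to_long))
  }
  landmark_table(dt, source = source, on_range = on_range)
}

mediapipe_frame_to_long <- function(fr) {
  lms <- fr$landmarks
  if (is.null(lms)) stop("mediapipe_json frame lacks a 'landmarks' array",
                         call. = FALSE)
  idx_to_role <- setNames(names(MEDIAPIPE_INDEX), MEDIAPIPE_INDEX)
  rows <- lapply(seq_along(lms), function(i) {
    lm <- lms[[i]]
    if (is.null(lm) || is.null(lm$x)) return(NULL)
    idx0 <- i - 1L           # dialect indices are 0-based
    role <- idx_to_role[as.character(idx0)]
    if (is.na(role)) role <- sprintf("mp_%02d", idx0)
    data.table(landmark_role = unname(role), x = lm$x, y = lm$y,
               visibility = lm$visibility %||% NA_real_)
  })
  out <- rbindlist(rows)
  out[, `:=`(subject_id = as.character(fr$subject_id),
             clip_id = as.character(fr$clip_id),
             frame_index = as.integer(fr$frame_index),
             true_angle_deg = as.numeric(fr$true_angle_deg))]
  out
}

#' Write a landmark table to disk
#'
#' Coordinates are serialized at 9 decimal digits, so a written table
#' re-reads to within 5e-10 of the original (and round-trips exactly once
#' quantized). For `mediapipe_json`, named roles are placed at their
#' standard 0-based indices in a 33-element array; positions the table does
#' not cover are `null`.
#'
#' @param table a `landmark_table`.
#' @param path output file.
#' @param dialect `"long_csv"` or `"mediapipe_json"`.
#' @return `path`, invisibly.
#' @export
write_landmark_table <- function(table, path,
                                 dialect = c("long_csv", "mediapipe_json")) {
  dialect <- match.arg(dialect)
  dt <- as.data.table(as.data.frame(table))
  if (dialect == "long_csv") {
    out <- copy(dt)
    out[, x := sprintf("%.9f", x)]
    out[, y := sprintf("%.9f", y)]
    keep <- intersect(
      c("subject_id", "clip_id", "frame_index", "true_angle_deg",
        "landmark_role", "x", "y", "visibility"), names(out))
    fwrite(out[, ..keep], path)
  } else {
    role_to_idx <- c(MEDIAPIPE_INDEX)     # named 0-based indices
    keys <- unique(dt[, .(subject_id, clip_id, frame_index, true_angle_deg)])
    frames <- lapply(seq_len(nrow(keys)), function(i) {
      k <- keys[i]
      rows <- dt[k, on = c("subject_id", "clip_id", "frame_index")]
      arr <- rep(list(NULL), 33L)
      for (j in seq_len(nrow(rows))) {
        role <- rows$landmark_role[j]
        idx0 <- if (role %in% names(role_to_idx)) {
          role_to_idx[[role]]
        } else if (grepl("^mp_[0-9]+$", role)) {
          as.integer(sub("^mp_", "", role))
        } else {
          NA_integer_
        }
        if (is.na(idx0) || idx0 < 0L || idx0 > 32L) next
        vis <- if ("visibility" %in% names(rows)) rows$visibility[j] else NA_real_
        pt <- list(x = round(rows$x[j], 9), y = round(rows$y[j], 9), z = 0)
        if (!is.na(vis)) pt$visibility <- vis
        arr[[idx0 + 1L]] <- pt
      }
      list(subject_id = k$subject_id, clip_id = k$clip_id,
           frame_index = k$frame_index, true_angle_deg = k$true_angle_deg,
           landmarks = arr)
    })
    jsonlite::write_json(frames, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}
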