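#' Default joint vocabulary (18-joint COCO-style body set)
#'
#' The upper-body camera view captures face and upper body; the two wrist
#' joints proxy the hands that hold the dolls.
#'
#' @return character vector of 18 joint names in keypoint order.
#' @export
coco_joints <- function() {
  c("nose", "neck",
    "right_shoulder", "right_elbow", "right_wrist",
    "left_shoulder", "left_elbow", "left_wrist",
    "right_hip", "right_knee", "right_ankle",
    "left_hip", "left_knee", "left_ankle",
    "right_eye", "left_eye", "right_ear", "left_ear")
}

#' Construct a validated pose-keypoint sequence
#'
#' One child session: per-frame keypoint coordinates in pixel units
#' (origin top-left, x rightward, y downward) with per-keypoint detection
#' confidence in \[0, 1\]. Absent keypoints are encoded with confidence 0
#' and NA coordinates.
#'
#' @param child_id opaque identifier.
#' @param frame_rate frames per second, > 0.
#' @param image_width,image_height image geometry in pixels, > 0.
#' @param x,y,conf numeric matrices, one row per frame and one column per
#'   joint (`joints` order).
#' @param joints joint names; defaults to [coco_joints()].
#' @param frame_index integer frame indices, strictly increasing;
#'   defaults to `0:(T-1)`.
#' @param time frame times in seconds; defaults to
#'   `frame_index / frame_rate`.
#' @return object of class `"pose_sequence"`.
#' @export
pose_sequence <- function(child_id, frame_rate, image_width, image_height,
                          x, y, conf, joints = coco_joints(),
                          frame_index = NULL, time = NULL) {
  x <- as.matrix(x); y <- as.matrix(y); conf <- as.matrix(conf)
  n <- nrow(x)
  if (!identical(dim(x), dim(y)) || !identical(dim(x), dim(conf)))
    stop("x, y and conf must have identical dimensions", call. = FALSE)
  if (ncol(x) != length(joints))
    stop("keypoint matrices must have one column per joint", call. = FALSE)
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop("frame_rate must be positive", call. = FALSE)
  if (image_width <= 0 || image_height <= 0)
    stop("image dimensions must be positive", call. = FALSE)
  if (any(conf < 0 | conf > 1, na.rm = TRUE))
    stop("confidence must lie in [0, 1]", call. = FALSE)
  if (is.null(frame_index)) frame_index <- seq_len(n) - 1L
  frame_index <- as.integer(frame_index)
  if (n > 1 && any(diff(frame_index) <= 0))
    stop("frame_index must be strictly increasing", call. = FALSE)
  if (is.null(time)) time <- frame_index / frame_rate
  # absent keypoints: confidence exactly 0, coordinates NA
  absent <- !is.na(conf) & conf == 0
  x[absent] <- NA_real_; y[absent] <- NA_real_
  colnames(x) <- colnames(y) <- colnames(conf) <- joints
  structure(
    list(child_id = as.character(child_id), frame_rate = frame_rate,
         image_width = image_width, image_height = image_height,
         joints = joints, frame_index = frame_index, time = as.numeric(time),
         x = x, y = y, conf = conf),
    class = "pose_sequence")
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf(
    "<pose_sequence> child '%s': %d frames @ %g fps, %dx%d px, %d joints\n",
    x$child_id, n_frames(x), x$frame_rate,
    x$image_width, x$image_height, length(x$joints)))
  invisible(x)
}

#' @rdname pose_sequence
#' @param seq a `pose_sequence`.
#' @return `n_frames()` returns the number of frames.
#' @export
n_frames <- function(seq) nrow(seq$x)

apply_missing_threshold <- function(seq, missing_threshold) {
  # keypoints below the threshold are treated as absent; monotone in the
  # threshold because the original confidences are never altered upward
  absent <- is.na(seq$conf) | seq$conf < missing_threshold | seq$conf == 0
  seq$conf[absent] <- 0
  seq$x[absent] <- NA_real_
  seq$y[absent] <- NA_real_
  seq
}

#' Read an OpenPose-style pose-keypoint session from JSON
#'
#' Accepts either a single session file or a directory. A session file is
#' a JSON object with metadata fields `child_id`, `fps`, `width`,
#' `height`, optional `joint_names`, and a `frames` array; each frame
#' record holds `people[[i]]$pose_keypoints_2d`, a flat
#' `[x1, y1, c1, x2, y2, c2, ...]` triplet vector, plus an optional
#' `frame_index`. A directory must contain a `header.json` with the same
#' metadata and one JSON frame record per file, concatenated in
#' lexicographic filename order.
#'
#' When a frame contains several detected people the one with the largest
#' keypoint bounding box is kept (the child is the near subject); the
#' event is reported via `message()`.
#'
#' @param path session file or directory.
#' @param missing_threshold keypoints with confidence below this are
#'   marked absent (confidence exactly 0 is always absent). Default 0.1.
#' @return a validated [pose_sequence()].
#' @export
read_pose_json <- function(path, missing_threshold = 0.1) {
  if (dir.exists(path)) {
    header_path <- file.path(path, "header.json")
    if (!file.exists(header_path))
      stop("pose directory is missing header.json", call. = FALSE)
    meta <- jsonlite::read_json(header_path)
    files <- sort(setdiff(list.files(path, pattern = "\\.json$",
                                     full.names = TRUE),
                          header_path))
    frames <- lapply(files, jsonlite::read_json)
  } else {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    if (file.size(path) == 0) stop("empty pose file: ", path, call. = FALSE)
    doc <- tryCatch(jsonlite::read_json(path),
                    error = function(e) stop("malformed pose JSON: ",
                                             conditionMessage(e),
                                             call. = FALSE))
    meta <- doc
    frames <- doc$frames
  }
  if (length(frames) == 0)
    stop("pose session contains no frame records", call. = FALSE)
  joints <- if (!is.null(meta$joint_names))
    unlist(meta$joint_names) else coco_joints()
  nj <- length(joints)

  kp <- lapply(frames, function(fr) {
    people <- fr$people
    if (length(people) == 0) return(rep(c(NA_real_, NA_real_, 0), nj))
    vecs <- lapply(people, function(p) as.numeric(unlist(p$pose_keypoints_2d)))
    if (length(vecs) > 1) {
      # keep the person with the largest keypoint bounding box
      area <- vapply(vecs, function(v) {
        xs <- v[seq(1, length(v), 3)]; ys <- v[seq(2, length(v), 3)]
        cs <- v[seq(3, length(v), 3)]
        xs <- xs[cs > 0]; ys <- ys[cs > 0]
        if (length(xs) == 0) 0 else diff(range(xs)) * diff(range(ys))
      }, numeric(1))
      message("frame with ", length(vecs),
              " detected people: keeping the largest")
      vecs <- vecs[which.max(area)]
    }
    v <- vecs[[1]]
    if (length(v) != 3 * nj)
      stop("inconsistent joint count: expected ", nj, " joints, got ",
           length(v) / 3, call. = FALSE)
    v
  })
  kp <- do.call(rbind, kp)
  x <- kp[, seq(1, 3 * nj, 3), drop = FALSE]
  y <- kp[, seq(2, 3 * nj, 3), drop = FALSE]
  conf <- kp[, seq(3, 3 * nj, 3), drop = FALSE]
  conf[is.na(conf)] <- 0

  fidx <- vapply(frames, function(fr) fr$frame_index %||% NA_integer_,
                 numeric(1))
  if (anyNA(fidx)) fidx <- seq_along(frames) - 1L
  tm <- vapply(frames, function(fr) fr$time %||% NA_real_, numeric(1))
  if (anyNA(tm)) tm <- NULL

  seq <- pose_sequence(
    child_id = meta$child_id %||% "unknown",
    frame_rate = meta$fps %||% 30,
    image_width = meta$width %||% stop("header lacks width", call. = FALSE),
    image_height = meta$height %||% stop("header lacks height", call. = FALSE),
    x = x, y = y, conf = conf, joints = joints,
    frame_index = fidx, time = tm)
  apply_missing_threshold(seq, missing_threshold)
}

#' Write a pose sequence to the single-file JSON dialect
#'
#' Inverse of [read_pose_json()]: the written file parses back to a
#' sequence equal to the input field-for-field. Absent keypoints are
#' encoded as confidence 0 with coordinates 0.
#'
#' @param seq a `pose_sequence`.
#' @param path output file path.
#' @export
write_pose_json <- function(seq, path) {
  stopifnot(inherits(seq, "pose_sequence"))
  nj <- length(seq$joints)
  frames <- lapply(seq_len(n_frames(seq)), function(i) {
    v <- as.vector(rbind(seq$x[i, ], seq$y[i, ], seq$conf[i, ]))
    v[is.na(v)] <- 0
    list(frame_index = seq$frame_index[i], time = seq$time[i],
         people = list(list(pose_keypoints_2d = v)))
  })
  doc <- list(child_id = seq$child_id, fps = seq$frame_rate,
              width = seq$image_width, height = seq$image_height,
              joint_names = seq$joints, frames = frames)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a child-to-attachment-label table from CSV
#'
#' Expects a header `child_id,label` with labels in \{B, A, C, D\}.
#'
#' @param path CSV file path.
#' @return data.frame of class `"label_table"` with character columns
#'   `child_id` (unique) and `label`.
#' @export
read_labels <- function(path) {
  df <- read.csv(path, colClasses = "character")
  if (!all(c("child_id", "label") %in% names(df)))
    stop("labels CSV must have columns child_id,label", call. = FALSE)
  label_table(df$child_id, df$label)
}

#' @rdname read_labels
#' @param child_id,label character vectors.
#' @export
label_table <- function(child_id, label) {
  if (anyDuplicated(child_id)) {
    dup <- unique(child_id[duplicated(child_id)])
    stop("duplicate child_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad <- which(!(label %in% attachment_levels()))
  if (length(bad))
    stop("invalid attachment label in row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(label[bad]), collapse = ", "), call. = FALSE)
  structure(data.frame(child_id = as.character(child_id),
                       label = as.character(label),
                       stringsAsFactors = FALSE),
            class = c("label_table", "data.frame"))
}

#' @rdname read_labels
#' @param labels a `label_table`.
#' @export
write_labels <- function(labels, path) {
  write.csv(as.data.frame(labels), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_labels
#' @return `label_for()` returns the four-way code for one child.
#' @export
label_for <- function(labels, child_id) {
  i <- match(child_id, labels$child_id)
  if (is.na(i)) stop("no label for child ", child_id, call. = FALSE)
  labels$label[i]
}
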