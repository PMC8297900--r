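#' Feature-extraction configuration
#'
#' @param window_size frames per window; 128 frames is roughly 4.25 s at
#'   30 fps, the standard unit of classification.
#' @param frame_rate frames per second used when a sequence does not carry
#'   its own; default 30.
#' @param missing_policy what a missing hand's coordinates become for the
#'   kinematic channels: `"hold-last"` keeps the last seen position (so
#'   dropouts do not fabricate speed spikes; the presence flags carry the
#'   dropout information) or `"zero"`.
#' @return list of class `"feature_config"`.
#' @export
feature_config <- function(window_size = 128L, frame_rate = 30,
                           missing_policy = c("hold-last", "zero")) {
  missing_policy <- match.arg(missing_policy)
  window_size <- as.integer(window_size)
  if (window_size < 2L) stop("window_size must be >= 2", call. = FALSE)
  if (frame_rate <= 0) stop("frame_rate must be positive", call. = FALSE)
  structure(list(window_size = window_size, frame_rate = frame_rate,
                 missing_policy = missing_policy),
            class = "feature_config")
}

#' Column order of the per-frame feature matrix handed to classifiers
#' @return character vector of 14 column names.
#' @export
feature_columns <- function() {
  c("left_x", "left_y", "right_x", "right_y",
    "dist", "dist_valid",
    "left_speed", "right_speed", "left_accel", "right_accel",
    "left_traj", "right_traj", "left_present", "right_present")
}

# forward fill, back-filling the leading run; all-NA -> fallback
na_locf <- function(v, fallback) {
  n <- length(v)
  if (all(is.na(v))) return(rep(fallback, n))
  # forward fill
  last <- NA_real_
  for (i in seq_len(n)) {
    if (is.na(v[i])) v[i] <- last else last <- v[i]
  }
  # back fill the leading NAs
  if (is.na(v[1])) {
    first_val <- v[which(!is.na(v))[1]]
    v[is.na(v)] <- first_val
  }
  v
}

#' Extract per-frame hand-kinematic features from a pose sequence
#'
#' Computes the six feature families used for movement-based attachment
#' rating, all normalised to the image so they are resolution-independent:
#'
#' * hand position: wrist `(x/width, y/height)`;
#' * inter-hand distance: Euclidean distance between the two wrists in
#'   normalised coordinates, with a validity flag (`dist_valid = 0` when a
#'   hand is absent; the value then holds the last defined distance);
#' * hand speed: backward finite difference
#'   \eqn{\|p_t - p_{t-1}\| \cdot fps}, zero at the first frame;
#' * hand acceleration: absolute change of scalar speed times fps, zero at
#'   the first two frames;
#' * hand 1-D trajectory: horizontal placement `x/width`;
#' * hand presence: per-frame 0/1 detection flags (the windowed
#'   presence proportions summarise the child's tendency to move one doll
#'   more than the other).
#'
#' @param seq a [pose_sequence()].
#' @param cfg a [feature_config()]; `seq$frame_rate` takes precedence over
#'   `cfg$frame_rate`.
#' @param left_joint,right_joint joint names proxying the hands.
#' @return data.frame with `frame_index`, `time` and the
#'   [feature_columns()] columns, one row per input frame.
#' @export
extract_features <- function(seq, cfg = feature_config(),
                             left_joint = "left_wrist",
                             right_joint = "right_wrist") {
  stopifnot(inherits(seq, "pose_sequence"))
  n <- n_frames(seq)
  if (n < 2L) stop("sequence shorter than 2 frames", call. = FALSE)
  if (seq$image_width <= 0 || seq$image_height <= 0)
    stop("zero image dimensions", call. = FALSE)
  for (j in c(left_joint, right_joint))
    if (!(j %in% seq$joints)) stop("unknown joint: ", j, call. = FALSE)
  fps <- seq$frame_rate %||% cfg$frame_rate

  norm_xy <- function(joint) {
    cbind(seq$x[, joint] / seq$image_width,
          seq$y[, joint] / seq$image_height)
  }
  lp <- norm_xy(left_joint); rp <- norm_xy(right_joint)
  l_present <- as.numeric(!is.na(lp[, 1]))
  r_present <- as.numeric(!is.na(rp[, 1]))

  fill <- function(m) {
    if (cfg$missing_policy == "hold-last") {
      apply(m, 2, na_locf, fallback = 0.5)
    } else {
      m[is.na(m)] <- 0
      m
    }
  }
  lf <- fill(lp); rf <- fill(rp)

  kin <- function(p) {
    d <- sqrt(rowSums((p - rbind(p[1, , drop = FALSE],
                                 p[-nrow(p), , drop = FALSE]))^2))
    speed <- d * fps
    speed[1] <- 0
    accel <- c(0, abs(diff(speed))) * fps
    accel[seq_len(min(2L, length(accel)))] <- 0
    list(speed = speed, accel = accel)
  }
  lk <- kin(lf); rk <- kin(rf)

  both <- l_present == 1 & r_present == 1
  dist_raw <- sqrt(rowSums((lp - rp)^2))
  dist_raw[!both] <- NA_real_
  dist <- na_locf(dist_raw, fallback = 0)

  data.frame(
    frame_index = seq$frame_index, time = seq$time,
    left_x = lf[, 1], left_y = lf[, 2],
    right_x = rf[, 1], right_y = rf[, 2],
    dist = dist, dist_valid = as.numeric(both),
    left_speed = lk$speed, right_speed = rk$speed,
    left_accel = lk$accel, right_accel = rk$accel,
    left_traj = lf[, 1], right_traj = rf[, 1],
    left_present = l_present, right_present = r_present)
}

#' Segment per-frame features into fixed-length non-overlapping windows
#'
#' Returns `floor(T / window_size)` contiguous windows; trailing remainder
#' frames are discarded. Each window carries the child's label (windows
#' inherit the child-level coding; there is no window-level ground truth)
#' and the per-window presence proportion of each hand.
#'
#' @param features data.frame from [extract_features()].
#' @param cfg a [feature_config()].
#' @param child_id identifier attached to every window.
#' @param label optional four-way attachment code inherited by each window.
#' @return list of `"feature_window"` objects, each holding a
#'   `window_size` x 14 feature matrix ([feature_columns()] order),
#'   `window_index` (0-based), `left_presence_prop`, `right_presence_prop`
#'   and `label`.
#' @export
window_features <- function(features, cfg = feature_config(),
                            child_id, label = NULL) {
  if (nrow(features) == 0) stop("empty feature table", call. = FALSE)
  if (!is.null(label)) check_fourway(label)
  ws <- cfg$window_size
  k <- nrow(features) %/% ws
  if (k == 0L) return(list())
  mat <- as.matrix(features[, feature_columns()])
  lapply(seq_len(k) - 1L, function(w) {
    rows <- (w * ws + 1L):((w + 1L) * ws)
    m <- mat[rows, , drop = FALSE]
    structure(
      list(child_id = as.character(child_id), window_index = w,
           features = m,
           left_presence_prop = mean(m[, "left_present"]),
           right_presence_prop = mean(m[, "right_present"]),
           label = label),
      class = "feature_window")
  })
}

#' @export
print.feature_window <- function(x, ...) {
  cat(sprintf(
    "<feature_window> child '%s' #%d: %d frames x %d features%s\n",
    x$child_id, x$window_index, nrow(x$features), ncol(x$features),
    if (is.null(x$label)) "" else paste0(", label ", x$label)))
  invisible(x)
}

#' Full pose-to-windows pipeline for one child session
#'
#' @param seq a [pose_sequence()].
#' @param cfg a [feature_config()].
#' @param label optional four-way code.
#' @return list of feature windows (see [window_features()]).
#' @export
windows_from_sequence <- function(seq, cfg = feature_config(), label = NULL) {
  window_features(extract_features(seq, cfg), cfg,
                  child_id = seq$child_id, label = label)
}
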