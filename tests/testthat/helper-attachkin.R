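# Fixture builders used across the suite. Everything is generated in
# code; no stored data.

# minimal pose sequence with both wrists on prescribed pixel tracks
make_track_sequence <- function(left_xy, right_xy, frame_rate = 30,
                                width = 320, height = 240,
                                child_id = "t1",
                                left_conf = NULL, right_conf = NULL) {
  n <- nrow(left_xy)
  joints <- coco_joints()
  x <- matrix(100, n, length(joints), dimnames = list(NULL, joints))
  y <- matrix(100, n, length(joints), dimnames = list(NULL, joints))
  conf <- matrix(0.9, n, length(joints), dimnames = list(NULL, joints))
  x[, "left_wrist"] <- left_xy[, 1]; y[, "left_wrist"] <- left_xy[, 2]
  x[, "right_wrist"] <- right_xy[, 1]; y[, "right_wrist"] <- right_xy[, 2]
  if (!is.null(left_conf)) conf[, "left_wrist"] <- left_conf
  if (!is.null(right_conf)) conf[, "right_wrist"] <- right_conf
  pose_sequence(child_id, frame_rate, width, height, x, y, conf, joints)
}

# hand-built feature window with controlled channel statistics
make_window <- function(child_id, window_index, label,
                        speed_level, dist_level, seed,
                        window_size = 128L) {
  set.seed(seed)
  m <- matrix(0, window_size, length(feature_columns()),
              dimnames = list(NULL, feature_columns()))
  m[, "left_x"] <- runif(window_size, 0.3, 0.7)
  m[, "left_y"] <- runif(window_size, 0.4, 0.8)
  m[, "right_x"] <- runif(window_size, 0.3, 0.7)
  m[, "right_y"] <- runif(window_size, 0.4, 0.8)
  m[, "dist"] <- abs(rnorm(window_size, dist_level, 0.03))
  m[, "dist_valid"] <- 1
  m[, "left_speed"] <- abs(rnorm(window_size, speed_level, 0.02))
  m[, "right_speed"] <- abs(rnorm(window_size, speed_level, 0.02))
  m[, "left_accel"] <- abs(rnorm(window_size, speed_level * 2, 0.05))
  m[, "right_accel"] <- abs(rnorm(window_size, speed_level * 2, 0.05))
  m[, "left_traj"] <- m[, "left_x"]
  m[, "right_traj"] <- m[, "right_x"]
  m[, "left_present"] <- 1
  m[, "right_present"] <- 1
  structure(list(child_id = as.character(child_id),
                 window_index = as.integer(window_index),
                 features = m,
                 left_presence_prop = 1, right_presence_prop = 1,
                 label = label),
            class = "feature_window")
}

# two linearly separable classes: secure = slow hands close together,
# insecure = fast hands far apart
make_separable_windows <- function(n_per_class = 40, seed = 1,
                                   children_per_class = 4) {
  idx <- 0
  out <- list()
  for (cls in c("B", "C")) {
    for (i in seq_len(n_per_class)) {
      child <- sprintf("%s%02d", cls, (i - 1) %% children_per_class + 1)
      out[[length(out) + 1]] <- make_window(
        child_id = child, window_index = (i - 1) %/% children_per_class,
        label = cls,
        speed_level = if (cls == "B") 0.05 else 0.5,
        dist_level = if (cls == "B") 0.2 else 0.6,
        seed = seed * 10000 + idx)
      idx <- idx + 1
    }
  }
  out
}

window_truth <- function(windows) {
  binary_label(vapply(windows, function(w) w$label, character(1)))
}

# brute-force kappa from label pairs (independent of cohen_kappa)
brute_kappa <- function(first, second, levels) {
  n <- length(first)
  po <- mean(first == second)
  pe <- 0
  for (lv in levels)
    pe <- pe + mean(first == lv) * mean(second == lv)
  (po - pe) / (1 - pe)
}

# brute-force binary metrics from prediction lists
brute_metrics <- function(truth, pred) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == "insecure" && pred[i] == "insecure") tp <- tp + 1
    if (truth[i] == "secure" && pred[i] == "insecure") fp <- fp + 1
    if (truth[i] == "insecure" && pred[i] == "secure") fn <- fn + 1
    if (truth[i] == "secure" && pred[i] == "secure") tn <- tn + 1
  }
  pi <- tp / (tp + fp); rho <- tp / (tp + fn)
  list(alpha = (tp + tn) / length(truth), pi = pi, rho = rho,
       f1 = 2 * pi * rho / (pi + rho))
}

# fabricated window predictions for majority-vote tests
make_predictions <- function(child_id, hard_labels) {
  data.frame(child_id = rep(child_id, length(hard_labels)),
             window_index = seq_along(hard_labels) - 1L,
             p_insecure = ifelse(hard_labels == "insecure", 0.9, 0.1),
             hard_label = hard_labels, stringsAsFactors = FALSE)
}
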