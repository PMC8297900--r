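#' Class-conditional parameters of the doll-play motion simulator
#'
#' The simulator emulates the two wrist tracks of a child completing
#' story stems with a child-doll and a mummy-doll, one doll per hand.
#' Each hand follows critically damped second-order (spring-damper)
#' motion toward a piecewise-constant target. Targets are resampled at
#' Poisson "play events"; half of the events are *approach events* during
#' which both targets contract exponentially toward a shared point —
#' the smooth proximity-seeking movement that characterises secure play.
#'
#' All lengths are in image-normalised units (1 = image width/height).
#'
#' @param approach_rate 1/s; exponential contraction rate of the two
#'   targets toward the shared point during approach events. High values
#'   give rapid, decisive closing of the inter-doll distance.
#' @param event_rate play events per minute (target switches).
#' @param noise_sd positional observation jitter, normalised units.
#' @param jerk_sd acceleration noise, normalised units/s^2; high values
#'   give erratic, jerky movement.
#' @param dropout_left,dropout_right per-frame probability that the hand
#'   is not detected (doll out of frame / occluded).
#' @param rest_distance typical inter-hand target separation outside
#'   approach events, normalised units in (0, 1.5].
#' @return list of class `"motion_class_params"`.
#' @export
motion_class_params <- function(approach_rate, event_rate, noise_sd,
                                jerk_sd, dropout_left, dropout_right,
                                rest_distance) {
  stopifnot(approach_rate >= 0, event_rate >= 0, noise_sd >= 0,
            jerk_sd >= 0,
            dropout_left >= 0, dropout_left <= 1,
            dropout_right >= 0, dropout_right <= 1,
            rest_distance > 0, rest_distance <= 1.5)
  structure(list(approach_rate = approach_rate, event_rate = event_rate,
                 noise_sd = noise_sd, jerk_sd = jerk_sd,
                 dropout_left = dropout_left, dropout_right = dropout_right,
                 rest_distance = rest_distance),
            class = "motion_class_params")
}

#' @rdname motion_class_params
#' @details `secure_motion_params()` encodes smooth, fairly rapid
#'   proximity-seeking: strong approach pull, low jerk, symmetric low
#'   dropout, small resting separation. `insecure_motion_params()` is the
#'   union preset of the insecure family: weak approach, erratic
#'   high-jerk switching, asymmetric dropout (one doll favoured), wide
#'   resting separation. `sublabel_motion_params()` derives
#'   avoidant-like (A: wide separation, one-hand dropout),
#'   ambivalent-like (C: frequent switching) and disorganised-like
#'   (D: highest jerk and switching) variants from the insecure preset.
#' @export
secure_motion_params <- function() {
  motion_class_params(approach_rate = 3, event_rate = 10,
                      noise_sd = 0.004, jerk_sd = 0.08,
                      dropout_left = 0.02, dropout_right = 0.02,
                      rest_distance = 0.3)
}

#' @rdname motion_class_params
#' @export
insecure_motion_params <- function() {
  motion_class_params(approach_rate = 0.4, event_rate = 25,
                      noise_sd = 0.008, jerk_sd = 0.5,
                      dropout_left = 0.05, dropout_right = 0.18,
                      rest_distance = 0.6)
}

#' @rdname motion_class_params
#' @param base insecure-family base parameters.
#' @param sublabel one of "A", "C", "D".
#' @export
sublabel_motion_params <- function(base = insecure_motion_params(),
                                   sublabel = c("A", "C", "D")) {
  sublabel <- match.arg(sublabel)
  p <- unclass(base)
  p <- switch(sublabel,
    A = modifyList(p, list(rest_distance = 0.75, dropout_right = 0.35,
                           event_rate = 12, jerk_sd = 0.25)),
    C = modifyList(p, list(event_rate = 30, jerk_sd = 0.55)),
    D = modifyList(p, list(event_rate = 35, jerk_sd = 0.7,
                           noise_sd = 0.012)))
  do.call(motion_class_params, p)
}

#' Interpolate between two motion-parameter sets
#'
#' Linear interpolation of every field; `s = 0` returns `from`, `s = 1`
#' returns `to`. Used to generate cohorts at graded class separation.
#'
#' @param from,to `motion_class_params`.
#' @param s interpolation weight in \[0, 1\].
#' @export
interpolate_params <- function(from, to, s) {
  stopifnot(s >= 0, s <= 1)
  vals <- Map(function(a, b) (1 - s) * a + s * b,
              unclass(from), unclass(to))
  do.call(motion_class_params, vals)
}

# static plausible upper-body layout for the 16 non-wrist joints,
# normalised coordinates; keeps emitted files schema-complete
static_body_layout <- function() {
  rbind(
    nose = c(0.50, 0.18), neck = c(0.50, 0.30),
    right_shoulder = c(0.40, 0.31), right_elbow = c(0.34, 0.45),
    left_shoulder = c(0.60, 0.31), left_elbow = c(0.66, 0.45),
    right_hip = c(0.43, 0.70), right_knee = c(0.43, 0.88),
    right_ankle = c(0.43, 0.99),
    left_hip = c(0.57, 0.70), left_knee = c(0.57, 0.88),
    left_ankle = c(0.57, 0.99),
    right_eye = c(0.46, 0.15), left_eye = c(0.54, 0.15),
    right_ear = c(0.42, 0.17), left_ear = c(0.58, 0.17))
}

#' Simulate one child's doll-play pose sequence
#'
#' Two wrist tracks evolve as critically damped spring-damper motion
#' (natural frequency 6 rad/s) toward piecewise-constant targets sampled
#' at `event_rate`; during approach events both targets contract toward a
#' shared point at `approach_rate`. Gaussian positional noise
#' (`noise_sd`) and acceleration noise (`jerk_sd`) are added, positions
#' reflect off the image bounds, and each hand drops out independently
#' per frame. Output is a pure function of the arguments and the seed.
#'
#' @param params a [motion_class_params()].
#' @param frames number of frames (>= 2).
#' @param frame_rate frames per second.
#' @param image_width,image_height pixels.
#' @param child_id identifier for the emitted sequence.
#' @param seed integer RNG seed.
#' @return a valid [pose_sequence()].
#' @export
simulate_child <- function(params, frames, frame_rate = 30,
                           image_width = 640, image_height = 480,
                           child_id = "sim", seed = 1) {
  stopifnot(inherits(params, "motion_class_params"))
  frames <- as.integer(frames)
  if (frames < 2L) stop("need at least 2 frames", call. = FALSE)
  with_seed(seed, {
    dt <- 1 / frame_rate
    omega <- 6                       # rad/s, smoothness of the tracks
    duration <- frames * dt
    base <- rbind(left = c(0.5 - params$rest_distance / 2, 0.6),
                  right = c(0.5 + params$rest_distance / 2, 0.6))
    base[, 1] <- pmin(pmax(base[, 1], 0.08), 0.92)

    # Poisson play-event times over the session
    rate_s <- params$event_rate / 60
    ev_times <- if (rate_s > 0) {
      tt <- cumsum(rexp(max(10, ceiling(duration * rate_s * 3) + 10),
                        rate = rate_s))
      tt[tt < duration]
    } else numeric(0)

    pos <- base                      # state: position, velocity per hand
    vel <- matrix(0, 2, 2)
    target <- base
    approach_until <- -1; shared <- c(0.5, 0.5); approach_t0 <- 0
    target_at_event <- target
    next_ev <- 1L

    X <- matrix(NA_real_, frames, 2)  # observed wrist x (left,right cols)
    Y <- matrix(NA_real_, frames, 2)
    for (i in seq_len(frames)) {
      t <- (i - 1L) * dt
      while (next_ev <= length(ev_times) && ev_times[next_ev] <= t) {
        if (runif(1) < 0.5) {        # approach event
          shared <- (target[1, ] + target[2, ]) / 2 +
            rnorm(2, 0, 0.03)
          approach_t0 <- ev_times[next_ev]
          approach_until <- ev_times[next_ev] + 2.0
          target_at_event <- target
        } else {                     # reposition event
          target <- base + matrix(rnorm(4, 0, 0.08), 2, 2)
          approach_until <- -1
        }
        next_ev <- next_ev + 1L
      }
      eff_target <- target
      if (t <= approach_until) {
        shrink <- exp(-params$approach_rate * (t - approach_t0))
        eff_target <- rbind(shared + (target_at_event[1, ] - shared) * shrink,
                            shared + (target_at_event[2, ] - shared) * shrink)
      }
      acc <- omega^2 * (eff_target - pos) - 2 * omega * vel +
        matrix(rnorm(4, 0, params$jerk_sd), 2, 2)
      vel <- vel + acc * dt
      pos <- pos + vel * dt
      # reflective image bounds
      for (h in 1:2) for (k in 1:2) {
        if (pos[h, k] < 0) { pos[h, k] <- -pos[h, k]; vel[h, k] <- -vel[h, k] }
        if (pos[h, k] > 1) { pos[h, k] <- 2 - pos[h, k]; vel[h, k] <- -vel[h, k] }
      }
      obs <- pos + matrix(rnorm(4, 0, params$noise_sd), 2, 2)
      obs <- pmin(pmax(obs, 0), 1)
      X[i, ] <- obs[, 1]; Y[i, ] <- obs[, 2]
    }

    drop_l <- runif(frames) < params$dropout_left
    drop_r <- runif(frames) < params$dropout_right

    joints <- coco_joints()
    nj <- length(joints)
    body <- static_body_layout()
    x <- matrix(rep(body[, 1], each = frames), frames, nrow(body))
    y <- matrix(rep(body[, 2], each = frames), frames, nrow(body))
    colnames(x) <- colnames(y) <- rownames(body)
    conf_body <- matrix(0.9, frames, nrow(body),
                        dimnames = list(NULL, rownames(body)))

    xm <- matrix(NA_real_, frames, nj, dimnames = list(NULL, joints))
    ym <- xm; cm <- matrix(0, frames, nj, dimnames = list(NULL, joints))
    xm[, rownames(body)] <- x * image_width
    ym[, rownames(body)] <- y * image_height
    cm[, rownames(body)] <- conf_body
    xm[, "left_wrist"] <- X[, 1] * image_width
    ym[, "left_wrist"] <- Y[, 1] * image_height
    cm[, "left_wrist"] <- ifelse(drop_l, 0, 0.95)
    xm[, "right_wrist"] <- X[, 2] * image_width
    ym[, "right_wrist"] <- Y[, 2] * image_height
    cm[, "right_wrist"] <- ifelse(drop_r, 0, 0.95)
    xm[cm == 0] <- NA_real_; ym[cm == 0] <- NA_real_

    pose_sequence(child_id = child_id, frame_rate = frame_rate,
                  image_width = image_width, image_height = image_height,
                  x = xm, y = ym, conf = cm, joints = joints)
  })
}

#' Specification of a synthetic doll-play cohort
#'
#' @param n_children total number of children (>= 2).
#' @param secure_fraction proportion labelled B;
#'   `round(n_children * secure_fraction)` children are secure.
#' @param frames_per_child frames per session; must cover at least one
#'   window. Default 896 frames (7 windows of 128 at 30 fps, ~30 s).
#' @param frame_rate,image_width,image_height geometry of the emitted
#'   sequences.
#' @param secure_params,insecure_params class-conditional
#'   [motion_class_params()]. Insecure children receive A/C/D sublabels in
#'   equal thirds (remainder to C); each sublabel perturbs
#'   `insecure_params` via [sublabel_motion_params()] when
#'   `sublabel_variants = TRUE`.
#' @param sublabel_variants use the per-sublabel insecure variants
#'   (default) or the same `insecure_params` for all insecure children.
#' @param seed integer RNG seed; child `i` is simulated with
#'   `seed + i`.
#' @return list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_children = 40, secure_fraction = 0.5,
                        frames_per_child = 896, frame_rate = 30,
                        image_width = 640, image_height = 480,
                        secure_params = secure_motion_params(),
                        insecure_params = insecure_motion_params(),
                        sublabel_variants = TRUE,
                        seed = 1) {
  stopifnot(n_children >= 2, secure_fraction > 0, secure_fraction < 1)
  structure(list(n_children = as.integer(n_children),
                 secure_fraction = secure_fraction,
                 frames_per_child = as.integer(frames_per_child),
                 frame_rate = frame_rate,
                 image_width = image_width, image_height = image_height,
                 secure_params = secure_params,
                 insecure_params = insecure_params,
                 sublabel_variants = sublabel_variants,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a labelled cohort of doll-play sessions
#'
#' @param spec a [cohort_spec()].
#' @param window_size used only to validate that sessions cover at least
#'   one window.
#' @return list with `sequences` (list of [pose_sequence()]) and
#'   `labels` (a [label_table()]; secure children B, insecure children
#'   A/C/D in equal thirds with the remainder to C).
#' @export
simulate_cohort <- function(spec, window_size = 128L) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$frames_per_child < window_size)
    stop("frames_per_child smaller than one window", call. = FALSE)
  n_secure <- round(spec$n_children * spec$secure_fraction)
  n_insecure <- spec$n_children - n_secure
  sub <- character(0)
  if (n_insecure > 0) {
    third <- n_insecure %/% 3
    sub <- c(rep("A", third), rep("D", third),
             rep("C", n_insecure - 2 * third))
  }
  labels <- c(rep("B", n_secure), sub)
  ids <- sprintf("child%03d", seq_len(spec$n_children))
  sequences <- lapply(seq_len(spec$n_children), function(i) {
    lb <- labels[i]
    p <- if (lb == "B") spec$secure_params
         else if (spec$sublabel_variants)
           sublabel_motion_params(spec$insecure_params, lb)
         else spec$insecure_params
    simulate_child(p, frames = spec$frames_per_child,
                   frame_rate = spec$frame_rate,
                   image_width = spec$image_width,
                   image_height = spec$image_height,
                   child_id = ids[i], seed = spec$seed + i)
  })
  list(sequences = sequences, labels = label_table(ids, labels))
}

#' Windows for a whole cohort
#'
#' @param cohort output of [simulate_cohort()].
#' @param cfg a [feature_config()].
#' @return flat list of labelled feature windows across all children.
#' @export
cohort_windows <- function(cohort, cfg = feature_config()) {
  out <- lapply(cohort$sequences, function(s)
    windows_from_sequence(s, cfg, label = label_for(cohort$labels,
                                                    s$child_id)))
  do.call(c, out)
}
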