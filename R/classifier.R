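#' Specification of a window classifier
#'
#' Two backends classify 128-frame feature windows as secure vs insecure:
#'
#' * `"recurrent"` — a single-layer LSTM over the per-frame feature
#'   sequence (hidden states mean-pooled, logistic head, class-weighted
#'   cross-entropy, full-batch Adam). The reference sequence model.
#' * `"logistic"` — logistic regression on per-window summary statistics
#'   (means/SDs of the kinematic channels plus the presence proportions).
#'   Fast and fully deterministic.
#'
#' @param backend `"recurrent"` (alias `"recurrent-sequence"`) or
#'   `"logistic"` (alias `"summary-logistic"`).
#' @param hidden_size LSTM hidden units.
#' @param epochs training epochs (recurrent backend).
#' @param learning_rate Adam step size (recurrent backend).
#' @param class_weighting `"balanced"` (inverse class frequency; the
#'   default, since doll-play cohorts run roughly 70/30 secure/insecure)
#'   or `"none"`.
#' @param seed integer; training is deterministic given the seed.
#' @param max_windows_per_child cap on the number of windows contributing
#'   to a child's majority vote, in temporal order; default 500.
#'   `Inf` disables the cap.
#' @param summary_features optional character subset of the summary
#'   statistics used by the logistic backend (e.g. only the
#'   inter-hand-distance family); `NULL` uses all.
#' @return list of class `"model_spec"`.
#' @export
model_spec <- function(backend = c("logistic", "recurrent",
                                   "summary-logistic", "recurrent-sequence"),
                       hidden_size = 8L, epochs = 60L,
                       learning_rate = 0.05,
                       class_weighting = c("balanced", "none"),
                       seed = 1L, max_windows_per_child = 500,
                       summary_features = NULL) {
  backend <- match.arg(backend)
  backend <- switch(backend, "summary-logistic" = "logistic",
                    "recurrent-sequence" = "recurrent", backend)
  class_weighting <- match.arg(class_weighting)
  stopifnot(hidden_size >= 1, epochs >= 1, learning_rate > 0,
            max_windows_per_child >= 1)
  structure(list(backend = backend, hidden_size = as.integer(hidden_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 class_weighting = class_weighting,
                 seed = as.integer(seed),
                 max_windows_per_child = max_windows_per_child,
                 summary_features = summary_features),
            class = "model_spec")
}

summary_feature_names <- function() {
  c("dist_mean", "dist_sd", "dist_valid_mean",
    "left_speed_mean", "left_speed_sd", "right_speed_mean",
    "right_speed_sd",
    "left_accel_mean", "left_accel_sd", "right_accel_mean",
    "right_accel_sd",
    "left_traj_mean", "left_traj_sd", "right_traj_mean", "right_traj_sd",
    "left_y_mean", "right_y_mean",
    "left_presence_prop", "right_presence_prop")
}

summarize_window <- function(w) {
  m <- w$features
  c(dist_mean = mean(m[, "dist"]), dist_sd = sd(m[, "dist"]),
    dist_valid_mean = mean(m[, "dist_valid"]),
    left_speed_mean = mean(m[, "left_speed"]),
    left_speed_sd = sd(m[, "left_speed"]),
    right_speed_mean = mean(m[, "right_speed"]),
    right_speed_sd = sd(m[, "right_speed"]),
    left_accel_mean = mean(m[, "left_accel"]),
    left_accel_sd = sd(m[, "left_accel"]),
    right_accel_mean = mean(m[, "right_accel"]),
    right_accel_sd = sd(m[, "right_accel"]),
    left_traj_mean = mean(m[, "left_traj"]),
    left_traj_sd = sd(m[, "left_traj"]),
    right_traj_mean = mean(m[, "right_traj"]),
    right_traj_sd = sd(m[, "right_traj"]),
    left_y_mean = mean(m[, "left_y"]),
    right_y_mean = mean(m[, "right_y"]),
    left_presence_prop = w$left_presence_prop,
    right_presence_prop = w$right_presence_prop)
}

check_windows <- function(windows, need_labels = FALSE) {
  if (length(windows) == 0) stop("no windows supplied", call. = FALSE)
  dims <- vapply(windows, function(w) dim(w$features), integer(2))
  if (length(unique(dims[1, ])) > 1 || length(unique(dims[2, ])) > 1)
    stop("inconsistent window shapes", call. = FALSE)
  if (need_labels) {
    labs <- vapply(windows, function(w) w$label %||% NA_character_,
                   character(1))
    if (anyNA(labs)) stop("all training windows need labels", call. = FALSE)
  }
  invisible(windows)
}

window_targets <- function(windows) {
  labs <- vapply(windows, function(w) w$label, character(1))
  as.numeric(binary_label(labs) == "insecure")  # 1 = insecure
}

class_weights <- function(y, scheme) {
  if (scheme == "none") return(rep(1, length(y)))
  # inverse-frequency weights, mean 1
  tab <- table(y)
  w <- length(y) / (length(tab) * as.numeric(tab[as.character(y)]))
  w
}

windows_to_cube <- function(windows, center = NULL, scale = NULL) {
  T <- nrow(windows[[1]]$features)
  d <- ncol(windows[[1]]$features)
  n <- length(windows)
  X <- array(0, dim = c(n, d, T))
  for (i in seq_len(n)) X[i, , ] <- t(windows[[i]]$features)
  if (!is.null(center)) {
    for (j in seq_len(d))
      X[, j, ] <- (X[, j, ] - center[j]) / scale[j]
  }
  X
}

#' Train a secure/insecure window classifier
#'
#' Windows inherit their child's binary label (B = secure; A, C, D =
#' insecure). Training is reproducible under `spec$seed`.
#'
#' @param windows list of labelled feature windows
#'   (see [window_features()]); both classes must be present.
#' @param spec a [model_spec()].
#' @return opaque model object of class `"attachkin_model"` carrying the
#'   spec and the feature schema; prediction refuses schema mismatches.
#' @export
train_classifier <- function(windows, spec = model_spec()) {
  check_windows(windows, need_labels = TRUE)
  y <- window_targets(windows)
  if (length(unique(y)) < 2)
    stop("degenerate training set: only one class present", call. = FALSE)
  w <- class_weights(y, spec$class_weighting)
  schema <- list(columns = colnames(windows[[1]]$features),
                 window_size = nrow(windows[[1]]$features))

  fit <- if (spec$backend == "logistic") {
    sf <- spec$summary_features %||% summary_feature_names()
    stopifnot(all(sf %in% summary_feature_names()))
    Xs <- t(vapply(windows, summarize_window,
                   numeric(length(summary_feature_names()))))
    df <- as.data.frame(Xs[, sf, drop = FALSE])
    df$.y <- y
    g <- suppressWarnings(
      glm(.y ~ ., family = binomial(), data = df, weights = w,
          control = list(maxit = 100)))
    list(glm = g, features = sf)
  } else {
    d <- length(schema$columns)
    h <- spec$hidden_size
    X <- windows_to_cube(windows)
    center <- apply(X, 2, mean)
    scale <- pmax(apply(X, 2, sd), 1e-8)
    X <- windows_to_cube(windows, center, scale)
    init <- with_seed(spec$seed, {
      s <- function(n, fan) (runif(n) - 0.5) * 2 / sqrt(fan)
      b <- rep(0, 4 * h)
      b[(h + 1):(2 * h)] <- 1   # forget-gate bias
      list(Wx = matrix(s(d * 4 * h, d), d, 4 * h),
           Wh = matrix(s(h * 4 * h, h), h, 4 * h),
           b = b, v = s(h, h), c = 0)
    })
    out <- lstm_fit_cpp(X, y, w, init, spec$epochs, spec$learning_rate)
    list(params = out[c("Wx", "Wh", "b", "v", "c")],
         loss_history = out$loss_history,
         center = center, scale = scale)
  }

  structure(list(spec = spec, backend = spec$backend, fit = fit,
                 schema = schema),
            class = "attachkin_model")
}

#' @export
print.attachkin_model <- function(x, ...) {
  cat(sprintf("<attachkin_model> backend '%s', %d-frame windows, %d features\n",
              x$backend, x$schema$window_size, length(x$schema$columns)))
  invisible(x)
}

#' Classify feature windows with a trained model
#'
#' @param model an `"attachkin_model"`.
#' @param windows list of feature windows with the same schema the model
#'   was trained on.
#' @return data.frame with one row per window: `child_id`,
#'   `window_index`, `p_insecure` in \[0, 1\] and `hard_label`
#'   (`"insecure"` iff `p_insecure >= 0.5`).
#' @export
predict_windows <- function(model, windows) {
  stopifnot(inherits(model, "attachkin_model"))
  if (length(windows) == 0)
    return(data.frame(child_id = character(0), window_index = integer(0),
                      p_insecure = numeric(0), hard_label = character(0),
                      stringsAsFactors = FALSE))
  check_windows(windows)
  sch <- list(columns = colnames(windows[[1]]$features),
              window_size = nrow(windows[[1]]$features))
  if (!identical(sch, model$schema))
    stop("feature schema mismatch between model and windows",
         call. = FALSE)
  p <- if (model$backend == "logistic") {
    Xs <- t(vapply(windows, summarize_window,
                   numeric(length(summary_feature_names()))))
    df <- as.data.frame(Xs[, model$fit$features, drop = FALSE])
    # rank-deficient fits (tiny training sets) predict fine; keep quiet
    as.numeric(suppressWarnings(
      predict(model$fit$glm, newdata = df, type = "response")))
  } else {
    X <- windows_to_cube(windows, model$fit$center, model$fit$scale)
    as.numeric(lstm_predict_cpp(X, model$fit$params))
  }
  data.frame(
    child_id = vapply(windows, function(w) w$child_id, character(1)),
    window_index = vapply(windows, function(w) w$window_index, integer(1)),
    p_insecure = p,
    hard_label = ifelse(p >= 0.5, "insecure", "secure"),
    stringsAsFactors = FALSE)
}

#' Aggregate one child's window predictions by majority vote
#'
#' The child is assigned the class most frequently predicted across their
#' windows, using at most `cap` windows in temporal order. Exact ties
#' resolve to insecure: as a screening decision, sensitivity is preferred.
#'
#' @param predictions data.frame from [predict_windows()], all rows for
#'   one child.
#' @param cap maximum number of windows contributing to the decision
#'   (default 500); `Inf` disables the cap.
#' @return list of class `"child_rating"`: `child_id`, `label`,
#'   `vote_fraction` (fraction of used windows voting for the assigned
#'   label, always in \[0.5, 1\]) and `n_windows` (windows used).
#' @export
majority_vote <- function(predictions, cap = 500) {
  if (nrow(predictions) == 0) stop("no predictions to vote on", call. = FALSE)
  ids <- unique(predictions$child_id)
  if (length(ids) != 1)
    stop("predictions mix several children: ",
         paste(ids, collapse = ", "), call. = FALSE)
  ord <- order(predictions$window_index)
  use <- head(ord, min(nrow(predictions), cap))
  votes <- predictions$hard_label[use]
  n_ins <- sum(votes == "insecure")
  n <- length(votes)
  label <- if (n_ins >= n / 2) "insecure" else "secure"  # tie -> insecure
  frac <- max(n_ins, n - n_ins) / n
  if (n_ins == n - n_ins) frac <- 0.5
  structure(list(child_id = ids, label = label,
                 vote_fraction = frac, n_windows = n),
            class = "child_rating")
}

#' @export
print.child_rating <- function(x, ...) {
  cat(sprintf("<child_rating> '%s': %s (%.0f%% of %d windows)\n",
              x$child_id, x$label, 100 * x$vote_fraction, x$n_windows))
  invisible(x)
}

#' Rate every child in a set of window predictions
#'
#' @param predictions data.frame from [predict_windows()] covering one or
#'   more children.
#' @param cap per-child window cap (see [majority_vote()]).
#' @return data.frame with one row per child: `child_id`, `label`,
#'   `vote_fraction`, `n_windows`.
#' @export
rate_children <- function(predictions, cap = 500) {
  ids <- unique(predictions$child_id)
  rows <- lapply(ids, function(id) {
    r <- majority_vote(predictions[predictions$child_id == id, ,
                                   drop = FALSE], cap = cap)
    data.frame(child_id = r$child_id, label = r$label,
               vote_fraction = r$vote_fraction, n_windows = r$n_windows,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Save / load a trained model
#'
#' Serialises the model together with its spec and feature schema; a
#' model loaded from file still refuses schema-mismatched windows.
#'
#' @param model an `"attachkin_model"`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "attachkin_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "attachkin_model"))
    stop("file does not contain an attachkin model", call. = FALSE)
  m
}
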