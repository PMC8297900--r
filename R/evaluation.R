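#' Binary confusion matrix with insecure as the positive class
#'
#' @param tp,fp,fn,tn non-negative counts. The positive class throughout
#'   is *insecure*: with a majority-secure population and recall higher
#'   than precision, this is the orientation under which screening
#'   performance is reported.
#' @return list of class `"confusion2"`.
#' @export
confusion2 <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (sum(counts) == 0) stop("empty confusion matrix", call. = FALSE)
  structure(as.list(counts), class = "confusion2")
}

#' @rdname confusion2
#' @param truth,predicted character vectors of `"secure"`/`"insecure"`.
#' @export
confusion_from_predictions <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  confusion2(tp = sum(truth == "insecure" & predicted == "insecure"),
             fp = sum(truth == "secure" & predicted == "insecure"),
             fn = sum(truth == "insecure" & predicted == "secure"),
             tn = sum(truth == "secure" & predicted == "secure"))
}

#' Accuracy, precision, recall and F1 from a binary confusion matrix
#'
#' \eqn{\alpha = (tp+tn)/N}, \eqn{\pi = tp/(tp+fp)},
#' \eqn{\rho = tp/(tp+fn)}, \eqn{F_1 = 2\pi\rho/(\pi+\rho)}.
#' Ratios with a zero denominator are reported as `NaN` with a warning,
#' never silently coerced to 0.
#'
#' @param cm a [confusion2()], or anything coercible via its fields.
#' @return list of class `"classification_metrics"` with `alpha`, `pi`,
#'   `rho`, `f1` and `n`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion2"))
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  alpha <- (cm$tp + cm$tn) / n
  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator", call. = FALSE)
      return(NaN)
    }
    num / den
  }
  pi <- safe_ratio(cm$tp, cm$tp + cm$fp, "precision")
  rho <- safe_ratio(cm$tp, cm$tp + cm$fn, "recall")
  f1 <- if (is.nan(pi) || is.nan(rho)) NaN
        else if (pi + rho == 0) {
          warning("F1 undefined: precision + recall is zero", call. = FALSE)
          NaN
        } else f1_score(pi, rho)
  structure(list(alpha = alpha, pi = pi, rho = rho, f1 = f1, n = n),
            class = "classification_metrics")
}

#' Harmonic mean of precision and recall
#' @param pi,rho precision and recall in \[0, 1\].
#' @export
f1_score <- function(pi, rho) 2 * pi * rho / (pi + rho)

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(
    "alpha %.1f%%  pi %.1f%%  rho %.1f%%  F1 %.1f%%  (n = %d)\n",
    100 * x$alpha, 100 * x$pi, 100 * x$rho, 100 * x$f1, x$n))
  invisible(x)
}

#' Leave-One-Child-Out evaluation of the window classifier
#'
#' One fold per child: the model is trained on every other child's
#' windows and tested on the held-out child, so a child's windows never
#' appear in their own training set. Per-child ratings come from
#' [majority_vote()]; metrics are computed at the child level and, for
#' diagnostics, at the window level. Per-fold retraining uses
#' `spec$seed + fold_index` so the whole protocol is reproducible.
#'
#' @param windows flat list of labelled feature windows covering >= 2
#'   children with both classes present at child level.
#' @param spec a [model_spec()].
#' @param progress emit a message per fold.
#' @return list of class `"loco_result"`: `per_child` data.frame
#'   (`child_id`, `truth`, `predicted`, `vote_fraction`, `n_windows`),
#'   `child_metrics`, `window_metrics`, `n_folds`, and `folds` (the
#'   train/test child ids of every fold, for leakage audits).
window_truth_internal <- function(windows) {
  binary_label(vapply(windows, function(w) w$label, character(1)))
}

#' @export
loco_evaluate <- function(windows, spec = model_spec(), progress = FALSE) {
  check_windows(windows, need_labels = TRUE)
  ids <- vapply(windows, function(w) w$child_id, character(1))
  children <- unique(ids)
  if (length(children) < 2)
    stop("Leave-One-Child-Out needs at least 2 children", call. = FALSE)
  child_truth <- vapply(children, function(id)
    binary_label(windows[[match(id, ids)]]$label), character(1))
  if (length(unique(child_truth)) < 2)
    stop("degenerate dataset: all children share one class", call. = FALSE)

  per_child <- vector("list", length(children))
  folds <- vector("list", length(children))
  win_truth <- character(0); win_pred <- character(0)
  for (k in seq_along(children)) {
    test_id <- children[k]
    train <- windows[ids != test_id]
    test <- windows[ids == test_id]
    fold_spec <- spec
    fold_spec$seed <- spec$seed + k
    stopifnot(length(intersect(
      unique(vapply(train, function(w) w$child_id, character(1))),
      test_id)) == 0)
    train_classes <- unique(window_truth_internal(train))
    preds <- if (length(train_classes) < 2) {
      # minimal protocol (e.g. two children): a single-class training
      # fold can only yield the training-class prior
      warning("fold ", k, ": training set holds one class; ",
              "predicting the training-class prior", call. = FALSE)
      data.frame(
        child_id = vapply(test, function(w) w$child_id, character(1)),
        window_index = vapply(test, function(w) w$window_index,
                              integer(1)),
        p_insecure = as.numeric(train_classes == "insecure"),
        hard_label = train_classes, stringsAsFactors = FALSE)
    } else {
      model <- train_classifier(train, fold_spec)
      predict_windows(model, test)
    }
    rating <- majority_vote(preds, cap = spec$max_windows_per_child)
    per_child[[k]] <- data.frame(
      child_id = test_id, truth = child_truth[k],
      predicted = rating$label, vote_fraction = rating$vote_fraction,
      n_windows = rating$n_windows, stringsAsFactors = FALSE)
    folds[[k]] <- list(test = test_id,
                       train = setdiff(children, test_id))
    win_truth <- c(win_truth, rep(child_truth[k], nrow(preds)))
    win_pred <- c(win_pred, preds$hard_label)
    if (progress)
      message(sprintf("fold %d/%d: held out %s -> %s",
                      k, length(children), test_id, rating$label))
  }
  per_child <- do.call(rbind, per_child)
  structure(list(
    per_child = per_child,
    child_metrics = compute_metrics(
      confusion_from_predictions(per_child$truth, per_child$predicted)),
    window_metrics = compute_metrics(
      confusion_from_predictions(win_truth, win_pred)),
    n_folds = length(children),
    folds = folds), class = "loco_result")
}

#' @export
print.loco_result <- function(x, ...) {
  cat(sprintf("<loco_result> %d folds\n  child level:  ", x$n_folds))
  print(x$child_metrics)
  cat("  window level: ")
  print(x$window_metrics)
  invisible(x)
}
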