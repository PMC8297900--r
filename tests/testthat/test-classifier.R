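test_that("both backends fit linearly separable window classes", {
  w <- make_separable_windows(n_per_class = 40, seed = 1)
  truth <- window_truth(w)
  for (bk in c("logistic", "recurrent")) {
    spec <- model_spec(backend = bk, epochs = 40, seed = 7)
    m <- train_classifier(w, spec)
    p <- predict_windows(m, w)
    expect_gte(mean(p$hard_label == truth), 0.95)
    expect_true(all(p$p_insecure >= 0 & p$p_insecure <= 1))
    if (bk == "recurrent") {
      lh <- m$fit$loss_history
      expect_lt(lh[length(lh)], lh[1])  # training loss decreases
    }
  }
})

test_that("held-out windows from the separable fixture are classified", {
  train <- make_separable_windows(n_per_class = 40, seed = 1)
  test <- make_separable_windows(n_per_class = 20, seed = 2)
  m <- train_classifier(train, model_spec(backend = "recurrent",
                                          epochs = 40, seed = 3))
  p <- predict_windows(m, test)
  expect_equal(nrow(p), length(test))
  expect_gte(mean(p$hard_label == window_truth(test)), 0.9)
})

test_that("training and prediction are deterministic under a fixed seed", {
  w <- make_separable_windows(n_per_class = 10, seed = 4)
  held <- make_separable_windows(n_per_class = 5, seed = 5)
  spec <- model_spec(backend = "recurrent", epochs = 15, seed = 7)
  p1 <- predict_windows(train_classifier(w, spec), held)
  p2 <- predict_windows(train_classifier(w, spec), held)
  expect_identical(p1, p2)
  # prediction is a pure function
  m <- train_classifier(w, spec)
  expect_identical(predict_windows(m, held), predict_windows(m, held))
})

test_that("degenerate training inputs are rejected", {
  w <- make_separable_windows(n_per_class = 6, seed = 1)
  one_class <- w[window_truth(w) == "secure"]
  expect_error(train_classifier(one_class, model_spec()), "one class")
  short_w <- w
  short_w[[1]]$features <- w[[1]]$features[1:64, ]
  expect_error(train_classifier(short_w, model_spec()),
               "inconsistent window shapes")
})

test_that("prediction refuses schema mismatches and handles empty input", {
  w <- make_separable_windows(n_per_class = 6, seed = 1)
  m <- train_classifier(w, model_spec())
  expect_equal(nrow(predict_windows(m, list())), 0)
  bad <- w
  for (i in seq_along(bad)) {
    bad[[i]]$features <- bad[[i]]$features[, 1:10]
  }
  expect_error(predict_windows(m, bad), "schema mismatch")
})

test_that("a serialised model round-trips and still guards its schema", {
  w <- make_separable_windows(n_per_class = 6, seed = 2)
  m <- train_classifier(w, model_spec())
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict_windows(m2, w), predict_windows(m, w))
  expect_identical(m2$schema, m$schema)
})

test_that("majority vote counts, caps and breaks ties to insecure", {
  # unanimity
  r <- majority_vote(make_predictions("c1", rep("insecure", 10)))
  expect_equal(r$label, "insecure")
  expect_equal(r$vote_fraction, 1)
  expect_equal(r$n_windows, 10)
  # 260 secure vs 240 insecure under the 500-window cap
  votes <- c(rep("secure", 260), rep("insecure", 240))
  r <- majority_vote(make_predictions("c1", votes), cap = 500)
  expect_equal(r$label, "secure")
  expect_equal(r$vote_fraction, 0.52)
  expect_equal(r$n_windows, 500)
  # exact tie resolves to insecure
  r <- majority_vote(make_predictions("c1", rep(c("secure", "insecure"),
                                                each = 250)))
  expect_equal(r$label, "insecure")
  expect_equal(r$vote_fraction, 0.5)
  # the cap keeps only the earliest windows in temporal order
  votes <- c(rep("insecure", 3), rep("secure", 7))
  r <- majority_vote(make_predictions("c1", votes), cap = 3)
  expect_equal(r$label, "insecure")
  expect_equal(r$n_windows, 3)
})

test_that("majority vote validates its input", {
  p <- rbind(make_predictions("c1", "secure"),
             make_predictions("c2", "secure"))
  expect_error(majority_vote(p), "mix several children")
  expect_error(majority_vote(make_predictions("c1", character(0))),
               "no predictions")
})

test_that("vote properties: flip symmetry, permutation, fraction range", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(1:30, 1)
    votes <- sample(c("secure", "insecure"), n, replace = TRUE)
    r <- majority_vote(make_predictions("c", votes))
    expect_gte(r$vote_fraction, 0.5)
    expect_lte(r$vote_fraction, 1)
    # permutation invariance when n <= cap
    perm <- sample(n)
    p2 <- make_predictions("c", votes)
    p2 <- p2[perm, ]
    expect_equal(majority_vote(p2)$label, r$label)
    # flipping every vote flips the rating except at an exact tie
    flipped <- ifelse(votes == "secure", "insecure", "secure")
    rf <- majority_vote(make_predictions("c", flipped))
    if (sum(votes == "insecure") * 2 != n) {
      expect_false(rf$label == r$label)
    } else {
      expect_equal(rf$label, "insecure")
      expect_equal(r$label, "insecure")
    }
  }
})

test_that("the inter-hand distance family alone carries class signal", {
  co_train <- simulate_cohort(cohort_spec(n_children = 12,
                                          frames_per_child = 384,
                                          seed = 21))
  co_test <- simulate_cohort(cohort_spec(n_children = 12,
                                         frames_per_child = 384,
                                         seed = 22))
  wtr <- cohort_windows(co_train)
  wte <- cohort_windows(co_test)
  spec <- model_spec(backend = "logistic",
                     summary_features = c("dist_mean", "dist_sd",
                                          "dist_valid_mean"))
  m <- train_classifier(wtr, spec)
  p <- predict_windows(m, wte)
  acc <- mean(p$hard_label == window_truth(wte))
  expect_gt(acc, 0.65)   # clearly above chance on 36 windows
})
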